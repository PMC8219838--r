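# Orchestration: stimulus/behavior -> synthetic LGN (or provided rasters)
# -> F1 d' -> population pooling -> cone matched filter -> cross-stage gaps,
# all from one config, fully reproducible given its master seed.

build_tcsf <- function(config) {
  if (is.null(config$tcsf)) tcsf_model() else do.call(tcsf_model, config$tcsf)
}

build_population <- function(config) {
  if (is.null(config$population)) population_model()
  else do.call(population_model, config$population)
}

build_cones <- function(config) {
  if (is.null(config$cones)) cone_mosaic_model()
  else do.call(cone_mosaic_model, config$cones)
}

#' Run the full cross-stage experiment
#'
#' Executes the whole pipeline from a config: builds the threshold-contrast
#' stimulus schedule, simulates magno and parvo LNP neurons (or analyzes
#' provided trial sets), estimates F1 d' with bootstrap SEs per neuron and
#' condition, pools to population d', computes the cone-array matched-filter
#' d', and tabulates cone vs LGN vs behavior SNR gaps per condition.
#'
#' @param config a config list (see [default_config()]); validated first.
#' @param trial_sets optional named list `list(magno = list(...), parvo =
#'   list(...))` of [trial_set()] objects to analyze instead of simulating
#'   (their condition tables must match the schedule the config implies).
#' @param out_dir optional directory; when given, the condition table,
#'   per-neuron d' table, stage-comparison table, window-sweep matrices and
#'   a metadata sidecar (config echo, seeds, package version) are written
#'   there as plain delimited text.
#' @param verbose emit stage-boundary log messages.
#' @return object of class `stage_comparison`: list with `comparison` (per
#'   condition: behavioral criterion, magno/parvo population d' and SE, cone
#'   d', cone-to-LGN and LGN-to-behavior gaps and transmitted fractions),
#'   `per_neuron`, `sweeps`, `schedule`, `criterion`, `config`.
#' @export
run_experiment <- function(config = default_config(), trial_sets = NULL,
                           out_dir = NULL, verbose = FALSE) {
  config <- validate_config(config)
  seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))

  tcsf <- build_tcsf(config)
  st <- config$stimulus
  schedule <- stimulus_schedule(tcsf, st$frequencies, st$directions,
                                st$eccentricity, st$duration, st$ramp,
                                st$aperture_sigma)
  if (any(schedule$clipped))
    warning(sprintf("threshold contrast gamut-clipped for: %s",
                    paste(schedule$condition_id[schedule$clipped],
                          collapse = ", ")), call. = FALSE)
  criterion <- config$behavior$criterion %||%
    pc_to_dprime(config$behavior$pc)
  say("schedule: %d conditions, behavioral criterion d' = %.3f",
      nrow(schedule), criterion)

  if (is.null(trial_sets)) {
    nm <- config$neurons$n_magno
    np <- config$neurons$n_parvo
    mk <- function(class, i, off) make_neuron(
      class, st$eccentricity, seed = derive_seed(seed, off + i),
      latency = config$neurons$latency,
      surround_delay = config$neurons$surround_delay)
    neurons <- list(
      magno = lapply(seq_len(nm), function(i) mk("magno", i, 100L)),
      parvo = lapply(seq_len(np), function(i) mk("parvo", i, 200L)))
    say("simulating %d magno + %d parvo neurons, %d trials/condition",
        nm, np, config$trials$n_per_condition)
    trial_sets <- list(
      magno = generate_experiment(neurons$magno, schedule,
                                  config$trials$n_per_condition,
                                  seed = derive_seed(seed, 300L),
                                  dt = config$trials$dt,
                                  pad = config$trials$pad),
      parvo = generate_experiment(neurons$parvo, schedule,
                                  config$trials$n_per_condition,
                                  seed = derive_seed(seed, 400L),
                                  dt = config$trials$dt,
                                  pad = config$trials$pad))
  }

  stim_ids <- schedule$condition_id[schedule$direction != "blank"]
  B <- config$snr$bootstrap_B
  per_neuron <- list()
  counter <- 0L
  for (class in names(trial_sets)) {
    for (i in seq_along(trial_sets[[class]])) {
      ts <- trial_sets[[class]][[i]]
      for (cid in stim_ids) {
        counter <- counter + 1L
        est <- dprime_f1(ts, cid, B = B,
                         seed = derive_seed(seed, 500L + counter))
        per_neuron[[length(per_neuron) + 1L]] <- data.frame(
          cell_class = class, neuron = i, condition_id = cid,
          frequency_hz = est$frequency,
          direction = schedule$direction[schedule$condition_id == cid],
          dprime = est$dprime, se = est$se,
          window_start_s = est$window$start,
          window_end_s = est$window$end)
      }
    }
  }
  per_neuron <- do.call(rbind, per_neuron)
  say("estimated %d per-neuron d' values", nrow(per_neuron))

  pop <- build_population(config)
  cones <- build_cones(config)
  rows <- list()
  n_unphysical <- 0L
  for (cid in stim_ids) {
    spec <- schedule_spec(schedule, cid)
    d_cone <- cone_array_dprime(spec, cones, dt = config$trials$dt)
    row <- list(condition_id = cid, direction = spec$direction,
                frequency_hz = spec$temporal_frequency,
                contrast = spec$cone_contrast,
                criterion_dprime = criterion, cone_dprime = d_cone)
    for (class in c("magno", "parvo")) {
      sub <- per_neuron[per_neuron$cell_class == class &
                          per_neuron$condition_id == cid, ]
      d_mean <- mean(sub$dprime)
      d_sem <- sd(sub$dprime) / sqrt(nrow(sub))
      N_eff <- effective_neuron_count(pop, spec, class)
      pd <- population_dprime(d_mean, max(1, N_eff), pop[[class]]$rho)
      gap_cone <- snr_gap(d_cone, max(0, pd$dprime_pop))
      if (gap_cone$unphysical) n_unphysical <- n_unphysical + 1L
      row[[paste0(class, "_dprime_single")]] <- d_mean
      row[[paste0(class, "_N_eff")]] <- N_eff
      row[[paste0(class, "_scale_factor")]] <- pd$scale_factor
      row[[paste0(class, "_dprime_pop")]] <- pd$dprime_pop
      row[[paste0(class, "_se_pop")]] <- pd$scale_factor * d_sem
      row[[paste0("cone_to_", class, "_gap")]] <- gap_cone$difference
      row[[paste0("cone_to_", class, "_fraction")]] <- gap_cone$fraction
      row[[paste0(class, "_unphysical")]] <- gap_cone$unphysical
      row[[paste0(class, "_to_behavior_gap")]] <- pd$dprime_pop - criterion
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row)
  }
  comparison <- do.call(rbind, rows)
  if (n_unphysical > 0)
    warning(sprintf(
      "%d condition(s) with unphysical cone-to-LGN SNR gap (LGN > cones)",
      n_unphysical), call. = FALSE)
  say("cross-stage comparison assembled (%d unphysical gaps)", n_unphysical)

  # window sweeps at the lowest preferred-direction frequency
  offs <- config$snr$sweep_offsets
  sweeps <- list()
  pick_low <- function(dir) {
    ids <- schedule$condition_id[schedule$direction == dir]
    ids[which.min(schedule$frequency_hz[schedule$direction == dir])]
  }
  for (class in c("magno", "parvo")) {
    dir <- if (class == "magno") "L_plus_M" else "L_minus_M"
    if (!dir %in% schedule$direction ||
        length(trial_sets[[class]]) == 0) next
    sweeps[[class]] <- window_sweep(trial_sets[[class]][[1]],
                                    pick_low(dir), offs, offs, criterion)
  }

  result <- structure(list(comparison = comparison, per_neuron = per_neuron,
                           sweeps = sweeps, schedule = schedule,
                           criterion = criterion,
                           n_unphysical = n_unphysical, config = config),
                      class = "stage_comparison")
  if (!is.null(out_dir)) write_stage_comparison(result, out_dir)
  result
}

write_stage_comparison <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(as.data.frame(result$schedule), "conditions.tsv")
  tsv(result$per_neuron, "per_neuron_dprime.tsv")
  tsv(result$comparison, "stage_comparison.tsv")
  for (class in names(result$sweeps)) {
    sw <- result$sweeps[[class]]
    tsv(data.frame(start_offset_s = rep(sw$start_offsets,
                                        times = length(sw$end_offsets)),
                   end_offset_s = rep(sw$end_offsets,
                                      each = length(sw$start_offsets)),
                   dprime = as.vector(sw$dprime)),
        sprintf("window_sweep_%s_%s.tsv", class, sw$condition_id))
  }
  yaml::write_yaml(list(package = "lgnsnr", version = "0.1.0",
                        seed = result$config$seed,
                        criterion = result$criterion,
                        config = result$config),
                   file.path(out_dir, "metadata.yaml"))
  invisible(out_dir)
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat(sprintf(
    "<stage_comparison> %d conditions, behavioral criterion d' = %.3f\n",
    nrow(x$comparison), x$criterion))
  cols <- c("direction", "frequency_hz", "contrast", "cone_dprime",
            "magno_dprime_pop", "parvo_dprime_pop")
  df <- x$comparison[, cols]
  df[, -1] <- lapply(df[, -1], function(v) round(v, 3))
  print(df, row.names = FALSE)
  if (x$n_unphysical > 0)
    cat(sprintf("NOTE: %d unphysical cone-to-LGN gap(s)\n", x$n_unphysical))
  invisible(x)
}

#' @export
summary.stage_comparison <- function(object, ...) {
  cmp <- object$comparison
  hi <- cmp[cmp$frequency_hz == max(cmp$frequency_hz), ]
  lo <- cmp[cmp$frequency_hz == min(cmp$frequency_hz), ]
  out <- list(
    criterion = object$criterion,
    n_conditions = nrow(cmp),
    n_unphysical_gaps = object$n_unphysical,
    parvo_magno_scale_ratio =
      mean(cmp$parvo_scale_factor / cmp$magno_scale_factor),
    high_freq_lgn_over_criterion =
      max(hi$magno_dprime_pop, hi$parvo_dprime_pop) / object$criterion,
    low_freq_parvo_LmM_pop_dprime =
      lo$parvo_dprime_pop[lo$direction == "L_minus_M"],
    min_cone_to_lgn_fraction =
      min(cmp$cone_to_magno_fraction, cmp$cone_to_parvo_fraction))
  structure(out, class = "summary.stage_comparison")
}

#' @export
print.summary.stage_comparison <- function(x, ...) {
  cat("Cross-stage SNR summary\n")
  cat(sprintf("  behavioral criterion d'          : %.3f\n", x$criterion))
  cat(sprintf("  conditions                       : %d\n", x$n_conditions))
  cat(sprintf("  unphysical cone-to-LGN gaps      : %d\n",
              x$n_unphysical_gaps))
  cat(sprintf("  parvo:magno scale-factor ratio   : %.2f\n",
              x$parvo_magno_scale_ratio))
  cat(sprintf("  high-freq LGN / criterion        : %.2f\n",
              x$high_freq_lgn_over_criterion))
  cat(sprintf("  low-freq parvo L-M population d' : %.2f\n",
              x$low_freq_parvo_LmM_pop_dprime))
  cat(sprintf("  min cone-to-LGN transmitted frac : %.3f\n",
              x$min_cone_to_lgn_fraction))
  invisible(x)
}

#' @export
plot.stage_comparison <- function(x, ...) {
  cmp <- x$comparison
  dirs <- unique(cmp$direction)
  old <- graphics::par(mfrow = c(1, length(dirs)))
  on.exit(graphics::par(old))
  for (dir in dirs) {
    sub <- cmp[cmp$direction == dir, ]
    y <- cbind(sub$cone_dprime, sub$magno_dprime_pop, sub$parvo_dprime_pop)
    matplot(sub$frequency_hz, pmax(y, 1e-3), type = "b", log = "xy",
            pch = c(2, 17, 16), lty = 1,
            col = c("gray40", "black", "magenta3"),
            xlab = "temporal frequency (Hz)", ylab = "d'",
            main = gsub("_", " ", dir), ...)
    abline(h = x$criterion, lty = 2)
    legend("bottomright", c("cones", "magno pop", "parvo pop", "criterion"),
           pch = c(2, 17, 16, NA), lty = c(1, 1, 1, 2),
           col = c("gray40", "black", "magenta3", "black"), bty = "n",
           cex = 0.8)
  }
  invisible(x)
}
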