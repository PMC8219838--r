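# Ideal-observer SNR estimation from spike trains. The per-trial response
# statistic is the magnitude of the complex projection of the spike train
# onto the stimulus fundamental frequency (F1); d' compares its distribution
# across stimulus trials with the blank-trial distribution under the
# equal-weight pooled-variance convention. Response phase is not assumed
# known, hence the magnitude rather than a signed projection.

#' Counting window
#' @param start,end window limits in seconds; `end > start`.
#' @return object of class `counting_window`.
#' @export
counting_window <- function(start, end) {
  if (!(end > start))
    stop_lgnsnr("counting window requires end > start",
                "lgnsnr_invalid_parameter")
  structure(list(start = start, end = end), class = "counting_window")
}

#' Complex F1 projection of a spike train
#'
#' Sum over spikes in `[start, end)` of `exp(-1i * 2 * pi * f * t_k)`. The
#' empty train gives `0 + 0i`.
#'
#' @param spike_times numeric vector of spike times, seconds.
#' @param window a [counting_window()].
#' @param f temporal frequency, Hz (`> 0`).
#' @return a complex scalar (cosine projection in the real part, negative
#'   sine projection in the imaginary part).
#' @export
f1_projection <- function(spike_times, window, f) {
  stopifnot(inherits(window, "counting_window"), f > 0)
  tk <- spike_times[spike_times >= window$start & spike_times < window$end]
  if (length(tk) == 0) return(complex(real = 0, imaginary = 0))
  sum(exp(-2i * pi * f * tk))
}

# per-trial |F1| for every trial of one condition (empty trials included)
trial_f1_stats <- function(ts, condition_id, window, f) {
  ids <- ts$trials$trial_id[ts$trials$condition_id == condition_id]
  spk <- ts$spikes[ts$spikes$condition_id == condition_id, , drop = FALSE]
  by_trial <- split(spk$spike_time_s, factor(spk$trial_id, levels = ids))
  vapply(by_trial,
         function(st) Mod(f1_projection(st, window, f)),
         numeric(1))
}

blank_condition_id <- function(ts) {
  id <- ts$conditions$condition_id[ts$conditions$direction == "blank"]
  if (length(id) == 0)
    stop_lgnsnr("no blank condition available for baseline",
                "lgnsnr_missing_baseline")
  id[1]
}

dprime_from_stats <- function(stat_stim, stat_blank) {
  vs <- var(stat_stim); vb <- var(stat_blank)
  pooled <- (vs + vb) / 2
  if (pooled == 0) {
    d <- if (mean(stat_stim) == mean(stat_blank)) 0 else
      sign(mean(stat_stim) - mean(stat_blank)) * Inf
    attr(d, "degenerate") <- TRUE
    return(d)
  }
  (mean(stat_stim) - mean(stat_blank)) / sqrt(pooled)
}

#' F1-based d' of one stimulus condition against blank
#'
#' Each trial is summarized by the magnitude of its F1 projection at the
#' condition's fundamental frequency; blank trials are scored at the same
#' frequency. d' is the difference of stimulus and blank means in units of
#' the equally weighted pooled standard deviation. Negative estimates are
#' permitted (estimator noise).
#'
#' @param ts a [trial_set()].
#' @param condition_id a non-blank condition identifier.
#' @param window a [counting_window()]; defaults to the stimulus
#'   presentation epoch `[stim_on, stim_off)`.
#' @param B bootstrap resample count for the standard error (0 to skip).
#' @param seed bootstrap seed.
#' @return object of class `dprime_estimate` with fields `dprime`, `se`,
#'   `window`, `n_stim`, `n_blank`, `frequency`, `condition_id`,
#'   `degenerate`.
#' @export
dprime_f1 <- function(ts, condition_id, window = NULL, B = 0, seed = 1) {
  stopifnot(inherits(ts, "trial_set"))
  if (is.null(window)) window <- counting_window(ts$stim_on, ts$stim_off)
  crow <- ts$conditions[ts$conditions$condition_id == condition_id, ,
                        drop = FALSE]
  if (nrow(crow) != 1L)
    stop_lgnsnr(sprintf("unknown condition '%s'", condition_id),
                "lgnsnr_invalid_parameter")
  f <- crow$frequency_hz
  if (is.na(f) || f <= 0)
    stop_lgnsnr("condition has no valid fundamental frequency (blank?)",
                "lgnsnr_invalid_parameter")
  blank_id <- blank_condition_id(ts)
  stat_stim <- trial_f1_stats(ts, condition_id, window, f)
  stat_blank <- trial_f1_stats(ts, blank_id, window, f)
  if (length(stat_stim) < 2 || length(stat_blank) < 2)
    stop_lgnsnr("need at least 2 stimulus and 2 blank trials",
                "lgnsnr_insufficient_data")
  d <- dprime_from_stats(stat_stim, stat_blank)
  se <- if (B >= 2) bootstrap_se_stats(stat_stim, stat_blank, B, seed)
        else NA_real_
  structure(list(dprime = as.numeric(d), se = se, window = window,
                 n_stim = length(stat_stim), n_blank = length(stat_blank),
                 frequency = f, condition_id = condition_id,
                 degenerate = isTRUE(attr(d, "degenerate"))),
            class = "dprime_estimate")
}

#' @export
print.dprime_estimate <- function(x, ...) {
  cat(sprintf("<dprime_estimate> condition %s (%g Hz): d' = %.3f%s, window [%g, %g) s, n = %d/%d%s\n",
              x$condition_id, x$frequency, x$dprime,
              if (is.na(x$se)) "" else sprintf(" +/- %.3f (bootstrap SE)", x$se),
              x$window$start, x$window$end, x$n_stim, x$n_blank,
              if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}

bootstrap_se_stats <- function(stat_stim, stat_blank, B, seed) {
  set.seed(seed)
  ns <- length(stat_stim); nb <- length(stat_blank)
  reps <- vapply(seq_len(B), function(b) {
    s <- stat_stim[sample.int(ns, ns, replace = TRUE)]
    bl <- stat_blank[sample.int(nb, nb, replace = TRUE)]
    as.numeric(dprime_from_stats(s, bl))
  }, numeric(1))
  sd(reps[is.finite(reps)])
}

#' Nonparametric bootstrap standard error of the F1 d'
#'
#' Trials are resampled with replacement independently within the stimulus
#' and blank sets; the SE is the standard deviation of the d' statistic over
#' `B` resamples. Deterministic given `seed`.
#'
#' @inheritParams dprime_f1
#' @param B resample count (`>= 2`; default 2000).
#' @param seed RNG seed.
#' @return scalar standard error.
#' @export
bootstrap_se <- function(ts, condition_id, window = NULL, B = 2000,
                         seed = 1) {
  if (B < 2)
    stop_lgnsnr("bootstrap needs B >= 2", "lgnsnr_invalid_parameter")
  if (is.null(window)) window <- counting_window(ts$stim_on, ts$stim_off)
  crow <- ts$conditions[ts$conditions$condition_id == condition_id, ,
                        drop = FALSE]
  f <- crow$frequency_hz
  stat_stim <- trial_f1_stats(ts, condition_id, window, f)
  stat_blank <- trial_f1_stats(ts, blank_condition_id(ts), window, f)
  bootstrap_se_stats(stat_stim, stat_blank, B, seed)
}

#' Spike-counting-window sweep of d'
#'
#' Recomputes the F1 d' on windows `[stim_on + start_i, stim_off + end_j)`
#' for every combination of start and end offsets, mirroring the analysis in
#' which start and stop times for spike inclusion are varied independently
#' over a 200-ms range. Offset pairs yielding an empty window are flagged
#' `NA`, not errors.
#'
#' @param ts a [trial_set()].
#' @param condition_id non-blank condition.
#' @param start_offsets,end_offsets offsets in seconds added to the stimulus
#'   onset (window start) and offset (window end); default 0-200 ms in 20-ms
#'   steps.
#' @param criterion d' level for the returned level-set (default 1.27, the
#'   behavioral criterion for 82% correct).
#' @return object of class `window_sweep`: list with the d' `matrix`
#'   (rows = start offsets, cols = end offsets), the offsets, and
#'   `above_criterion`, the boolean level-set `d' >= criterion`.
#' @export
window_sweep <- function(ts, condition_id,
                         start_offsets = seq(0, 0.2, by = 0.02),
                         end_offsets = seq(0, 0.2, by = 0.02),
                         criterion = 1.27) {
  m <- matrix(NA_real_, length(start_offsets), length(end_offsets),
              dimnames = list(sprintf("%g", start_offsets),
                              sprintf("%g", end_offsets)))
  for (i in seq_along(start_offsets)) for (j in seq_along(end_offsets)) {
    s <- ts$stim_on + start_offsets[i]
    e <- ts$stim_off + end_offsets[j]
    if (s >= e) next
    m[i, j] <- dprime_f1(ts, condition_id,
                         counting_window(s, e))$dprime
  }
  structure(list(dprime = m, start_offsets = start_offsets,
                 end_offsets = end_offsets, criterion = criterion,
                 above_criterion = !is.na(m) & m >= criterion,
                 condition_id = condition_id),
            class = "window_sweep")
}

#' @export
print.window_sweep <- function(x, ...) {
  cat(sprintf("<window_sweep> condition %s: %d x %d windows, d' in [%.3f, %.3f], %d at or above criterion %.2f\n",
              x$condition_id, nrow(x$dprime), ncol(x$dprime),
              min(x$dprime, na.rm = TRUE), max(x$dprime, na.rm = TRUE),
              sum(x$above_criterion), x$criterion))
  invisible(x)
}

#' Spike-triggered average
#'
#' Spike-weighted mean of the stimulus `l` frames before each spike, minus
#' the raw stimulus mean, for lags `0 .. n_lags - 1`. Used to localize the
#' receptive field and classify neurons under white-noise stimulation.
#'
#' @param noise_frames numeric matrix (frames x stimulus dimensions) or
#'   vector of stimulus values at the frame rate.
#' @param spike_counts_per_frame integer vector, aligned with the frames.
#' @param n_lags number of lags (`>= 1`).
#' @return matrix (n_lags x stimulus dimensions) of STA values.
#' @export
spike_triggered_average <- function(noise_frames, spike_counts_per_frame,
                                    n_lags) {
  if (is.vector(noise_frames)) noise_frames <- matrix(noise_frames, ncol = 1)
  stopifnot(nrow(noise_frames) == length(spike_counts_per_frame),
            n_lags >= 1)
  total <- sum(spike_counts_per_frame)
  if (total == 0)
    stop_lgnsnr("no spikes: spike-triggered average undefined",
                "lgnsnr_undefined_sta")
  mu <- colMeans(noise_frames)
  nf <- nrow(noise_frames)
  sta <- matrix(NA_real_, n_lags, ncol(noise_frames))
  for (l in seq_len(n_lags) - 1L) {
    idx <- seq_len(nf - l)             # frame preceding each spike by l
    w <- spike_counts_per_frame[idx + l]
    sta[l + 1L, ] <- colSums(noise_frames[idx, , drop = FALSE] * w) /
      sum(w) - mu
  }
  sta
}

#' Write a d' results table
#'
#' Delimited export with columns `condition_id, frequency_hz, direction,
#' dprime, se, window_start_s, window_end_s`.
#'
#' @param estimates list of [dprime_f1()] results.
#' @param conditions the condition table (for direction lookup).
#' @param path output file path.
#' @export
write_dprime_table <- function(estimates, conditions, path) {
  rows <- lapply(estimates, function(e) {
    dir <- conditions$direction[conditions$condition_id == e$condition_id]
    data.frame(condition_id = e$condition_id, frequency_hz = e$frequency,
               direction = dir, dprime = e$dprime, se = e$se,
               window_start_s = e$window$start, window_end_s = e$window$end)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
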