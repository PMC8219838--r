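# Synthetic LGN: linear-nonlinear-Poisson magno/parvo neurons whose
# temporal tuning arises from center-surround subtraction with a delayed
# surround. Spatial structure is collapsed (the Gabor is approximately
# uniform within the RF), so center and surround are temporal channels with
# scalar cone weights sharing one gamma kernel; the surround is the center
# kernel delayed by delta. At low temporal frequency the delayed surround
# nearly cancels the center for stimuli that drive both (L+M for magno,
# making magno bandpass); a single-cone center with a mixed surround leaves
# L-M input uncancelled (parvo lowpass for L-M).

#' Construct a synthetic LGN neuron
#'
#' Draws a linear-nonlinear-Poisson neuron from class-conditional parameter
#' distributions. Magno neurons have non-opponent centers and surrounds
#' (`w_Lc = w_Mc`, `w_Ls = w_Ms`); parvo neurons have a single-cone center
#' and a mixed surround. Baseline rates, gains and the ~100-120 ms response
#' latency are calibrated so that single-neuron d' at threshold contrast is
#' of order 0.1-3 (population d' of order 1-10).
#'
#' @param cell_class `"magno"` or `"parvo"`.
#' @param eccentricity RF eccentricity, degrees.
#' @param seed RNG seed (same seed, same neuron).
#' @param latency mean response latency, seconds.
#' @param surround_delay surround delay delta, seconds (default 10 ms).
#' @return object of class `lnp_neuron`.
#' @export
make_neuron <- function(cell_class, eccentricity = 5, seed = 1,
                        latency = 0.1, surround_delay = 0.010) {
  if (!cell_class %in% c("magno", "parvo"))
    stop_lgnsnr(sprintf("unknown cell class '%s'", cell_class),
                "lgnsnr_invalid_parameter")
  set.seed(seed)
  jit <- function(x, cv = 0.1) x * exp(rnorm(1, 0, cv))
  if (cell_class == "magno") {
    # fast kernel, near-balanced delayed surround: bandpass for L+M
    w_c <- 1; w_s <- 0.95
    weights <- list(w_Lc = w_c, w_Mc = w_c, w_Ls = w_s, w_Ms = w_s)
    r0 <- jit(12); g <- jit(600); tau <- 0.006
  } else {
    # slower kernel, single-cone center, mixed surround: lowpass for L-M
    center_cone <- sample(c("L", "M"), 1)
    weights <- list(
      w_Lc = if (center_cone == "L") 1 else 0,
      w_Mc = if (center_cone == "M") 1 else 0,
      w_Ls = 0.4, w_Ms = 0.4)
    r0 <- jit(8); g <- jit(350); tau <- 0.012
  }
  structure(c(list(cell_class = cell_class, eccentricity = eccentricity,
                   kernel_tau = tau, kernel_n = 3,
                   surround_delay = surround_delay,
                   baseline_rate = r0, contrast_gain = g,
                   latency = max(0, latency + rnorm(1, 0, 0.005)),
                   seed = seed),
              weights),
            class = "lnp_neuron")
}

#' @export
print.lnp_neuron <- function(x, ...) {
  cat(sprintf("<lnp_neuron> %s at %.1f deg: weights C(%.2g,%.2g) S(%.2g,%.2g), r0 %.1f sp/s, gain %.0f, latency %.0f ms, surround delay %.0f ms\n",
              x$cell_class, x$eccentricity, x$w_Lc, x$w_Mc, x$w_Ls, x$w_Ms,
              x$baseline_rate, x$contrast_gain, 1000 * x$latency,
              1000 * x$surround_delay))
  invisible(x)
}

# monophasic gamma kernel normalized to unit DC gain
lnp_kernel <- function(neuron, dt, length = 0.2) {
  t <- seq(dt, length, by = dt)
  k <- (t / neuron$kernel_tau)^(neuron$kernel_n - 1) *
    exp(-t / neuron$kernel_tau)
  k / (sum(k) * dt)
}

shift_lag <- function(x, lag_samples) {
  n <- length(x)
  if (lag_samples <= 0) return(x)
  c(numeric(min(lag_samples, n)), x)[seq_len(n)]
}

#' Firing rate of an LNP neuron driven by cone-contrast waveforms
#'
#' `rate(t) = max(0, r0 + g * [center_drive (x) k](t - latency)
#'                    - g * [surround_drive (x) k](t - latency - delta))`
#' where `center_drive = w_Lc c_L + w_Mc c_M`, `surround_drive = w_Ls c_L +
#' w_Ms c_M`, `k` is the shared gamma kernel and `delta` the surround delay.
#' Half-wave rectification at zero.
#'
#' @param neuron an [make_neuron()] result.
#' @param c_L,c_M uniformly sampled cone-contrast waveforms (equal length).
#' @param dt sample interval, seconds.
#' @return firing rate vector, spikes/s, same length as the input.
#' @export
drive <- function(neuron, c_L, c_M, dt) {
  if (length(c_L) != length(c_M))
    stop_lgnsnr("c_L and c_M must have the same length",
                "lgnsnr_invalid_input")
  k <- lnp_kernel(neuron, dt)
  center <- filtered_signal(neuron$w_Lc * c_L + neuron$w_Mc * c_M, k, dt)
  surround <- filtered_signal(neuron$w_Ls * c_L + neuron$w_Ms * c_M, k, dt)
  lag_c <- round(neuron$latency / dt)
  lag_s <- round((neuron$latency + neuron$surround_delay) / dt)
  lin <- neuron$baseline_rate +
    neuron$contrast_gain * (shift_lag(center, lag_c) -
                            shift_lag(surround, lag_s))
  pmax(0, lin)
}

#' Sample inhomogeneous Poisson spike trains from a rate function
#'
#' Bin-wise Poisson counts (`rate * dt` expected per bin) with spike times
#' placed uniformly within their bin; exact for the piecewise-constant rate
#' used throughout. Deterministic given `seed`.
#'
#' @param rate nonnegative rate vector, spikes/s, sampled at `dt`.
#' @param dt sample interval, seconds.
#' @param n_trials number of independent trials.
#' @param seed RNG seed.
#' @return list of `n_trials` sorted spike-time vectors (seconds).
#' @export
sample_spikes <- function(rate, dt, n_trials, seed = 1) {
  if (any(rate < 0))
    stop_lgnsnr("rate must be nonnegative", "lgnsnr_invalid_input")
  set.seed(seed)
  nb <- length(rate)
  counts <- matrix(rpois(nb * n_trials, rate * dt), nrow = nb)
  t0 <- (seq_len(nb) - 1L) * dt
  lapply(seq_len(n_trials), function(j) {
    cj <- counts[, j]
    idx <- rep.int(seq_len(nb), cj)
    if (length(idx) == 0) return(numeric(0))
    sort(t0[idx] + runif(length(idx)) * dt)
  })
}

#' Generate a full synthetic experiment
#'
#' For each neuron, simulates `n_trials` spike trains per condition of the
#' stimulus schedule (contrasts at behavioral threshold as recorded in the
#' schedule, including the blank whose rate is the neuron's baseline), and
#' assembles them into [trial_set()] objects. Every neuron x condition block
#' uses a sub-seed derived from `seed` via [derive_seed()].
#'
#' @param neurons a single [make_neuron()] result or a list of them.
#' @param schedule a [stimulus_schedule()] (must contain a blank).
#' @param n_trials trials per condition.
#' @param seed master seed.
#' @param dt simulation step, seconds.
#' @param pad post-stimulus recording pad, seconds (captures latency-shifted
#'   spikes).
#' @return a list of [trial_set()] (one per neuron), or a single
#'   [trial_set()] when one neuron is given.
#' @export
generate_experiment <- function(neurons, schedule, n_trials = 50, seed = 1,
                                dt = 0.001, pad = 0.3) {
  if (inherits(neurons, "lnp_neuron")) {
    single <- TRUE
    neurons <- list(neurons)
  } else single <- FALSE
  if (!any(schedule$direction == "blank"))
    stop_lgnsnr("schedule contains no blank condition",
                "lgnsnr_missing_baseline")
  duration <- schedule$duration_s[1]
  n_pad <- round(pad / dt)
  # epoch covers every sample bin (waveforms have duration/dt + 1 samples)
  epoch_end <- (round(duration / dt) + 1 + n_pad) * dt
  out <- vector("list", length(neurons))
  counter <- 0L
  for (i in seq_along(neurons)) {
    nr <- neurons[[i]]
    trial_rows <- list(); spike_rows <- list()
    for (ci in seq_len(nrow(schedule))) {
      counter <- counter + 1L
      cid <- schedule$condition_id[ci]
      spec <- schedule_spec(schedule, cid)
      wf <- cone_contrast_waveforms(spec, dt)
      cl <- c(wf$c_L, numeric(n_pad)); cm <- c(wf$c_M, numeric(n_pad))
      rate <- drive(nr, cl, cm, dt)
      trains <- sample_spikes(rate, dt, n_trials,
                              seed = derive_seed(seed, counter))
      tids <- sprintf("n%02d_%s_t%04d", i, cid, seq_len(n_trials))
      trial_rows[[ci]] <- data.frame(trial_id = tids, condition_id = cid)
      ns <- lengths(trains)
      spike_rows[[ci]] <- data.frame(
        trial_id = rep(tids, ns), condition_id = cid,
        spike_time_s = unlist(trains))
    }
    out[[i]] <- trial_set(do.call(rbind, trial_rows),
                          do.call(rbind, spike_rows),
                          schedule, stim_on = 0, stim_off = duration,
                          epoch_end = epoch_end)
  }
  if (single) out[[1]] else out
}
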