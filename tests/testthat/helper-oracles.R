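# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive the statistics from first principles with
# different algorithms (thinning instead of bin-Poisson, direct complex
# sums instead of the package F1 helpers).

# Minimal condition table in the stimulus_schedule layout, with a blank.
make_test_schedule <- function(directions, frequencies, contrast,
                               duration = 0.666, ramp = 0.166,
                               eccentricity = 5, aperture_sigma = 0.4) {
  stopifnot(length(directions) == length(frequencies))
  out <- data.frame(
    condition_id = sprintf("c%02d", seq_len(length(directions) + 1L)),
    direction = c(directions, "blank"),
    frequency_hz = c(frequencies, NA_real_),
    contrast = c(rep(contrast, length(directions)), 0),
    duration_s = duration, ramp_s = ramp,
    eccentricity_deg = eccentricity, aperture_sigma_deg = aperture_sigma,
    clipped = FALSE)
  class(out) <- c("stimulus_schedule", "data.frame")
  out
}

# Sinusoidally modulated Poisson trains, rate r0 * (1 + m sin(2 pi f t)) on
# [0, T), generated by thinning a homogeneous process (independent of the
# package's bin-based sampler). Returns per-trial |F1| at frequency f.
oracle_f1_mags <- function(n_trials, r0, m, f, T) {
  rmax <- r0 * (1 + max(m, 0))
  counts <- rpois(n_trials, rmax * T)
  tot <- sum(counts)
  tt <- runif(tot, 0, T)
  keep <- runif(tot) < r0 * (1 + m * sin(2 * pi * f * tt)) / rmax
  grp <- factor(rep.int(seq_len(n_trials), counts)[keep],
                levels = seq_len(n_trials))
  z <- exp(-2i * pi * f * tt[keep])
  re <- tapply(Re(z), grp, sum, default = 0)
  im <- tapply(Im(z), grp, sum, default = 0)
  sqrt(re^2 + im^2)
}

oracle_dprime <- function(stat_stim, stat_blank) {
  (mean(stat_stim) - mean(stat_blank)) /
    sqrt((var(stat_stim) + var(stat_blank)) / 2)
}

# Assemble a trial_set from two lists of spike-time vectors (stimulus at
# frequency f, blanks), bypassing the package generator.
trains_to_trial_set <- function(stim_trains, blank_trains, f, T,
                                contrast = 0.5) {
  sched <- make_test_schedule("L_plus_M", f, contrast,
                              duration = T, ramp = 0)
  mk <- function(trains, cid, tag) {
    ids <- sprintf("%s_t%04d", tag, seq_along(trains))
    ns <- lengths(trains)
    list(trials = data.frame(trial_id = ids, condition_id = cid),
         spikes = data.frame(trial_id = rep(ids, ns), condition_id = cid,
                             spike_time_s = unlist(trains)))
  }
  s <- mk(stim_trains, "c01", "s")
  b <- mk(blank_trains, "c02", "b")
  trial_set(rbind(s$trials, b$trials), rbind(s$spikes, b$spikes),
            sched, stim_on = 0, stim_off = T, epoch_end = T)
}

# Thinned Poisson trains as raw spike-time lists.
oracle_trains <- function(n_trials, r0, m, f, T) {
  rmax <- r0 * (1 + max(m, 0))
  lapply(seq_len(n_trials), function(j) {
    k <- rpois(1, rmax * T)
    tt <- sort(runif(k, 0, T))
    tt[runif(k) < r0 * (1 + m * sin(2 * pi * f * tt)) / rmax]
  })
}
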