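test_that("neurons are reproducible draws with class-appropriate cone weights", {
  n1 <- make_neuron("magno", seed = 3)
  n2 <- make_neuron("magno", seed = 3)
  expect_identical(n1, n2)
  expect_false(identical(n1, make_neuron("magno", seed = 4)))
  expect_equal(n1$w_Lc, n1$w_Mc)   # non-opponent center
  p <- make_neuron("parvo", seed = 3)
  expect_equal(sort(c(p$w_Lc, p$w_Mc)), c(0, 1))  # single-cone center
  expect_error(make_neuron("konio"), class = "lgnsnr_invalid_parameter")
})

test_that("the rate stays at baseline for blanks and is never negative", {
  nr <- make_neuron("magno", seed = 1)
  z <- numeric(1000)
  expect_equal(drive(nr, z, z, 0.001), rep(nr$baseline_rate, 1000))
  wf <- cone_contrast_waveforms(stimulus_spec("L_plus_M", 8, 0.5), 0.001)
  expect_true(all(drive(nr, wf$c_L, wf$c_M, 0.001) >= 0))
  expect_error(drive(nr, z, z[-1], 0.001), class = "lgnsnr_invalid_input")
})

test_that("class signatures hold across the neuron population", {
  # F1 amplitude of the noise-free rate at the stimulus frequency
  f1_amp <- function(nr, direction, f, contrast = 0.1, dt = 0.001) {
    wf <- cone_contrast_waveforms(
      stimulus_spec(direction, f, contrast, duration = 2, ramp = 0), dt)
    r <- drive(nr, wf$c_L, wf$c_M, dt)
    t <- seq(0, by = dt, length.out = length(r))
    Mod(sum(r * exp(-2i * pi * f * t)) * dt)
  }
  magno_pref <- vapply(1:20, function(s) {
    nr <- make_neuron("magno", seed = s)
    f1_amp(nr, "L_plus_M", 10) > f1_amp(nr, "L_minus_M", 10)
  }, logical(1))
  parvo_pref <- vapply(1:20, function(s) {
    nr <- make_neuron("parvo", seed = s)
    f1_amp(nr, "L_minus_M", 2) > f1_amp(nr, "L_plus_M", 2)
  }, logical(1))
  expect_gte(mean(magno_pref), 0.9)
  expect_gte(mean(parvo_pref), 0.9)
})

test_that("the Poisson sampler delivers the requested mean count, support and determinism", {
  rate <- rep(40, 500)           # 40 sp/s for 0.5 s
  dt <- 0.001
  a <- sample_spikes(rate, dt, n_trials = 400, seed = 9)
  b <- sample_spikes(rate, dt, n_trials = 400, seed = 9)
  expect_identical(a, b)
  counts <- lengths(a)
  expect_equal(mean(counts), 20, tolerance = 0.1)    # ~ 3 SE
  expect_equal(var(counts), 20, tolerance = 0.25)    # Poisson dispersion
  all_t <- unlist(a)
  expect_true(all(all_t >= 0 & all_t <= 0.5))
  expect_false(is.unsorted(a[[1]]))
  expect_error(sample_spikes(c(1, -1), dt, 1), class = "lgnsnr_invalid_input")
})

test_that("a generated experiment is a complete, reproducible trial set", {
  sched <- make_test_schedule("L_plus_M", 8, 0.15)
  nr <- make_neuron("magno", seed = 2)
  ts <- generate_experiment(nr, sched, n_trials = 15, seed = 77)
  expect_s3_class(ts, "trial_set")
  expect_equal(nrow(ts$trials), 15 * nrow(sched))
  expect_equal(as.integer(table(ts$trials$condition_id)[sched$condition_id]),
               rep(15L, nrow(sched)))
  expect_true(all(ts$spikes$spike_time_s >= 0 &
                    ts$spikes$spike_time_s <= ts$epoch_end))
  ts2 <- generate_experiment(nr, sched, n_trials = 15, seed = 77)
  expect_identical(ts$spikes, ts2$spikes)
  # schedules without a blank are refused
  expect_error(generate_experiment(nr, sched[sched$direction != "blank", ],
                                   n_trials = 5),
               class = "lgnsnr_missing_baseline")
})
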