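test_that("the F1 projection is the complex sum over spikes in the window", {
  w <- counting_window(0, 1)
  tk <- c(0.1, 0.25, 0.8)
  expect_equal(f1_projection(tk, w, 3), sum(exp(-2i * pi * 3 * tk)))
  # spikes outside [start, end) are excluded; empty train gives 0 + 0i
  expect_equal(f1_projection(c(-0.1, 1.0, 1.5), w, 3), 0 + 0i)
  expect_equal(f1_projection(numeric(0), w, 3), 0 + 0i)
  # half-open convention: a spike exactly at the end is excluded
  expect_equal(f1_projection(c(0, 1), w, 2), exp(-2i * pi * 2 * 0))
})

test_that("|F1| is invariant to a common time translation of spikes and window", {
  set.seed(5)
  tk <- sort(runif(40, 0, 1))
  f <- 4
  m0 <- Mod(f1_projection(tk, counting_window(0, 1), f))
  for (shift in c(0.3, 1.7)) {
    m1 <- Mod(f1_projection(tk + shift,
                            counting_window(shift, 1 + shift), f))
    expect_equal(m1, m0, tolerance = 1e-10)
  }
})

test_that("d-prime vanishes when the stimulus carries no modulation", {
  set.seed(21)
  stim <- oracle_trains(400, 30, 0, 5, 1)    # unmodulated "stimulus"
  blank <- oracle_trains(400, 30, 0, 5, 1)
  ts <- trains_to_trial_set(stim, blank, 5, 1)
  expect_lt(abs(dprime_f1(ts, "c01")$dprime), 0.3)
})

test_that("degenerate and error cases of the d-prime estimator are classed", {
  sched <- make_test_schedule("L_plus_M", 5, 0.1, duration = 1, ramp = 0)
  trials <- data.frame(trial_id = c("a", "b", "x", "y"),
                       condition_id = c("c01", "c01", "c02", "c02"))
  spikes <- data.frame(trial_id = c("a", "b"), condition_id = "c01",
                       spike_time_s = 0.2)   # identical one-spike trials
  ts <- trial_set(trials, spikes, sched, stim_off = 1, epoch_end = 1)
  expect_error(dprime_f1(ts, "nope"), class = "lgnsnr_invalid_parameter")
  expect_error(dprime_f1(ts, "c02"), class = "lgnsnr_invalid_parameter")
  # zero pooled variance with different means: degenerate +/- Inf flagged
  est <- dprime_f1(ts, "c01")
  expect_true(est$degenerate)
  expect_identical(est$dprime, Inf)
  # no blank in the condition table is refused at construction
  sched_nb <- sched[sched$direction != "blank", ]
  expect_error(trial_set(trials[1:2, ], spikes, sched_nb, stim_off = 1),
               class = "lgnsnr_missing_baseline")
})

test_that("the bootstrap SE tracks the empirical sampling SD of d-prime", {
  r0 <- 25; m <- 0.4; f <- 5; T <- 1; n <- 60
  set.seed(31)
  ds <- ses <- numeric(40)
  for (i in 1:40) {
    ts <- trains_to_trial_set(oracle_trains(n, r0, m, f, T),
                              oracle_trains(n, r0, 0, f, T), f, T)
    est <- dprime_f1(ts, "c01", B = 400, seed = i)
    ds[i] <- est$dprime; ses[i] <- est$se
  }
  expect_lt(abs(mean(ses) - sd(ds)) / sd(ds), 0.25)
})

test_that("the window sweep matches the point estimator and flags impossible windows", {
  set.seed(41)
  ts <- trains_to_trial_set(oracle_trains(80, 30, 0.6, 5, 1),
                            oracle_trains(80, 30, 0, 5, 1), 5, 1)
  sw <- window_sweep(ts, "c01", start_offsets = c(0, 0.1),
                     end_offsets = c(-1.05, 0), criterion = 1.27)
  expect_s3_class(sw, "window_sweep")
  # zero offsets reproduce the default-window estimate exactly
  expect_equal(sw$dprime["0", "0"], dprime_f1(ts, "c01")$dprime)
  # start >= end is NA, not an error, and never above criterion
  expect_true(is.na(sw$dprime["0.1", "-1.05"]))
  expect_false(sw$above_criterion["0.1", "-1.05"])
  expect_identical(sw$above_criterion, !is.na(sw$dprime) &
                     sw$dprime >= 1.27)
})

test_that("the spike-triggered average recovers a known temporal kernel", {
  set.seed(51)
  nf <- 40000
  kern <- dgamma(seq(0, 9), shape = 3, scale = 1.5)  # known filter, lag 0..9
  x <- rnorm(nf)
  lin <- as.numeric(stats::filter(x, kern, sides = 1))
  lin[is.na(lin)] <- 0
  counts <- rpois(nf, pmax(0, 4 + 6 * lin))
  sta <- spike_triggered_average(x, counts, n_lags = 10)
  expect_equal(which.max(sta[, 1]), which.max(kern))
  expect_gt(cor(sta[, 1], kern), 0.9)
  expect_error(spike_triggered_average(x, integer(nf), 5),
               class = "lgnsnr_undefined_sta")
})
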