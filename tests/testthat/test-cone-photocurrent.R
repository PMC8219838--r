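test_that("the cone impulse response is biphasic with the configured DC gain", {
  model <- cone_mosaic_model()
  dt <- 1e-4
  k <- cone_impulse_response(model, dt)
  expect_equal(k[1], 0)                    # zero at t = 0
  expect_gt(max(k), 0)
  expect_lt(min(k), 0)                     # undershoot
  expect_lt(which.max(k), which.min(k))    # positive lobe leads
  # net integral equals the configured gain (unit-DC normalization)
  expect_equal(sum(k) * dt, model$kernel$gain, tolerance = 1e-3)
  # too-short support is a classed truncation error
  slow <- cone_mosaic_model(kernel = list(g1 = 1, tau1 = 0.2, n1 = 4,
                                          g2 = 0.25, tau2 = 0.3, n2 = 4,
                                          gain = 30))
  expect_error(cone_impulse_response(slow, 1e-3, length = 0.3),
               class = "lgnsnr_truncation_error")
})

test_that("the synthesized noise reproduces the Lorentzian power spectrum", {
  model <- cone_mosaic_model()
  dt <- 0.002
  n <- 2048
  set.seed(61)
  nseg <- 300
  acc <- 0
  for (i in 1:nseg) {
    x <- simulate_cone_current(numeric(n), model, dt)$current
    acc <- acc + Mod(fft(x))^2 * dt / n    # two-sided periodogram
  }
  pgram <- acc / nseg
  f <- (0:(n / 2)) / (n * dt)
  # PSD check at low / corner / high frequency (nearest DFT bins)
  idx <- vapply(c(5, 25, 100), function(ff) which.min(abs(f - ff)),
                integer(1))
  expect_equal(2 * pgram[idx],               # one-sided = 2 x two-sided
               cone_noise_psd(model, f[idx]), tolerance = 0.1)
  # noise-free trace is deterministic and flagged
  quiet <- simulate_cone_current(c(numeric(50), rep(1, 50)), model, 1e-3,
                                 noise = FALSE)
  expect_true(quiet$is_noise_free)
  expect_true(quiet$metadata$light_level_extrapolated)  # 8000 R*/s > calib
  expect_equal(quiet$current[1:50], numeric(50))        # causal
})

test_that("the cone-array d-prime respects blanks, eccentricity and the SNR-gap flags", {
  model <- cone_mosaic_model()
  expect_identical(cone_array_dprime(stimulus_spec("blank"), model), 0)
  d5 <- cone_array_dprime(stimulus_spec("L_plus_M", 5, 0.1,
                                        eccentricity = 5), model)
  d15 <- cone_array_dprime(stimulus_spec("L_plus_M", 5, 0.1,
                                         eccentricity = 15), model)
  expect_gt(d5, d15)   # fewer cones at larger eccentricity
  # chromatic and luminance stimuli of equal contrast drive each cone with
  # equal signal magnitude, so the array d' is identical
  dchr <- cone_array_dprime(stimulus_spec("L_minus_M", 5, 0.1), model)
  expect_equal(dchr, d5)
  g <- snr_gap(10, 2)
  expect_equal(g$fraction, 0.2)
  expect_false(g$unphysical || g$undefined)
  expect_true(snr_gap(1, 2)$unphysical)
  expect_true(snr_gap(0, 0)$undefined)
  expect_true(is.na(snr_gap(0, 0)$fraction))
})
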