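test_that("the TCSF is the magnitude of a difference of cascaded low-pass filters", {
  m <- tcsf_model()
  p <- m$L_plus_M
  f <- 7
  w <- 2i * pi * f
  hand <- Mod(p$xi1 * (w * p$tau1 + 1)^(-p$n1) -
              p$xi2 * (w * p$tau2 + 1)^(-p$n2))
  expect_equal(tcsf_sensitivity(m, "L_plus_M", f), hand)
})

test_that("chromatic sensitivity dominates at low frequency and luminance at high frequency", {
  m <- tcsf_model()
  expect_gt(tcsf_sensitivity(m, "L_minus_M", 1),
            tcsf_sensitivity(m, "L_plus_M", 1))
  expect_gt(tcsf_sensitivity(m, "L_plus_M", 20),
            tcsf_sensitivity(m, "L_minus_M", 20))
  # luminance channel is bandpass: interior peak between 2 and 20 Hz
  fs <- seq(0.5, 40, by = 0.5)
  s <- tcsf_sensitivity(m, "L_plus_M", fs)
  f_peak <- fs[which.max(s)]
  expect_gt(f_peak, 2)
  expect_lt(f_peak, 20)
  # sensitivity declines with eccentricity
  expect_gt(tcsf_sensitivity(m, "L_plus_M", 5, eccentricity = 5),
            tcsf_sensitivity(m, "L_plus_M", 5, eccentricity = 15))
})

test_that("threshold contrast inverts sensitivity and clips at the display gamut", {
  m <- tcsf_model()
  th <- threshold_contrast(m, "L_plus_M", 10)
  expect_false(th$clipped)
  expect_equal(th$contrast, 1 / tcsf_sensitivity(m, "L_plus_M", 10))
  # chromatic threshold at 20 Hz exceeds the 0.19 gamut cap
  th2 <- threshold_contrast(m, "L_minus_M", 20)
  expect_true(th2$clipped)
  expect_equal(th2$contrast, gamut_cap("L_minus_M"))
})

test_that("the trapezoidal envelope ramps linearly and integrates to duration minus ramp", {
  env <- make_envelope(0.666, 0.166, dt = 1e-4)
  expect_equal(range(env$gain), c(0, 1))
  plateau <- env$sample_times >= 0.166 & env$sample_times <= 0.5
  expect_true(all(env$gain[plateau] == 1))
  # mid-ramp value is exactly half
  expect_equal(env$gain[which.min(abs(env$sample_times - 0.083))], 0.5,
               tolerance = 1e-3)
  # trapezoid area = duration - ramp
  expect_equal(sum(env$gain) * 1e-4, 0.666 - 0.166, tolerance = 1e-3)
  # zero ramp degenerates to a rectangle with zero endpoints
  env0 <- make_envelope(0.5, 0, dt = 1e-3)
  expect_equal(env0$gain[1], 0)
  expect_true(all(env0$gain[2:(length(env0$gain) - 1)] == 1))
  expect_error(make_envelope(0.3, 0.2, 1e-3),
               class = "lgnsnr_invalid_envelope")
})

test_that("cone contrasts are in phase for luminance and counterphase for chromatic stimuli", {
  lum <- cone_contrast_waveforms(stimulus_spec("L_plus_M", 5, 0.2), 0.001)
  chr <- cone_contrast_waveforms(stimulus_spec("L_minus_M", 5, 0.1), 0.001)
  expect_identical(lum$c_L, lum$c_M)
  expect_identical(chr$c_L, -chr$c_M)
  expect_lte(max(abs(lum$c_L)), 0.2)
  blank <- cone_contrast_waveforms(stimulus_spec("blank"), 0.001)
  expect_true(all(blank$c_L == 0) && all(blank$c_M == 0))
  expect_error(stimulus_spec("L_minus_M", 5, 0.5),
               class = "lgnsnr_gamut_error")
  expect_error(stimulus_spec("L_plus_M", -2, 0.1),
               class = "lgnsnr_invalid_stimulus")
})

test_that("the stimulus schedule is a threshold-contrast factorial plus one blank", {
  m <- tcsf_model()
  sch <- stimulus_schedule(m)
  expect_s3_class(sch, "stimulus_schedule")
  expect_equal(nrow(sch), 11)
  expect_equal(sum(sch$direction == "blank"), 1)
  expect_false(anyDuplicated(sch$condition_id) > 0)
  i <- which(sch$direction == "L_plus_M" & sch$frequency_hz == 5)
  expect_equal(sch$contrast[i], threshold_contrast(m, "L_plus_M", 5)$contrast)
  # round trip through the delimited format
  p <- tempfile(fileext = ".tsv")
  write_schedule(sch, p)
  sch2 <- read_schedule(p)
  expect_equal(as.data.frame(sch2), as.data.frame(sch), tolerance = 1e-12)
})
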