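test_that("the effective neuron count is density times the squared-envelope integral", {
  pm <- population_model()
  spec <- stimulus_spec("L_plus_M", 5, 0.1, aperture_sigma = 0.4)
  # oracle: 2-D quadrature of the squared Gaussian contrast envelope
  sigma <- spec$aperture_sigma
  r <- seq(0, 6 * sigma, by = 1e-4)
  area <- sum(exp(-r^2 / sigma^2) * 2 * pi * r) * 1e-4
  expect_equal(effective_neuron_count(pm, spec, "magno"),
               rf_density(pm, "magno", spec$eccentricity) * area,
               tolerance = 1e-6)
  # parvo outnumber magno by d0 ratio at matched eccentricity
  expect_equal(effective_neuron_count(pm, spec, "parvo") /
                 effective_neuron_count(pm, spec, "magno"), 44 / 10)
  expect_error(effective_neuron_count(pm, spec, "konio"),
               class = "lgnsnr_invalid_parameter")
})

test_that("RF density declines log-linearly with eccentricity", {
  pm <- population_model()
  expect_equal(rf_density(pm, "magno", 5), 10)
  expect_equal(rf_density(pm, "magno", 15) / rf_density(pm, "magno", 5),
               10^(-0.03 * 10))
})

test_that("population pooling validates its inputs and reports its scale factor", {
  out <- population_dprime(0.5, 25, 0)
  expect_equal(out$dprime_pop, 0.5 * 5)
  expect_equal(out$scale_factor, 5)
  expect_error(population_dprime(Inf, 10, 0.1),
               class = "lgnsnr_invalid_parameter")
  expect_error(population_dprime(1, 0.5, 0.1),
               class = "lgnsnr_invalid_parameter")
  expect_error(population_dprime(1, 10, 1),
               class = "lgnsnr_invalid_parameter")
  expect_error(population_model(magno = list(d0 = 10, slope = 0, rho = -0.1)),
               class = "lgnsnr_invalid_parameter")
})
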