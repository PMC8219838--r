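# Population SNR: single-neuron d' is inflated by the number of neurons the
# stimulus modulates, discounted for correlated noise. Pooling N equally
# sensitive channels with pairwise noise correlation rho multiplies d' by
# k = sqrt(N / (1 + (N - 1) rho)), the closed form for an equicorrelated
# Gaussian population. Magno and parvo populations are pooled separately;
# there is deliberately no cross-class correlation parameter.

#' LGN population model
#'
#' Per cell class, receptive-field density declines log-linearly with
#' eccentricity: `density(e) = d0 * 10^(-slope * (e - ecc_ref))` in
#' neurons/deg^2. Pairwise noise correlation `rho` applies within a class
#' only. Defaults are calibrated so that at matched eccentricity the parvo
#' effective count is about 4.4x the magno count, making the parvo:magno
#' population scale-factor ratio approximately 2.1.
#'
#' @param magno,parvo lists with `d0` (neurons/deg^2 at `ecc_ref`), `slope`
#'   (log10 units per degree) and `rho` (within-class pairwise noise
#'   correlation, `0 <= rho < 1`).
#' @param ecc_ref reference eccentricity, degrees.
#' @return object of class `population_model`.
#' @export
population_model <- function(
    magno = list(d0 = 10, slope = 0.03, rho = 0.002),
    parvo = list(d0 = 44, slope = 0.03, rho = 0.002),
    ecc_ref = 5) {
  for (cl in list(magno, parvo))
    if (cl$rho < 0 || cl$rho >= 1)
      stop_lgnsnr("rho must satisfy 0 <= rho < 1", "lgnsnr_invalid_parameter")
  structure(list(magno = magno, parvo = parvo, ecc_ref = ecc_ref),
            class = "population_model")
}

#' RF density of a cell class at an eccentricity
#' @param model a [population_model()].
#' @param cell_class `"magno"` or `"parvo"`.
#' @param eccentricity degrees.
#' @return neurons per square degree.
#' @export
rf_density <- function(model, cell_class, eccentricity) {
  cell_class <- match.arg(cell_class, c("magno", "parvo"))
  p <- model[[cell_class]]
  p$d0 * 10^(-p$slope * (eccentricity - model$ecc_ref))
}

#' Effective number of neurons modulated by a Gabor stimulus
#'
#' Energy-weighted count: RF density at the stimulus eccentricity times the
#' spatial integral of the squared Gaussian contrast envelope,
#' `2 * pi * (aperture_sigma / sqrt(2))^2 = pi * aperture_sigma^2`. Squared
#' weighting makes pooled d'^2 additive across neurons that see reduced
#' contrast near the Gabor fringe.
#'
#' @param model a [population_model()].
#' @param spec a [stimulus_spec()].
#' @param cell_class `"magno"` or `"parvo"`.
#' @return scalar effective neuron count (nonnegative).
#' @export
effective_neuron_count <- function(model, spec, cell_class) {
  if (!cell_class %in% c("magno", "parvo"))
    stop_lgnsnr(sprintf("unknown cell class '%s'", cell_class),
                "lgnsnr_invalid_parameter")
  dens <- rf_density(model, cell_class, spec$eccentricity)
  dens * 2 * pi * (spec$aperture_sigma / sqrt(2))^2
}

#' Population d' from single-neuron d' under equicorrelated pooling
#'
#' @param d_single single-neuron d' (finite).
#' @param N_eff effective neuron count (`>= 1`).
#' @param rho pairwise noise correlation, `0 <= rho < 1`.
#' @return list with `dprime_pop`, `scale_factor` (k), `N_eff`, `rho`.
#' @export
population_dprime <- function(d_single, N_eff, rho) {
  if (!is.finite(d_single))
    stop_lgnsnr("d_single must be finite", "lgnsnr_invalid_parameter")
  if (N_eff < 1)
    stop_lgnsnr("N_eff must be >= 1", "lgnsnr_invalid_parameter")
  if (rho < 0 || rho >= 1)
    stop_lgnsnr("rho must satisfy 0 <= rho < 1", "lgnsnr_invalid_parameter")
  k <- sqrt(N_eff / (1 + (N_eff - 1) * rho))
  list(dprime_pop = k * d_single, scale_factor = k, N_eff = N_eff, rho = rho)
}
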