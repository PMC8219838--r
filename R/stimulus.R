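# Stimuli in cone-contrast space: drifting Gabors whose L and M cone
# contrasts are equal in magnitude and either in phase (L+M, luminance) or
# in counterphase (L-M, chromatic), with a trapezoidal contrast envelope.

#' Display gamut cap on cone contrast for a color direction
#'
#' Maximum fractional cone contrast the display can produce: 0.19 for L-M
#' and 0.86 for L+M. Blanks have no contrast so their cap is 0.
#'
#' @param direction one of `"L_plus_M"`, `"L_minus_M"`, `"blank"`.
#' @return scalar contrast cap.
#' @export
gamut_cap <- function(direction) {
  direction <- match.arg(direction, c("L_plus_M", "L_minus_M", "blank"))
  switch(direction, L_plus_M = 0.86, L_minus_M = 0.19, blank = 0)
}

#' Construct a stimulus specification
#'
#' One condition of the detection experiment: a drifting Gabor defined by
#' color direction, temporal frequency, cone contrast, duration, contrast
#' ramp and retinal location.
#'
#' @param direction `"L_plus_M"`, `"L_minus_M"` or `"blank"`.
#' @param temporal_frequency drift frequency in Hz (`NA` for blank).
#' @param cone_contrast fractional cone contrast, identical for L and M
#'   cones; must respect the direction's [gamut_cap()].
#' @param duration stimulus duration in seconds.
#' @param ramp duration of the linear contrast ramps at onset and offset,
#'   seconds; `2 * ramp <= duration`.
#' @param eccentricity receptive-field eccentricity, degrees of visual angle.
#' @param aperture_sigma SD of the Gaussian spatial envelope of the Gabor,
#'   degrees.
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(direction, temporal_frequency = NA_real_,
                          cone_contrast = 0, duration = 0.666, ramp = 0.166,
                          eccentricity = 5, aperture_sigma = 0.4) {
  direction <- match.arg(direction, c("L_plus_M", "L_minus_M", "blank"))
  if (direction != "blank") {
    if (!is.finite(temporal_frequency) || temporal_frequency <= 0)
      stop_lgnsnr("temporal_frequency must be > 0 for non-blank stimuli",
                  "lgnsnr_invalid_stimulus")
    if (cone_contrast < 0 || cone_contrast > gamut_cap(direction))
      stop_lgnsnr(sprintf(
        "cone contrast %.3f outside display gamut for %s (cap %.2f)",
        cone_contrast, direction, gamut_cap(direction)), "lgnsnr_gamut_error")
  } else {
    cone_contrast <- 0
  }
  if (2 * ramp > duration)
    stop_lgnsnr("2*ramp exceeds stimulus duration", "lgnsnr_invalid_envelope")
  structure(list(direction = direction,
                 temporal_frequency = temporal_frequency,
                 cone_contrast = cone_contrast,
                 duration = duration, ramp = ramp,
                 eccentricity = eccentricity,
                 aperture_sigma = aperture_sigma),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> %s, %s Hz, contrast %.4g, %.3f s (ramp %.3f s), ecc %.1f deg\n",
              x$direction,
              if (is.na(x$temporal_frequency)) "-" else format(x$temporal_frequency),
              x$cone_contrast, x$duration, x$ramp, x$eccentricity))
  invisible(x)
}

#' Trapezoidal temporal contrast envelope
#'
#' Contrast gain rises linearly from 0 to 1 over `[0, ramp]`, holds at 1 on
#' the plateau, and falls linearly back to 0 over
#' `[duration - ramp, duration]`.
#'
#' @param duration stimulus duration, seconds.
#' @param ramp ramp duration, seconds (166 ms in the default stimulus).
#' @param dt sample interval, seconds.
#' @return a `temporal_envelope`: list with `sample_times` and `gain`.
#' @export
make_envelope <- function(duration, ramp, dt) {
  if (dt <= 0) stop_lgnsnr("dt must be > 0", "lgnsnr_invalid_envelope")
  if (2 * ramp > duration)
    stop_lgnsnr("2*ramp exceeds duration", "lgnsnr_invalid_envelope")
  t <- seq(0, duration, by = dt)
  if (ramp > 0) {
    gain <- pmin(1, pmin(t / ramp, (duration - t) / ramp))
    gain <- pmax(0, gain)
  } else {
    gain <- as.numeric(t > 0 & t < duration)
  }
  structure(list(sample_times = t, gain = gain), class = "temporal_envelope")
}

#' Cone-contrast waveforms of a stimulus
#'
#' L and M cone contrast time courses: a sinusoid at the stimulus temporal
#' frequency under the trapezoidal envelope. L and M are modulated in phase
#' for L+M and in counterphase for L-M; blanks give zero contrast.
#'
#' @param spec a [stimulus_spec()].
#' @param dt sample interval, seconds.
#' @return list with `sample_times`, `c_L`, `c_M`.
#' @export
cone_contrast_waveforms <- function(spec, dt) {
  stopifnot(inherits(spec, "stimulus_spec"))
  env <- make_envelope(spec$duration, spec$ramp, dt)
  if (spec$direction == "blank") {
    z <- numeric(length(env$sample_times))
    return(list(sample_times = env$sample_times, c_L = z, c_M = z))
  }
  if (spec$cone_contrast > gamut_cap(spec$direction))
    stop_lgnsnr("contrast exceeds gamut cap", "lgnsnr_gamut_error")
  c_L <- spec$cone_contrast * env$gain *
    sin(2 * pi * spec$temporal_frequency * env$sample_times)
  c_M <- if (spec$direction == "L_plus_M") c_L else -c_L
  list(sample_times = env$sample_times, c_L = c_L, c_M = c_M)
}
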