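# Behavioral temporal contrast sensitivity model. Sensitivity in each color
# direction is the magnitude of a difference of two cascaded first-order
# low-pass filters,
#
#   S(f) = | xi1 (i 2 pi f tau1 + 1)^(-n1) - xi2 (i 2 pi f tau2 + 1)^(-n2) |
#
# the standard psychophysical filter family for temporal sensitivity.
# Defaults reproduce the canonical ordering: chromatic (L-M) sensitivity
# exceeds luminance (L+M) sensitivity at 1 Hz, the reverse holds at 20 Hz,
# and the luminance function is bandpass with a peak near 10 Hz.

#' Temporal contrast sensitivity function (TCSF) model
#'
#' Per color direction, a difference of two cascaded low-pass filters with
#' gains `xi1`, `xi2`, time constants `tau1`, `tau2` (seconds) and stage
#' counts `n1`, `n2`, plus a multiplicative log-linear attenuation of
#' sensitivity with eccentricity.
#'
#' @param L_plus_M,L_minus_M named lists with elements `xi1, tau1, n1, xi2,
#'   tau2, n2` for the luminance and chromatic directions.
#' @param ecc_slope attenuation slope, log10 sensitivity units per degree.
#' @param ecc_ref reference eccentricity in degrees at which attenuation is 1.
#' @return object of class `tcsf_model`.
#' @export
tcsf_model <- function(
    L_plus_M  = list(xi1 = 40, tau1 = 0.005, n1 = 3,
                     xi2 = 38, tau2 = 0.010, n2 = 5),
    L_minus_M = list(xi1 = 90, tau1 = 0.025, n1 = 4,
                     xi2 = 20, tau2 = 0.050, n2 = 5),
    ecc_slope = 0.025, ecc_ref = 5) {
  structure(list(L_plus_M = L_plus_M, L_minus_M = L_minus_M,
                 ecc_slope = ecc_slope, ecc_ref = ecc_ref),
            class = "tcsf_model")
}

#' Behavioral contrast sensitivity at a temporal frequency
#'
#' @param model a [tcsf_model()].
#' @param direction `"L_plus_M"` or `"L_minus_M"`.
#' @param frequency temporal frequency, Hz (vectorized).
#' @param eccentricity degrees of visual angle.
#' @return sensitivity (1 / threshold contrast), same length as `frequency`.
#' @export
tcsf_sensitivity <- function(model, direction, frequency,
                             eccentricity = model$ecc_ref) {
  stopifnot(inherits(model, "tcsf_model"))
  direction <- match.arg(direction, c("L_plus_M", "L_minus_M"))
  p <- model[[direction]]
  w <- 2i * pi * frequency
  s <- Mod(p$xi1 * (w * p$tau1 + 1)^(-p$n1) -
           p$xi2 * (w * p$tau2 + 1)^(-p$n2))
  s * 10^(-model$ecc_slope * (eccentricity - model$ecc_ref))
}

#' Threshold cone contrast for a stimulus condition
#'
#' Inverse of [tcsf_sensitivity()], clipped at the direction's display gamut
#' cap. Clipping is a valid, flagged outcome (the recordings used
#' display-limited maximum contrasts at frequencies where threshold exceeded
#' the gamut).
#'
#' @inheritParams tcsf_sensitivity
#' @return list with `contrast` (scalar) and `clipped` (logical).
#' @export
threshold_contrast <- function(model, direction, frequency,
                               eccentricity = model$ecc_ref) {
  sens <- tcsf_sensitivity(model, direction, frequency, eccentricity)
  contrast <- 1 / sens
  cap <- gamut_cap(direction)
  clipped <- contrast > cap
  list(contrast = if (clipped) cap else contrast, clipped = clipped)
}

#' Convert 2AFC percent correct to d' and back
#'
#' Ideal-observer mapping for two-alternative forced choice:
#' `pc = pnorm(dprime / sqrt(2))`. The monkeys' 82% correct at threshold
#' corresponds to d' of about 1.27 under this convention.
#'
#' @param pc proportion correct, in (0.5, 1).
#' @return `pc_to_dprime`: the d' whose 2AFC percent correct is `pc`.
#' @export
pc_to_dprime <- function(pc) {
  if (any(pc <= 0.5 | pc >= 1))
    stop_lgnsnr("pc must lie strictly between 0.5 and 1",
                "lgnsnr_domain_error")
  sqrt(2) * qnorm(pc)
}

#' @rdname pc_to_dprime
#' @param dprime discriminability index, `>= 0`.
#' @return `dprime_to_pc`: 2AFC proportion correct in `[0.5, 1)`.
#' @export
dprime_to_pc <- function(dprime) {
  if (any(dprime < 0))
    stop_lgnsnr("dprime must be >= 0", "lgnsnr_domain_error")
  pnorm(dprime / sqrt(2))
}

#' Build a stimulus schedule at behavioral threshold
#'
#' Full factorial of color directions and temporal frequencies with contrast
#' set to behavioral detection threshold (gamut-clipped where necessary),
#' plus one blank condition for baseline firing statistics.
#'
#' @param model a [tcsf_model()].
#' @param frequencies vector of temporal frequencies, Hz.
#' @param directions character vector of non-blank color directions.
#' @param eccentricity degrees.
#' @param duration,ramp,aperture_sigma passed to [stimulus_spec()].
#' @return data.frame with columns `condition_id, direction, frequency_hz,
#'   contrast, duration_s, ramp_s, clipped` (class `stimulus_schedule`).
#' @export
stimulus_schedule <- function(model, frequencies = c(1, 2, 5, 10, 20),
                              directions = c("L_plus_M", "L_minus_M"),
                              eccentricity = 5, duration = 0.666,
                              ramp = 0.166, aperture_sigma = 0.4) {
  rows <- list()
  for (dir in directions) for (f in frequencies) {
    th <- threshold_contrast(model, dir, f, eccentricity)
    rows[[length(rows) + 1L]] <- data.frame(
      direction = dir, frequency_hz = f, contrast = th$contrast,
      clipped = th$clipped)
  }
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(direction = "blank", frequency_hz = NA_real_,
                               contrast = 0, clipped = FALSE))
  out <- data.frame(condition_id = sprintf("c%02d", seq_len(nrow(out))), out)
  out$duration_s <- duration
  out$ramp_s <- ramp
  out$eccentricity_deg <- eccentricity
  out$aperture_sigma_deg <- aperture_sigma
  out <- out[, c("condition_id", "direction", "frequency_hz", "contrast",
                 "duration_s", "ramp_s", "eccentricity_deg",
                 "aperture_sigma_deg", "clipped")]
  class(out) <- c("stimulus_schedule", "data.frame")
  out
}

#' Convert a schedule row to a stimulus_spec
#' @param schedule a [stimulus_schedule()].
#' @param condition_id condition identifier.
#' @return a [stimulus_spec()].
#' @export
schedule_spec <- function(schedule, condition_id) {
  row <- schedule[schedule$condition_id == condition_id, , drop = FALSE]
  if (nrow(row) != 1L)
    stop_lgnsnr(sprintf("condition '%s' not found in schedule", condition_id),
                "lgnsnr_invalid_parameter")
  stimulus_spec(row$direction, row$frequency_hz, row$contrast,
                row$duration_s, row$ramp_s, row$eccentricity_deg,
                row$aperture_sigma_deg)
}

#' Write / read a stimulus schedule as tab-delimited text
#' @param schedule a [stimulus_schedule()].
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  write.table(as.data.frame(schedule), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("stimulus_schedule", "data.frame")
  out
}
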