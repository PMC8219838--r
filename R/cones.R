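# Cone outer-segment photocurrent simulation and the matched-filter bound.
# The photocurrent is modelled as a linear temporal filter (difference of two
# gamma kernels, biphasic) applied to the cone-contrast waveform, plus
# additive stationary Gaussian noise whose one-sided power spectral density
# is a sum of two Lorentzians. Noise is approximated as independent of the
# signal and independent across cones. The matched-filter SNR of this model
# upper-bounds the d' of any decoder of the noisy currents.

#' Cone mosaic and photocurrent model
#'
#' @param density list with `d0` (cones/deg^2 at `ecc_ref`) and `slope`
#'   (log10 decline per degree of eccentricity).
#' @param lm_ratio L:M cone ratio (does not affect d' because L and M cone
#'   contrasts have equal magnitude for both stimulus classes; kept for
#'   completeness of the mosaic description).
#' @param kernel impulse-response parameters: difference of two gamma
#'   filters with gains `g1`, `g2`, time constants `tau1`, `tau2` (s) and
#'   stage counts `n1`, `n2` (each `>= 2` so the kernel is zero at t = 0),
#'   scaled by `gain` (current units per unit contrast at DC) after
#'   normalizing the positive-minus-negative lobe integral to 1.
#' @param psd noise power spectral density (one-sided, current units^2/Hz):
#'   sum of two Lorentzians with amplitudes `A1`, `A2` and corner
#'   frequencies `fc1`, `fc2` (Hz).
#' @param mean_light mean light level, photoisomerizations/s, at which the
#'   model is applied.
#' @param calib_light range of light levels (R*/s) at which the underlying
#'   photocurrent measurements were made; an applied level outside this
#'   range is recorded as a calibration mismatch in output metadata.
#' @param light_exponent power with which kernel time constants scale with
#'   `mean_light / mean(calib_light)`; the default 0 applies no
#'   extrapolation correction.
#' @param ecc_ref reference eccentricity, degrees.
#' @return object of class `cone_mosaic_model`.
#' @export
cone_mosaic_model <- function(
    density = list(d0 = 1500, slope = 0.04),
    lm_ratio = 2,
    kernel = list(g1 = 1, tau1 = 0.012, n1 = 4,
                  g2 = 0.25, tau2 = 0.018, n2 = 4, gain = 30),
    psd = list(A1 = 3e-3, fc1 = 30, A2 = 3e-4, fc2 = 180),
    mean_light = 8000, calib_light = c(4000, 6500),
    light_exponent = 0, ecc_ref = 5) {
  stopifnot(kernel$n1 >= 2, kernel$n2 >= 2, mean_light > 0,
            psd$A1 > 0 || psd$A2 > 0)
  structure(list(density = density, lm_ratio = lm_ratio, kernel = kernel,
                 psd = psd, mean_light = mean_light,
                 calib_light = calib_light,
                 light_exponent = light_exponent, ecc_ref = ecc_ref),
            class = "cone_mosaic_model")
}

# effective time constants after light-level scaling
cone_taus <- function(model) {
  scale <- (model$mean_light / mean(model$calib_light))^
    (-model$light_exponent)
  c(tau1 = model$kernel$tau1 * scale, tau2 = model$kernel$tau2 * scale)
}

cone_kernel_raw <- function(model, t) {
  k <- model$kernel
  taus <- cone_taus(model)
  k$g1 * (t / taus[["tau1"]])^(k$n1 - 1) * exp(-t / taus[["tau1"]]) -
    k$g2 * (t / taus[["tau2"]])^(k$n2 - 1) * exp(-t / taus[["tau2"]])
}

#' Cone photocurrent impulse response
#'
#' Biphasic kernel (positive lobe then undershoot), zero at t = 0, sampled
#' on `seq(0, length, dt)`. The kernel is normalized so that its net time
#' integral is `kernel$gain / 1` in current units per unit contrast.
#'
#' @param model a [cone_mosaic_model()].
#' @param dt sample interval, seconds.
#' @param length kernel support to return, seconds; must contain at least
#'   99% of the kernel energy or a truncation error is raised.
#' @return numeric kernel vector with attribute `sample_times`.
#' @export
cone_impulse_response <- function(model, dt, length = 0.3) {
  stopifnot(dt > 0)
  t <- seq(0, length, by = dt)
  k <- cone_kernel_raw(model, t)
  # energy check against a much longer dense evaluation
  t_full <- seq(0, 5 * length, by = dt)
  k_full <- cone_kernel_raw(model, t_full)
  if (sum(k^2) < 0.99 * sum(k_full^2))
    stop_lgnsnr("kernel support too short: < 99% of kernel energy captured",
                "lgnsnr_truncation_error")
  # unit net integral, then overall gain
  kk <- model$kernel
  taus <- cone_taus(model)
  net <- kk$g1 * taus[["tau1"]] * gamma(kk$n1) -
    kk$g2 * taus[["tau2"]] * gamma(kk$n2)
  k <- k / net * kk$gain
  attr(k, "sample_times") <- t
  k
}

#' One-sided noise power spectral density of the cone current
#'
#' @param model a [cone_mosaic_model()].
#' @param f frequency, Hz (vectorized, `>= 0`).
#' @return PSD in current units^2 / Hz.
#' @export
cone_noise_psd <- function(model, f) {
  p <- model$psd
  p$A1 / (1 + (f / p$fc1)^2) + p$A2 / (1 + (f / p$fc2)^2)
}

# stationary Gaussian noise with the model's one-sided PSD, by spectral
# synthesis with hermitian-symmetric Fourier coefficients
sample_cone_noise <- function(n, dt, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  half <- floor(n / 2)
  f <- (0:half) / (n * dt)
  S1 <- cone_noise_psd(model, f)
  X <- complex(real = rep(0, half + 1), imaginary = rep(0, half + 1))
  X[1] <- sqrt(n * S1[1] / (2 * dt)) * rnorm(1)
  if (n %% 2 == 0) {
    mid <- 2:half
    X[half + 1] <- sqrt(n * S1[half + 1] / (2 * dt)) * rnorm(1)
  } else mid <- 2:(half + 1)
  a <- sqrt(n * S1[mid] / (4 * dt))
  X[mid] <- a * complex(real = rnorm(length(mid)),
                        imaginary = rnorm(length(mid)))
  full <- c(X, Conj(rev(X[mid])))
  Re(fft(full, inverse = TRUE)) / n
}

#' Simulate a cone photocurrent trace
#'
#' Linear response (impulse response convolved with the contrast waveform)
#' plus, optionally, additive stationary Gaussian noise with the configured
#' spectrum. Deterministic given `seed`.
#'
#' @param contrast uniformly sampled cone-contrast waveform.
#' @param model a [cone_mosaic_model()].
#' @param dt sample interval of `contrast`, seconds.
#' @param seed RNG seed for the noise.
#' @param noise logical; `FALSE` returns the noise-free trace.
#' @return object of class `cone_current_trace`: `sample_times`, `current`,
#'   `is_noise_free`, and `metadata` (light-level calibration note).
#' @export
simulate_cone_current <- function(contrast, model, dt, seed = NULL,
                                  noise = TRUE) {
  k <- cone_impulse_response(model, dt)
  sig <- filtered_signal(contrast, k, dt)
  cur <- if (noise) sig + sample_cone_noise(length(sig), dt, model, seed)
         else sig
  mismatch <- model$mean_light < model$calib_light[1] ||
    model$mean_light > model$calib_light[2]
  structure(list(
    sample_times = seq(0, by = dt, length.out = length(cur)),
    current = cur, is_noise_free = !noise,
    metadata = list(
      mean_light = model$mean_light, calib_light = model$calib_light,
      light_level_extrapolated = mismatch,
      light_exponent = model$light_exponent)),
    class = "cone_current_trace")
}

filtered_signal <- function(contrast, kernel, dt) {
  n <- length(contrast)
  out <- convolve(contrast, rev(kernel), type = "open") * dt
  out[seq_len(n)]
}

# discrete matched-filter SNR of one cone: d'^2 = sum_k |S_k|^2 / E|N_k|^2
# with E|N_k|^2 = n * S2(f_k) / dt, the DFT-domain noise power. This equals
# the continuous 2 * integral over all f of |S(f)|^2 / PSD_onesided(f).
cone_unit_dprime <- function(contrast, model, dt) {
  k <- cone_impulse_response(model, dt)
  # pad so the filtered response decays within the analysis window
  sig <- filtered_signal(c(contrast, numeric(length(k))), k, dt)
  n <- length(sig)
  fk <- (0:(n - 1)) / (n * dt)
  fk <- pmin(fk, 1 / dt - fk)                   # alias to [0, Nyquist]
  S2 <- cone_noise_psd(model, fk) / 2           # two-sided PSD
  Sk <- fft(sig)
  sqrt(sum(Mod(Sk)^2 / (n * S2 / dt)))
}

#' Matched-filter d' of the cone array for one stimulus
#'
#' Per cone, the ideal-observer (matched filter) SNR for detecting the
#' noise-free filtered contrast signal in the configured current noise:
#' `d_i'^2 = 2 * integral of |S_i(f)|^2 / PSD(f) df`. Cones under the Gabor
#' envelope see the contrast scaled by the local envelope, so with
#' independent noise the array d' is the single-cone d' times the square
#' root of the energy-weighted cone count (density times the integral of the
#' squared Gaussian envelope), exactly as in the LGN population model.
#'
#' @param spec a [stimulus_spec()].
#' @param model a [cone_mosaic_model()].
#' @param dt simulation time step, seconds.
#' @return scalar d' (0 for blanks).
#' @export
cone_array_dprime <- function(spec, model, dt = 0.001) {
  stopifnot(inherits(spec, "stimulus_spec"),
            inherits(model, "cone_mosaic_model"))
  if (spec$direction == "blank" || spec$cone_contrast == 0) return(0)
  wf <- cone_contrast_waveforms(spec, dt)
  # |c_L| = |c_M| for both L+M and L-M, so every cone sees the same
  # signal magnitude and the L:M ratio drops out
  d_unit <- cone_unit_dprime(wf$c_L, model, dt)
  dens <- model$density$d0 *
    10^(-model$density$slope * (spec$eccentricity - model$ecc_ref))
  n_cones <- dens * 2 * pi * (spec$aperture_sigma / sqrt(2))^2
  d_unit * sqrt(n_cones)
}

#' SNR gap between an upstream and a downstream stage
#'
#' @param d_upstream,d_downstream nonnegative d' values (e.g. cone array vs
#'   LGN population, or LGN population vs behavioral criterion).
#' @return list with `difference` (`d_upstream - d_downstream`, reported
#'   as-is and flagged `unphysical` when negative, since SNR cannot increase
#'   between the cones and the LGN), `fraction`
#'   (`d_downstream / d_upstream`; flagged `undefined` when the upstream d'
#'   is 0), and the two flags.
#' @export
snr_gap <- function(d_upstream, d_downstream) {
  stopifnot(d_upstream >= 0, d_downstream >= 0)
  diff <- d_upstream - d_downstream
  undefined <- d_upstream == 0
  list(difference = diff,
       fraction = if (undefined) NA_real_ else d_downstream / d_upstream,
       unphysical = diff < 0,
       undefined = undefined)
}
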