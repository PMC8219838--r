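---
title: "Cross-stage SNR: from cone currents through LGN spikes to behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-stage SNR: from cone currents through LGN spikes to behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgnsnr)
```

## The question

Visual detection at threshold can be limited anywhere between the
photoreceptors and the decision. This package quantifies each stage of a
near-threshold detection experiment with the same signal-detection currency,
the discriminability index

$$ d' = \frac{\mu_\text{stim} - \mu_\text{blank}}
             {\sqrt{(\sigma^2_\text{stim} + \sigma^2_\text{blank})/2}}, $$

and compares, condition by condition, the matched-filter bound of the cone
photocurrent array, the population d′ of magnocellular and parvocellular LGN
neurons, and the behavioral criterion. A stage that holds much more SNR than
the next stage uses marks a lossy transformation downstream of it.

## Stimuli and behavior

Stimuli are drifting Gabors in two cone-contrast directions: luminance
(L+M; equal-magnitude, in-phase L- and M-cone contrast) and chromatic
(L−M; counterphase), at temporal frequencies 1–20 Hz. Contrast follows a
trapezoidal envelope: 166 ms linear ramps flanking a plateau, 666 ms total
(`make_envelope()`). Spatially the Gabor is treated as uniform at the scale
of one receptive field; its Gaussian aperture (σ = 0.4°) enters only through
the *effective count* of units it stimulates (below).

Behavioral sensitivity per direction is a difference of two cascaded
first-order low-pass filters,

$$ S(f) = \left| \xi_1 (i 2\pi f \tau_1 + 1)^{-n_1}
               - \xi_2 (i 2\pi f \tau_2 + 1)^{-n_2} \right|, $$

the standard psychophysical TCSF family (`tcsf_model()`): subtracting a
slower cascade from a faster one yields low-pass behavior for small
$\tau$-separation and bandpass behavior for large gains of the slow branch.
Defaults were chosen once, by hand, to reproduce the canonical qualitative
shape of primate detection data: chromatic sensitivity ≈ 77 at 1 Hz falling
monotonically, luminance sensitivity ≈ 9 at 1 Hz peaking ≈ 43 near 10 Hz, so
the two curves cross between 2 and 10 Hz. Threshold contrast is $1/S(f)$,
clipped at the display gamut caps (0.86 for L+M, 0.19 for L−M); clipping is a
flagged, legitimate outcome — at 20 Hz the chromatic threshold exceeds the
gamut, as it did for the display used in the recordings this pipeline
mirrors. Sensitivity declines log-linearly with eccentricity
(0.025 log₁₀ units/degree around the 5° reference).

Percent correct in 2AFC maps to d′ through the no-lapse ideal-observer rule
$p_c = \Phi(d'/\sqrt{2})$. The conventional printed pair "82% ↔ d′ = 1.27"
is a rounding: $\Phi(1.27/\sqrt 2) = 0.8154$, and $p_c = 0.82$ exactly gives
d′ = 1.2945. The package treats `pc = 0.82` as primary and derives the
criterion from it; `pc_to_dprime(0.82)` therefore returns 1.2945, not 1.27.

## The F1 ideal observer for spike trains

Each trial's response statistic is the magnitude of the complex projection
of its spike train onto the stimulus fundamental:

$$ R = \Big| \sum_k e^{-i 2 \pi f t_k} \Big|, \qquad t_k \in
   [\text{start}, \text{end}). $$

Blank trials are scored at the same frequency, and d′ uses the
equal-weight pooled-variance convention above (`dprime_f1()`). The
*magnitude* is used rather than a signed projection because response phase is
not assumed known to the observer; this makes the blank statistic a Rayleigh
variable rather than Gaussian, which is why the estimator is validated
against Monte-Carlo oracles rather than closed forms. Negative d′ estimates
are allowed (estimator noise around zero), and exactly identical stimulus and
blank sets return exactly 0. Standard errors come from a nonparametric
bootstrap (trials resampled with replacement within stimulus and blank sets
independently; B = 2000 by default). `window_sweep()` re-estimates d′ over a
grid of counting-window start/end offsets (0–200 ms): because LGN responses
lag the stimulus by ~100 ms, a window delayed by the latency captures the
driven spikes and excludes undriven baseline, raising d′.

## Population pooling

Pooling $N$ equally sensitive neurons whose noise is pairwise correlated at
$\rho$ multiplies single-neuron d′ by

$$ k = \sqrt{\frac{N}{1 + (N - 1)\rho}}, $$

the closed form for an equicorrelated Gaussian population: $\sqrt N$ growth
when independent, saturating at $1/\sqrt\rho$. The effective count is RF
density times the integral of the *squared* Gaussian contrast envelope,
$2\pi(\sigma/\sqrt2)^2 = \pi\sigma^2$ — squared weighting makes pooled d′²
additive across neurons that see reduced contrast near the Gabor fringe.
Default densities (magno 10/deg², parvo 44/deg² at 5°) give a parvo:magno
effective-count ratio of 4.4 and hence a scale-factor ratio of ≈ 2.1,
slightly discounted by the shared correlation ρ = 0.002. That ρ was
calibrated once so that a default single-neuron d′ of order 1 lands the
population d′ in the 1–10 range while keeping the saturation ceiling
($1/\sqrt\rho \approx 22$) far above any default estimate; within-class
correlation only, with deliberately no cross-class parameter.

## Cone photocurrents and the matched-filter bound

The cone current is a linear filter on cone contrast plus additive
stationary Gaussian noise. The impulse response is a difference of gamma
kernels (biphasic: fast positive lobe, slower undershoot; zero at $t=0$
because stage counts are ≥ 2), normalized to unit net integral and scaled by
a DC gain. The noise has a one-sided power spectral density that is a sum of
two Lorentzians (corner frequencies 30 and 180 Hz), and is synthesized
spectrally with Hermitian-symmetric Fourier coefficients so the sample paths
have exactly the configured spectrum in expectation. Parameter values are
plausible for primate cones at photopic light levels but are *model
defaults*, not fits: the shipped `mean_light` (8000 R*/s) deliberately lies
above the nominal calibration range (4000–6500 R*/s) of the measurements the
model family comes from, and every simulated trace carries a
`light_level_extrapolated` flag in its metadata to make that visible.

For a known signal $s(t)$ (the noise-free filtered contrast) in Gaussian
noise, the likelihood-ratio observer is the whitened matched filter with

$$ d'^2 = 2 \int_0^\infty \frac{|S(f)|^2}{\text{PSD}(f)}\, df, $$

computed discretely as $\sum_k |S_k|^2 / (n\,\text{PSD}_2(f_k)/\Delta t)$
over the DFT, with the signal zero-padded by one kernel length so its energy
is fully inside the analysis window. Both L+M and L−M stimuli drive every
cone with the same contrast magnitude, so the L:M mosaic ratio cancels and
the array bound is the single-cone d′ times the square root of the effective
cone count (same squared-envelope integral as for neurons, density
1500 cones/deg² at 5°). `snr_gap()` reports the upstream-minus-downstream
difference and the transmitted fraction, flagging `unphysical` whenever a
downstream stage appears to exceed its upstream bound and `undefined` when
the upstream d′ is zero.

## The synthetic LGN generator

Recorded spike trains can be supplied as `trial_set` objects (plain TSV
rasters round-trip losslessly, including spike-free trials); the shipped
generator exists so the full pipeline runs self-contained. Each neuron is
linear–nonlinear–Poisson:

$$ r(t) = \max\!\big(0,\; r_0 + g\,[c \ast k](t - \ell)
                      - g\,[s \ast k](t - \ell - \delta)\big), $$

where $c$ and $s$ are center and surround cone-weight combinations of the
L/M contrast waveforms, $k$ is a monophasic gamma kernel, $\ell \approx$
100 ms the response latency and $\delta = 10$ ms the surround delay. The
delayed surround is the whole mechanism: magno neurons weight L and M
equally in center and surround (0.95 surround weight), so for L+M stimuli the
surround nearly cancels the center at low frequencies but not at high —
bandpass luminance tuning — while L−M input cancels exactly (non-opponent).
Parvo neurons have a single-cone center and mixed surround, so L−M input
passes uncancelled through their slower kernel — low-pass chromatic tuning.
Spikes are bin-wise Poisson (1 ms bins, uniform jitter within the bin), which
is exact for the piecewise-constant rate used.

Generator realism and calibration: baseline rates (magno ~12, parvo ~8
spikes/s), gains, kernel time constants (6 ms magno, 12 ms parvo) and
latency were set **once**, before the test suite existed, so that at the
default threshold contrasts single-neuron d′ is of order 0.1–2 and population
d′ of order 1–10, with the class signatures above; they were not adjusted
afterwards. Per-neuron parameters get 10% lognormal jitter so populations are
heterogeneous but reproducible from their seeds. The generator is a
caricature in known ways: no contrast-gain control or saturation beyond
rectification, no spike-history dependence (refractoriness, bursting), no
extraclassical surround, and rate noise is exactly Poisson, so realistic
sub- or supra-Poisson variability is absent.

## Numerical choices and problem sizes

- Time step 1 ms everywhere (Nyquist 500 Hz, far above the 20 Hz stimuli and
  the cone noise corners); envelope and kernel integrals are plain Riemann
  sums at that step.
- All convolutions are discrete FFT convolutions scaled by $\Delta t$;
  kernel supports must carry ≥ 99% of kernel energy or a classed truncation
  error is raised.
- Every stochastic block (each neuron, each neuron × condition simulation,
  each bootstrap) draws its own sub-seed from the master seed via a fixed
  integer hash (`derive_seed()`), so results are independent of evaluation
  order and bit-reproducible; all seeds stay below 2³¹.
- Default problem sizes — 4 magno + 4 parvo neurons, 40 trials per condition,
  11 conditions, 500 bootstrap resamples — are this package's own choice,
  sized so the full experiment runs in a few seconds while keeping bootstrap
  SEs on population d′ below ~1.

## Limitations

The cross-stage comparison inherits every simplification above, and its
headline ratios (transmitted fractions of a few percent from cones to LGN at
low frequency; several-fold LGN-over-behavior surplus at high frequency)
should be read as orderings, not measurements: they move with the TCSF
defaults, the cone noise amplitude, and the generator gains. What is robust
under the shipped defaults, and what the acceptance tests pin down, is the
structure — cones ≥ LGN everywhere, LGN ≫ criterion at high frequency with
the low-frequency chromatic population near the criterion, bandpass magno
versus low-pass parvo tuning, and the latency-matched counting window beating
the undelayed one.
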