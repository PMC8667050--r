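---
title: "Simulating bandwidth effects on envelope-ITD sensitivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating bandwidth effects on envelope-ITD sensitivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itdsim)
```

This vignette is the package's account of the science it implements:
the stimulus model, the sharpness metrics, the adaptive procedure, the
simulated-listener population, and the statistical pipeline, together
with the numerical and design choices that the underlying experiment
design leaves open.

## The stimulus: Gabor pulse trains on an ERB grid

A Gabor pulse is a cosine carrier under a Gaussian temporal envelope.
Because the Fourier transform of a Gaussian is Gaussian, the time and
frequency descriptions are tied analytically: if the magnitude
spectrum has half-power (−3 dB) full width $BW$ Hz, the temporal
envelope SD is

$$\sigma = \frac{\sqrt{\ln 2}}{\pi \, BW}.$$

Bandwidths are specified in cochlear units: one ERB at centre
frequency $f$ is $24.7\,(4.37 f_{\mathrm{kHz}} + 1)$ Hz
(Glasberg–Moore), so a "1-ERB" stimulus at 12 kHz is almost three
times wider in Hz than at 4 kHz. The study grid is 3 carriers (4, 8,
12 kHz) × 6 relative bandwidths (0.5–3 ERB in 0.5 steps).

Synthesis is done in the frequency domain: a Gaussian magnitude
spectrum centred on the carrier, with linear phase placing each
envelope peak, Hermitian-symmetrized and inverse-transformed. This
makes the carrier cosine-phase at the envelope peak and the pulse
even-symmetric. The carrier's phase relative to the envelope, and
whether successive pulses are phase-locked, are not constrained by the
design; cosine-at-peak for every pulse is adopted throughout. Trains
default to 10 pulses/s for 300 ms — three pulses, at 50/150/250 ms, so
the Gaussian tails at the buffer edges are negligible (< −80 dB for
every grid condition) and no windowing is applied.

Key sampling decisions:

* **400 kHz synthesis rate.** The ITD is applied as a whole-waveform
  integer-sample delay of the lagging channel before downsampling, so
  the ITD grid is 2.5 µs. Requested ITDs more than a quarter sample
  off the grid are rejected rather than silently rounded.
* **Whole-waveform delay, not ±ITD/2.** The task presents a 0-µs
  reference and then the same stimulus with a left- or right-leading
  ITD, so delaying the lagging ear is the faithful construction.
  Positive ITD means left-leading.
* **Plain 4:1 decimation to 100 kHz.** No anti-alias filter is used
  because none is needed: the stimuli are narrowband and far below the
  50-kHz output Nyquist. This is not left to luck — the spec validator
  requires carrier + 4 spectral SDs below the output Nyquist, and the
  synthesis function additionally verifies that the analytic Gaussian
  tail above 50 kHz holds less than 0.01% of the spectral energy,
  erroring otherwise.
* **Level.** Absolute calibration (dBA) is hardware-bound and out of
  scope. Stimuli of different bandwidths are equated by spectral-peak
  normalization against a reference condition (one common gain across
  both channels, leaving interaural relations untouched); the masking
  noise — two independent Gaussian channels through a 1st-order
  200 Hz plus 3rd-order 1 kHz Butterworth low-pass cascade, −24
  dB/octave asymptotically — takes a relative RMS argument instead of
  a dBA level. Whether the masker was gated or continuous is not
  constrained; it is generated per trial duration (gated).

## Envelope sharpness: t90 before and after the periphery

The sharpness metric is the 10→90% envelope rise time. For the
Gaussian envelope it has the closed form

$$t_{90} = \sigma\left(\sqrt{-2\ln 0.1} - \sqrt{-2\ln 0.9}\right)
         \approx \frac{0.447}{BW},$$

with arbitrary start/end proportions supported. The printed constant
0.447 is the rounded value; internal computations use the exact form.
The empirical measurement extracts the analytic-signal (Hilbert)
envelope, takes the last upward crossing of the 10% level before the
global peak and the first upward crossing of the 90% level, with
linear interpolation between samples (ties broken toward the sample
nearest the peak by the crossing definitions themselves). An attack
that is non-monotone beyond a 2%-of-peak tolerance, or whose 90%
crossing precedes its 10% crossing, yields a flagged result rather
than a silent number.

Peripheral filtering uses the standard 4th-order gammatone with decay
parameter $b = 1.019\cdot\mathrm{ERB}(f_c)$ — the conventional
auditory-filter parameterization; the experiment design names only "a
gammatone peripheral filter", so order and bandwidth factor are
package choices. The filter is applied as FFT convolution with the
sampled impulse response $t^3 e^{-2\pi b t}\cos(2\pi f_c t)$,
truncated where the gamma envelope falls below $10^{-6}$ of its peak
and normalized to unity gain at $f_c$. Rise times are measured on a
single pulse; because the measurement is differential (between two
envelope crossings), the filter's group delay drops out and needs no
explicit compensation.

Two properties matter scientifically and are asserted in the tests:
post-filter t90 is monotone non-increasing in stimulus bandwidth, and
it saturates toward the filter's own impulse-response rise time once
the stimulus is wider than the filter. One quantitative caveat: the
residual 2→3 ERB change is of order 10%, not a few percent — a
Gaussian-convolution argument ($\sigma^2_{\mathrm{out}} \approx
\sigma^2_{\mathrm{stim}} + \sigma^2_{\mathrm{filt}}$) predicts a
~13% change there, so the plateau is approached but not yet flat at
3 ERB with this filter. The off-frequency profile
(`off_frequency_profile()`) quantifies the related confound: remote
channels can be sharper but carry tens of dB less stimulus energy.

## The adaptive procedure

The task is two-interval lateralization: a 0-µs reference, then the
same stimulus with a randomly left- or right-leading ITD; the response
is the perceived side of the second interval, with no feedback in test
mode. The 3-down-1-up staircase divides the ITD by the step factor
after three consecutive correct responses and multiplies after each
error (factor 2 initially, √2 once two reversals have been logged),
ending after 10 reversals; the threshold is the geometric mean of the
last six reversal magnitudes. This converges on the
$(1/2)^{1/3} \approx 79.4\%$-correct point.

Bookkeeping conventions the design leaves open:

* A *reversal* is a trial whose prescribed step direction differs from
  the previous step's; the initial descent has no direction until the
  first increase, and the reversal is logged at the ITD of the
  triggering trial.
* The consecutive-correct counter resets on every step in either
  direction (standard transformed up-down bookkeeping).
* The step that logs the switch-triggering reversal already uses the
  smaller factor for its own movement.
* No ceiling is specified by the design; upward steps are capped at a
  configurable 3000 µs (just above the 2500-µs start) and every capped
  step is counted, so ceiling-limited tracks are identifiable in the
  logs rather than silently truncated.
* Threshold reversals are unsigned magnitudes, since the lead side is
  re-randomized every trial.

Training runs feedback-enabled staircases on the 8-kHz, 1-ERB
condition and stops, from the third track on, when the newest
threshold is within ±15% of the mean of all previous ones, with a
configurable cap (default 20) for non-stationary observers. With the
default observer noise the simulated count distribution sits mostly in
the 3–8 range but with a mean near 6 — somewhat above what trained
human listeners show — because the dominant noise source is the
staircase estimator itself (CV ≈ 0.3 for a six-reversal geometric
mean at these step sizes), not the track-to-track jitter.

## The simulated listener population

The observer consumes the ITD parameter directly — deliberately.
The stimulus and sharpness modules exist to verify stimulus-level
claims (ITD fidelity, sharpness saturation); a waveform-level decision
model (cross-correlation front ends and the like) is a different
research object and out of scope. The psychometric function is a
lapse-contaminated cumulative normal on log ITD,

$$P(\mathrm{correct}\mid \mathrm{ITD}) = \tfrac12 + \left(\tfrac12 -
\lambda\right)\Phi\!\left(\frac{\ln \mathrm{ITD} - \ln
\alpha}{\beta}\right),$$

log-normal because the staircase moves in geometric steps. The
population model makes expected log₁₀ threshold linear in bandwidth:

$$\log_{10}\alpha(f, e) = a + b\,e + c_f + u_\ell, \qquad
u_\ell \sim N(0, \sigma_\ell^2),$$

with per-track lognormal jitter (SD $\sigma_t$ in log₁₀ units)
applied per staircase. Defaults, chosen once as plausible for trained
normal-hearing listeners and exposed in the config:

| parameter | default | rationale |
|---|---|---|
| slope $b$ | −0.20 log₁₀(µs)/ERB | the bandwidth effect size the analysis targets |
| intercept $a$ | chosen so $\alpha(8\,\mathrm{kHz}, 1\,\mathrm{ERB}) = 300$ µs | low-rate pulse trains yield relatively high envelope-ITD thresholds; no threshold table exists to calibrate against, so this is an assumption, not an assertion |
| carrier offsets $c_f$ | 0 | the null of no centre-frequency effect |
| $\sigma_\ell$ | 0.15 | a ×1.4 between-listener spread |
| $\sigma_t$ | 0.08 | test-retest variability that makes the 3-track geometric mean and the training rule meaningful |
| $\beta$ | 0.8 | moderate psychometric slope on log ITD |
| $\lambda$ | 0.02 | occasional attention lapses |

The ideal across-channel integrator sets the observer threshold to
$\alpha_1/\sqrt{n}$ for $n$ recruited channels — the
signal-detection-theoretic benchmark under which the log threshold vs
log channel-count slope is exactly −0.5. Driving the full staircase
machinery with integrator observers (200 tracks per $n$, $n$ = 1–8)
recovers that slope within simulation error, which is how the package
connects the benchmark to the measurable quantity.

What the generator emulates: the log-linear bandwidth dependence,
its absence under the null, between-listener and between-track
variability, lapses, and staircase measurement noise. What it does not
emulate: learning within or across sessions, serial dependence between
trials, condition-specific lapse or slope changes, ceiling-driven
response strategies, or any waveform-level limitation (peripheral
noise, compression). Passing tests therefore validate the machinery
and the statistical pipeline under the assumed generative model — they
are parameter-recovery and calibration results, not evidence about
human listeners.

## The statistical pipeline

Thresholds are analyzed on the log₁₀ scale throughout (geometric
means per cell; the log base affects only intercepts). The headline
fits are OLS of log₁₀ threshold on bandwidth over the 18 condition
means (geometric mean across listeners), with the predictor either
ERB or log₁₀ ERB; per-listener fitting is available but the
condition-mean fit is the default. The two predictors are mechanically
linked at these design points: a line with slope $b$ in ERB refits
against log₁₀ ERB with slope
$b \cdot \mathrm{cov}(e, \log_{10} e)/\mathrm{var}(\log_{10} e)
\approx 3.15\,b$, which is why slopes near −0.2 and −0.63 cohere.

The two-way repeated-measures ANOVA uses the classical within-subject
decomposition, each effect tested against its subject × effect
interaction. Sphericity is assessed per effect by Mauchly's test on
the orthonormal-contrast covariance; the Greenhouse–Geisser
$\hat\varepsilon$ (trace formula on the same matrix) scales both
degrees of freedom when Mauchly rejects at 0.05. With 9 listeners the
interaction has 10 contrast dimensions but only 8 error degrees of
freedom, so its contrast covariance is singular and Mauchly is
undefined; in that case the correction is applied whenever
$\hat\varepsilon < 1$ — the conservative choice, and the one that
yields fractional interaction df with small samples. The
implementation is cross-checked against `car::Anova` (multivariate
formulation) in the test suite, and the sums of squares are verified
to partition the total exactly (relative error < 1e−9). Effect sizes
are partial η² = SS_effect/(SS_effect + SS_error). Post hoc
comparisons are two-sided paired t-tests between all 15 bandwidth
pairs on listener means collapsed over carrier (collapsing is assumed
since the comparisons are bandwidth-only), with Bonferroni
multiplication by 15, clipped at 1.

Type-I calibration draws null threshold tables directly from the
population model (the staircase layer contributes noise but no
systematic effects, so bypassing it is both faster and a cleaner test
of the ANOVA itself). Calibration runs use 12 listeners rather than 9
so that $n - 1 \ge 10$ and the interaction's sphericity test is
actually computable — otherwise the rejection rate would measure the
singular-case fallback policy rather than the F-test.

## Problem sizes, determinism, degenerate inputs

The shipped checks use: 500 staircases for the convergence check, 200
tracks per channel count for the integrator slope, 20–100 replicate
full experiments (each 9 listeners × 54 staircases) for slope
recovery and CI coverage, and 1000 simulated experiments for the
type-I calibration — sizes at which the Monte-Carlo error is small
relative to the tolerances being checked.

Every stochastic function takes an explicit seed; the experiment
runner derives per-listener streams from the master seed by a counter
scheme (`master × 100003 + counter`, mod 2³¹−1), so adding listeners
never perturbs existing ones, and seeded helpers restore the caller's
RNG state. Degenerate inputs fail loudly: off-grid ITDs, spectra that
clip at DC/Nyquist or exceed the decimation-safety bound, silent
inputs to the normalizer, incomplete threshold tables, stepping a
completed staircase, and non-terminating tracks (aborted with a
diagnostic after 10,000 trials).

## Known limitations

* The observer is parameter-level; no waveform-in decision model, so
  stimulus-level manipulations (e.g., masker level) do not influence
  simulated thresholds.
* The gammatone periphery is linear — no compression, suppression or
  adaptation — and the sharpness plateau is asserted as a monotone
  saturation, not an exact value.
* Absolute threshold levels are assumptions; only relative structure
  (slopes, effects) is calibrated.
* The RM-ANOVA is the design's analysis; mixed-effects or Bayesian
  reanalyses are out of scope.
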