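# itdsim

Simulation toolkit for interaural-time-difference (ITD) psychophysics
with band-limited Gabor pulse trains.

Humans can detect microsecond-scale arrival-time differences between
the ears, even at high carrier frequencies where the cue is carried by
the slow temporal envelope rather than the fine structure. A recurring
question in binaural hearing (and in acoustic simulations of cochlear
implant stimulation) is *why* ITD sensitivity improves as stimulus
bandwidth grows: is it the sharper temporal envelope that wider bands
produce, or the recruitment of additional cochlear channels? The two
hypotheses dissociate when bandwidth is scaled in cochlear units —
equivalent rectangular bandwidths (ERB) — across different center
frequencies, because envelope sharpness saturates once the stimulus is
wider than the peripheral filter, while channel count keeps growing.

`itdsim` implements the full computational apparatus needed to exercise
that design without human subjects, for hearing scientists who want to
prototype, power-check, or verify this class of experiment:

- **Stimulus synthesis** — Gabor pulse trains (Gaussian-envelope cosine
  pulses) built in the frequency domain at 400 kHz, ITD applied as a
  whole-waveform delay on the 2.5 µs synthesis grid, decimated to
  100 kHz; spectral-peak normalization; binaurally uncorrelated
  low-pass masking noise; float32 WAV output.
- **Envelope sharpness** — the t90 metric (10→90% envelope rise time).
  For a Gabor pulse with −3 dB bandwidth *BW*, the envelope SD is
  σ = √(ln 2)/(π·BW), giving the closed form t90 ≈ 0.447/*BW*; the
  package also measures t90 empirically from the Hilbert envelope and
  after 4th-order gammatone peripheral filtering (bandwidth
  1.019·ERB), including off-frequency channel energy/sharpness
  profiles.
- **Adaptive psychophysics** — the two-interval left/right
  lateralization task run as a 3-down-1-up transformed up-down
  staircase (start 2500 µs, step factor 2 → √2 after the second
  reversal, stop at 10 reversals, threshold = geometric mean of the
  last six), which converges on the (1/2)^⅓ ≈ 79.4%-correct point; a
  training phase with a ±15% moving-average stopping rule; a blocked
  experiment runner (3 carriers × 6 bandwidths × 3 repetitions = 54
  staircases per listener).
- **Simulated listeners** — lapse-contaminated cumulative-normal
  psychometric functions on the log-ITD axis, drawn from a population
  model that is log-linear in bandwidth (ERB) with listener- and
  track-level variability; plus an ideal across-channel integrator
  whose threshold improves as 1/√n, the signal-detection-theoretic
  benchmark (log–log slope −0.5).
- **Statistics** — threshold aggregation by geometric means; OLS slope
  fits of log₁₀ threshold against ERB or log ERB with 95% CIs and R²;
  two-way repeated-measures ANOVA with per-effect Mauchly sphericity
  tests, Greenhouse–Geisser correction and partial η²;
  Bonferroni-corrected paired post hoc comparisons.

## Worked example

```r
library(itdsim)

erb_bandwidth_hz(8000)          # 888.2  (Hz in one ERB at 8 kHz)
t90_closed_form(888.2)          # 503 us: envelope rise time, 1 ERB pulse
post_filter_t90(8000, 1)        # 636 us: after gammatone filtering

pop <- population_model()       # slope -0.20 log10(us)/ERB, ~300 us at 8 kHz/1 ERB
raw <- run_experiment(pop, seed = 1)   # 9 listeners x 54 staircases
tab <- aggregate_thresholds(raw)
fit_slope(tab, "erb")
#> slope fit (log10 threshold ~ erb): slope -0.204 [-0.221, -0.187], R2 = 0.975
fit_slope(tab, "log_erb")
#> slope fit (log10 threshold ~ log_erb): slope -0.632 [-0.753, -0.512], R2 = 0.886
rm_anova(tab)[, c("effect", "df_num", "df_den", "F", "p")]
#>   effect           df_num df_den      F        p
#> 1 bandwidth          5     40    112.5    1.9e-22
#> 2 center_frequency   1.12   8.96   0.494  0.521
#> 3 interaction        4.46  35.7    0.870  0.501
```

The recovered slope (−0.204) matches the generative population slope
(−0.20): thresholds improve by a factor ~10^0.2 ≈ 1.6 per ERB of
bandwidth. The ANOVA shows the expected pattern — a large bandwidth
effect, no center-frequency effect, no interaction — the signature of
channel recruitment rather than envelope sharpness. Note the
fractional degrees of freedom where sphericity could not be assumed
and the Greenhouse–Geisser correction was applied.

A complete run (stimuli → staircases → analysis → tidy CSVs and a JSON
manifest) is one call:

```r
run_all(default_run_config(), seed = 1, out_dir = "run1")
```

or from the shell, `Rscript inst/scripts/run_all.R --seed 1 --out run1`.

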