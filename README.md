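# transadapt

Simulation and analysis of trans-saccadic contrast-adaptation experiments.

## The scientific problem

Neurons throughout the visual system adapt to unchanging input within tens of
milliseconds, reducing perceived contrast. Saccadic eye movements refresh the
retinal image — but only where the postsaccadic input actually differs from
the presaccadic one. The contrast-cancellation paradigm probes this directly:
an observer fixates two horizontal luminance gratings (one per screen half),
then saccades to a target placed exactly two wavelengths of one grating away.
After the saccade, that *correlated* grating occupies the same retinal phase
as before (shift `0 mod 2π`), while the other, whose wavelength satisfies
`λ_anti = 2 λ_corr / F_anti` with `F_anti ∈ {1.5, 2.5}`, lands phase-inverted
(*anticorrelated*, shift `π`). If adaptation survives the saccade, the
correlated grating looks washed out and the anticorrelated one vivid: the
point of subjective equality (PSE) of a 2AFC contrast judgment shifts to
negative contrast differences `Δc = c_anti − c_corr`.

`transadapt` packages the entire experimental pipeline in simulation:

- **stimulus geometry** — gratings, generalized-Gaussian windows
  (`exp(−(|y−y₀|/α)^β)`, α = 2.1°, β = 3), retinal-phase arithmetic,
  Gaussian-filtered noise masks (0.18 ± 0.02 cyc/°, contrast 0.7);
- **experiment designs** — counterbalanced, randomized schedules for five
  designs (full crossing of Δc × grating position × `F_anti` × saccade
  direction, plus adaptation duration, blank duration, or slice location),
  with the adaptive saccade-latency predictor (median of the last 20
  latencies, 190 ms before the first observation) and the gaze-contingent
  onset rules;
- **a generative observer** — PSE builds up with adaptation duration `t` as
  `pse_max (1 − e^{−t/τ})` and decays over a postsaccadic blank along
  `A log(blank) + B`; 2AFC responses follow a lapse-bounded cumulative
  Gaussian `λ/2 + (1−λ) Φ((Δc − PSE)/JND)`; 1000 Hz gaze traces with
  shifted-gamma latencies, minimum-jerk saccades, Gaussian landing error,
  smoothed fixational jitter and blinks;
- **offline gaze processing** — velocity/acceleration saccade detection
  (22 °/s, 3800 °/s²), the online 2° trigger, fixation-window measures and
  every exclusion rule (blinks, switch outside the saccade, fixation SD
  > 0.5°, saccade-amplitude ratio `F_corr = |ampl|/λ_corr` more than 0.25
  from an integer, latency > 600 ms, deviant adaptation duration);
- **psychometrics** — maximum-likelihood cumulative-Gaussian fits (PSE,
  JND, symmetric lapse, bootstrap CIs), the growing/sliding/shrinking
  300 ms running-average curve over `[0, 1400]` ms, logarithmic decay fits
  and t tests (pooled two-sample convention).

## Worked example

Simulate four observers in the main-effect design and analyse them end to
end:

```r
library(transadapt)
report <- run_experiment(run_config(experiment = 1, n_participants = 4, seed = 11))
report
#> <run_report> Experiment 1, 4 participant(s), seed 11 [1c757d50]
#>   trials: 1920 (9.7% excluded)
#>   group PSE -0.140 ± 0.005, JND 0.071 ± 0.006 (Mean ± SD)
report$t_pse_vs_zero[c("t", "df", "p")]
#> $t
#> [1] -56.41762
#> $df
#> [1] 3
#> $p
#> [1] 6.13346e-06
```

Each observer completes 480 trials (15 contrast-difference levels × 2
grating positions × 2 anticorrelation factors × 2 saccade directions × 4
repetitions). About 10% of trials are excluded by the fixation-accuracy
rules, mirroring realistic oculomotor noise. The group mean PSE of −0.140
means the correlated grating had to be raised in contrast by 0.14 (Δc
units) to be judged equal to the anticorrelated one — the signature of
adaptation surviving the saccade — and the one-sided t test against zero
confirms the shift. Lower-level entry points (`build_schedule()`,
`simulate_gaze()`, `detect_saccades()`, `fit_psychometric()`,
`running_average()`, `fit_log_decay()`, ...) expose every stage
individually; see the vignette source in `vignettes/` for the model
details.

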