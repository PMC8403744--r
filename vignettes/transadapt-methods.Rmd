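---
title: "Models and methods behind transadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind transadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transadapt)
```

`transadapt` simulates gaze-contingent contrast-cancellation experiments and
recovers adaptation effects with the same analysis pipeline one would apply
to real eye-movement and response data. This vignette documents the models,
the parameters that matter, the numerical choices, and what the simulations
can and cannot establish.

## The paradigm in brief

An observer adapts to two horizontal luminance gratings (upper and lower
screen half, separated by a grey bar carved out by an inverted
generalized-Gaussian window, scale 2.1°, shape 3) and then saccades to a
target placed at exactly twice the wavelength of one grating
(10°–12.5° eccentricity). That *correlated* grating retains its retinal
phase across the saccade; the other grating's wavelength,
`λ_anti = 2 λ_corr / F_anti` with `F_anti` of 1.5 or 2.5, makes the same
displacement equal a half-integer number of its cycles, inverting its
retinal phase (*anticorrelated*). A 400 ms test display with a contrast
difference `Δc = c_anti − c_corr` about a fixed mean of 0.15 follows the
saccade, then a noise mask; the observer reports which half looked higher
in contrast. Adaptation shifts the point of subjective equality (PSE) of
this judgment toward negative `Δc`.

## The generative observer

### Adaptation dynamics

The observer's PSE on a trial depends on how long the adaptation stimulus
was fixated (`t_adapt`, from adaptation onset to saccade onset) and on any
blank inserted before the test (`t_blank`):

* **Build-up** is a saturating exponential,
  `PSE(t) = pse_max · (1 − exp(−t_adapt/τ))`. The experiments only report a
  monotone build-up measured through a running average, not a fitted
  functional form, so the simplest monotone saturating form was chosen; `τ`
  is configurable (default 0.23 s).
* **Decay** multiplies the built-up PSE by a factor that is 1 at no blank
  and follows `decay_A · log(blank_ms) + decay_B` (clamped to `[0, 1]`)
  for blanks of at least 100 ms, linearly interpolated below that. The
  logarithm mirrors the analysis-side decay model, which is undefined at 0
  and therefore anchored at the no-blank PSE rather than extrapolated.

The defaults (`pse_max = −0.14`, `τ = 0.23 s`, `decay_A = −0.103`,
`decay_B = 1.188`) are calibrated so that the canonical group-level
magnitudes emerge: ≈ −0.14 after 1.7 s of adaptation with no blank,
≈ −0.06 after 1.5 s of adaptation and a 1.6 s blank, and roughly −0.05
(proportion ≈ 0.39 at `Δc = −0.07`) after only 100 ms of adaptation. These
are generator *settings*, not outcomes; the tests then ask whether the
full pipeline recovers them.

```{r pse-curve, eval = FALSE}
p <- observer_params()
curve(true_pse(x, 0, p), 0, 3, xlab = "adaptation duration (s)",
      ylab = "PSE (delta-c)")
```

Two secondary effects are modelled multiplicatively: the Experiment 4
slice conditions scale the PSE (defaults 0.79 centre, 0.21 periphery,
reflecting the dominance of the central visual field), and in Experiment 5
the PSE scales with `0.15 / test mean contrast` — a Weber-like attenuation
of the contrast-difference shift when the test stimulus is high-contrast.
An optional additive `position_bias` models the upper/lower visual-field
asymmetry and defaults to 0 (not generated).

### Responses

A 2AFC response is a Bernoulli draw from
`P(anticorrelated higher) = λ/2 + (1 − λ) Φ((Δc − PSE)/JND)` with default
`JND = 0.077` and lapse `λ = 0.02`. The lapse bounds the asymptotes in
`[λ/2, 1 − λ/2]`, which is what fitted psychometric functions on real data
show.

### Gaze traces

Traces are sampled at 1000 Hz. Saccade latency is shifted-gamma
(`80 + Gamma(8, 14.5)` ms, median ≈ 191 ms) — a conventional positively
skewed latency model whose parameters are configurable per observer so
group medians in the 160–235 ms range can be produced. The saccade itself
follows a minimum-jerk position profile with main-sequence duration
`21 + 2.2·amplitude` ms (peak velocity several hundred °/s, comfortably
above the 22 °/s detection threshold), landing at the target plus a
Gaussian error (default SD 0.75°, the middle of the typical 0.5°–1° range
for saccades of this size). Fixational jitter is Gaussian noise smoothed
with a 10 ms kernel — smooth enough that its velocity and acceleration
stay far below the detection thresholds, as real drift does. Blinks (one
per trial with probability 0.04, 100–300 ms, signal frozen) are flagged
per sample. Adaptation is frozen at saccade onset: the adaptation duration
that drives the PSE is the time from adaptation-stimulus onset to the
ground-truth saccade onset, with no further build-up during the saccade or
blank.

What the generator deliberately does **not** emulate: microsaccades and
ocular drift microstructure (negligible at 0.12–0.25 cyc/° stimulus
frequencies), pupil signals, binocular disparity, calibration drift of the
eye tracker, and visual-field asymmetries in adaptation (off by default).
Passing tests therefore demonstrate that the *pipeline* is correct and
unbiased under realistic oculomotor noise — not that the dynamical model
is the true model of human adaptation.

## Scheduling and gaze-contingent timing

Schedules fully cross the design factors and shuffle trial order;
saccade direction (left/right) is treated as an additional counterbalanced
factor in every design, which reproduces all printed trial counts (480,
384, 528, 120 per block, and 416). Wavelength (`U[5, 6.25]°`), common
phase (`U[−π/2, π/2]`), fixation-to-target interval (`U[1.4, 1.6] s` in
the overlap designs) and the Experiment 5 adaptation contrast
(`U[0.3, 0.7]`) are drawn per trial from named RNG streams of the master
seed, so every schedule and dataset is exactly reproducible and
independent of the caller's RNG state.

The adaptive latency predictor returns 190 ms before the first observation
and thereafter the median of up to the last 20 realized latencies. In the
build-up design the saccade target is anchored at 1.2 s after trial
initiation and the adaptation onset is placed at
`1200 + predicted − intended` ms, so a saccade at the predicted latency
realizes the intended adaptation duration; in the persistence design the
adaptation onset is delayed by the prediction and the target fixed at
1.5 s, targeting a constant 1.5 s adaptation duration.

## Offline gaze analysis

Saccades are detected by thresholding velocity (22 °/s) or acceleration
(3800 °/s²). The reference algorithm's internals are proprietary, so the
estimation details are fixed here and exposed as arguments: central-
difference velocities smoothed with a 5-sample running mean, events merged
when separated by less than 20 ms, events shorter than 4 ms discarded,
blink samples excluded. On simulated traces the detected onset stays
within ±2 ms of ground truth, which the test suite asserts over 1000
trials.

Per-trial measures follow the fixation-window definitions: presaccadic
fixation position is the mean horizontal gaze from adaptation onset to
saccade onset, postsaccadic from saccade offset to mask onset, amplitude
their difference, latency the saccade onset minus target onset at 1 ms
resolution. Exclusion rules are evaluated exhaustively (all violated rules
reported): blinks before mask onset, display switch outside the saccade,
fixation SD above 0.5°, amplitude ratio `F_corr = |ampl| / λ_corr` at
distance ≥ 0.25 from the nearest integer (0.5 being the worst case, a
role swap of the two gratings), latency above 600 ms (overlap designs
only), and adaptation duration more than 100 ms from the intended 1.5 s
(persistence design only). The ratio is taken unsigned; whether a signed
convention was used for leftward saccades is unknowable from the printed
rules, and the unsigned form is symmetric and conservative.

## Psychometric analysis

The cumulative Gaussian with a single symmetric lapse (free in `[0, 0.1]`)
is fitted by maximum likelihood with L-BFGS-B from a deterministic grid of
starting values (location guesses from the weighted mean and the level
closest to 50%, three scale guesses, two lapse guesses), keeping the best
optimum — deterministic given the data, no RNG involved. Degenerate data
(all responses identical) raise an informative error rather than returning
a meaningless fit. Bootstrap CIs resample trials nonparametrically.

The running average over adaptation duration uses the exact growing /
sliding / shrinking bin scheme on `[0, 1400]` ms: bins anchored at 0
growing from 150 to 300 ms width, a 300 ms bin sliding in 1 ms steps, and
mirrored shrinking bins anchored at 1400 ms; each point sits at its bin
midpoint. Empty bins are omitted rather than interpolated, and group
curves average participants pointwise over emitted bins. The
implementation uses sorted cumulative sums; the test suite checks it
against a brute-force enumeration oracle.

The decay of the group PSE over blank duration is fitted as
`PSE = A·log(blank_ms) + B` by least squares on blanks ≥ 100 ms, with the
blank-0 PSE reported separately as the anchor (the natural log is
undefined at 0; whether the original analysis transformed the 0 point is
not stated, so it is excluded here). t tests wrap the standard
implementations, with pooled variance for two-sample comparisons (so
groups of 16 and 7 give 21 degrees of freedom).

## Problem sizes and reproducibility

The simulations used by the test suite and the acceptance script run the
studies at their native sizes — 16 participants × 480 trials for the
main-effect design, 7 × 528 for persistence — and smaller cohorts (1–4
participants) for unit-level checks; these sizes make the whole suite run
in a few minutes while keeping group-level estimates stable. Every dataset
is reproducible byte-for-byte from its master seed. Known limitations:
participant heterogeneity is absent unless a list of per-participant
`observer_params()` is supplied, so between-participant SDs of simulated
groups are smaller than empirical ones; the build-up time constant and the
Experiment 4/5 scalings are phenomenological conveniences, not mechanistic
claims; and the noise-mask filter is defined only up to its stated mean
spatial frequency and bandwidth, the exact original filter being
unspecified.
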