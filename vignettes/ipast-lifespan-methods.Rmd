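---
title: "Modeling IPAST behavior across the lifespan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling IPAST behavior across the lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipastr)
```

## The task and the pipeline

The interleaved pro/anti-saccade task (IPAST) probes inhibitory control with
eye movements. Each trial shows a central fixation point (FP) for 1000 ms
whose color cues the condition, removes it for a 200 ms gap, then presents a
peripheral stimulus (STIM) at 10 degrees left or right for 1000 ms. On PRO
trials the participant looks at the stimulus; on ANTI trials the participant
must suppress that reflexive response and look to the mirror location. A
session is two blocks of 120 trials with condition and side counterbalanced
and pseudo-randomly interleaved within block, so the correct response must
be re-selected on every trial. The gap boosts *express* saccades —
short-latency (90–139 ms) responses near the minimum sensorimotor delay —
which on ANTI trials are almost always direction errors.

`ipastr` implements the complete analysis chain for such data:

1. **Saccade detection** on 500 Hz monocular gaze traces with a per-trial
   dynamic speed threshold,
2. **trial classification** into a nine-category taxonomy,
3. **participant-level quality control**,
4. **seven behavioral measures**, including the voluntary override time
   (VOT),
5. **lifespan GAMs** with posterior-simulation change-point analysis and
   percentile growth curves, and
6. **age-controlled Spearman correlations** between measures.

Because raw IPAST recordings are not generally shareable, the package also
contains a first-class synthetic-data generator that emulates the study
design from single gaze samples up to full cross-sectional cohorts with
known ground truth, so every stage is testable end to end.

## The generative race model

Latent trial outcomes are drawn from a race between saccade-programming
processes, following the two-suppression account of interleaved
pro/anti-saccade behavior. On each behavioral trial:

- With probability `p_express[condition]` the **express pathway** fires: a
  stimulus-directed saccade with truncated-normal latency on 90–139 ms
  (defaults: mean 108 ms, sd 14 ms). On ANTI trials this is an
  express-latency direction error — a failure of the *first* (pre-emptive,
  global) suppression.
- Otherwise an **automated** stimulus-directed command (shifted gamma:
  shape 2, scale 55 ms, shift 105 ms) races a **voluntary** goal-directed
  command (shifted gamma: shape 8, scale 12 ms, shift 150 ms). On ANTI
  trials the *second* (location-specific) suppression cancels the automated
  command outright with probability `1 - p_automatic` (default
  `p_automatic = 0.30`); a surviving automated command that finishes first
  triggers a regular-latency direction error, and a winning voluntary
  command a correct anti-saccade. On PRO trials both commands drive the same
  (correct) response, and the earlier finishing time wins.

Trials can instead be diverted to eye-tracking loss, three non-compliance
modes (never fixating, an off-axis random saccade, no saccade), or an
anticipatory guess (uniform on −110..89 ms, random direction), each with a
small configurable probability.

The shifted-gamma choice gives the right-skew typical of saccadic reaction
time distributions; the shift parameters encode non-decision time and the
constraint that the voluntary command cannot start before the automated one.
The cancellation probability `p_automatic` is essential: without it, an
independent race cannot simultaneously produce adult-typical error rates
(~20–25%) and error latencies that lead correct latencies, because the
faster automated process would win far too often. The default values were
fixed from the analytic race formulas — adult ANTI error rate 0.26
(`race_anti_error_probability()`), analytic crossover VOT 187 ms
(`race_analytic_vot()`) — and are configuration constants, not estimates
from any dataset.

All analytic race quantities (error probabilities, latency sub-densities,
cumulative curves, the exact VOT) are computed by numerical
integration/quadrature of the model densities and serve as independent
ground truth for the Monte-Carlo sampler and the downstream pipeline.

## Rendering gaze traces

Latent outcomes are rendered into 500 Hz traces covering FP onset through
STIM offset. Fixation epochs are white Gaussian positional noise at
0.02 degrees RMS, a typical video-tracker noise floor. Saccades are
raised-cosine position ramps — the simplest waveform with a smooth,
symmetric, single-peaked speed profile — with amplitude-scaled durations
(30–60 ms, ~55 ms at 10 degrees). The latent latency is *defined* as the
operational saccade onset: the ramp is led in by the short analytic interval
its speed spends below the 20 deg/s detection floor, so a threshold detector
sees onset at the nominal latency. Eye-loss trials carry long invalid-sample
runs; no-fixation trials park gaze away from the FP; random-saccade trials
launch a vertical (off-axis) saccade; no-saccade trials fixate throughout.

What the renderer deliberately does **not** emulate: drift and slow control
movements, corrective/secondary saccades, saccade curvature, pupil dynamics,
temporally correlated tracker noise, and blink-recovery transients. Passing
round-trip tests therefore show that the detector and classifier implement
their stated rules faithfully on well-formed input — not that they are
robust to every artifact of real recordings.

## Detection and classification rules

Speed is the magnitude of the central-difference derivative of position
after a 3-sample median filter (suppresses single-sample spikes without
blurring onsets). Invalid samples propagate to every speed sample whose
stencil touches them, and saccades never span invalid runs. The per-trial
threshold is `mean + 2.5 sd` of fixation-epoch speed (FP onset + 100 ms to
FP offset, valid samples only; the first 100 ms are dropped to avoid
landing-saccade contamination), floored at 20 deg/s; a saccade requires 10 ms
(5 consecutive samples, inclusive) above threshold. Onset is the first
sample of the run — deterministic, no sub-sample interpolation.

Classification windows, relative to STIM onset and inclusive at integer
bounds: anticipatory −110..89 ms, viable 90..800 ms, express 90..139 ms,
regular 140..800 ms. A saccade counts as stimulus-axis-directed when its
horizontal displacement toward one of the two possible STIM locations is at
least 2 degrees (stimuli appear only at ±10 degrees, so no angular criterion
is needed). Fixation is acquired when gaze stays within 2 degrees of the FP
for at least 200 ms of the FP epoch; a trial is eye loss when more than 25%
of samples between FP onset and 800 ms post-STIM are invalid. These three
spatial parameters are not dictated by the task geometry and are exposed in
`classification_params()`. Two bookkeeping choices worth making explicit:
anticipatory trials form their own stratum (they are neither non-compliant
nor viable), and a PRO-trial saccade away from the stimulus is classed as a
random-saccade non-compliance rather than an error, because direction errors
are an ANTI-trial concept and PRO error rates are not among the seven
measures. Only the first substantive saccade of a trial is scored.

## The seven measures and VOT

Per participant: mean PRO and ANTI viable correct SRT; PRO express- and
regular-latency correct-response ratios and ANTI express- and
regular-latency direction-error ratios (all with the condition's viable
trial count as denominator); and VOT. For VOT, the cumulative SRT
distributions of ANTI correct responses and direction errors (1 ms grid,
common viable-count denominator, so each curve asymptotes at its category
ratio) are differenced, smoothed with a 7-point box kernel, and the earliest
minimum within 90–400 ms is taken — the time at which voluntary processes
begin to overcome automated ones.

Numerical choices: the 1 ms grid loses nothing against 2 ms-quantized
samples and makes the kernel footprint exactly ±3 ms; the kernel shrinks to
the valid overlap at the grid edges (zero-padding would manufacture boundary
minima); ties in the argmin go to the earliest bin, and the smoothed curve
is rounded to 9 significant digits first so that mathematically flat
plateaus are not broken by floating-point associativity.

## Quality control

The participant screen mirrors standard practice for this design: exclude if
(1) the PRO or ANTI viable count is below 30; (2) the PRO or ANTI eye-loss
count *or* non-compliance count exceeds 20% of the 120 expected trials
(i.e., strictly more than 24 — the two counts are tested separately, either
sufficing); (3) a MoCA score is present and below 20. Eye-tracker validation
accuracy at or above 1.5 degrees is screened at ingest, and participants
with no ANTI viable correct response are excluded (their VOT is undefined).
Missing MoCA or validation values never exclude. Multi-reason participants
are attributed to the earliest rule for sequential accounting.

## Lifespan GAMs and change-point analysis

Each measure is modeled as a Gaussian GAM with a penalized cubic regression
spline smooth of age, fitted by mgcv with REML smoothing-parameter
selection. Ratio measures are first squeezed with the empirical logit,
`p' = (p(n-1) + 0.5)/n` with `n` the participant's viable count, then
logit-transformed; the squeeze handles the natural zero/one inflation and is
exactly invertible.

Significant periods of change are found by posterior simulation: draw
coefficient vectors from the Gaussian posterior `N(beta, Vp)` of the
penalized fit (10,000 draws by default), push them through the basis on a
0.1-year age grid, and build a *simultaneous* 95% confidence band for the
first derivative from the max-over-grid standardized deviation of the
draws. Maximal grid runs where the band excludes zero are the significant
periods, labeled developmental when they begin before age 23 and aging
otherwise. Derivatives use central finite differences of the
linear-predictor matrix (half-step 0.01 years); a two-step-size comparison
in the tests bounds the O(h²) error, replacing an analytic-basis derivative
that mgcv does not expose. Single-grid-point runs (below the grid's
resolution) are dropped. A non-positive-definite posterior covariance is
repaired by eigenvalue clipping with a warning; degenerate (zero-sd) grid
points fall back to a zero-width band with a warning.

**Basis dimension.** The default is `k = 20`. With a cubic regression
spline over an 88-year range, `k = 10` places knots roughly every ten years
and demonstrably smears slope kinks: in recovery experiments on synthetic
cohorts it biased the end of the developmental period about +4–5 years. A
generous basis with the penalty left to shrink it (standard mgcv advice)
removes that resolution bias; REML keeps the effective degrees of freedom
modest regardless.

**Known limitation — detection-onset lag.** A simultaneous band switches on
only after the accumulated derivative exceeds the band half-width, so the
*start* of a weak-slope period necessarily lags the true change point. In
our recovery experiments (n = 600, between-participant sd ≈ 25 ms), a
−7 ms/year developmental segment ending at age 18 is localized to within
±3 years reliably, but the onset of a +2 ms/year aging segment at age 60 is
detected 2–10 years late at any basis dimension. This is an inherent
property of conservative simultaneous inference, not an implementation
artifact (the fit matches a direct normal-equations oracle and the band's
simultaneous coverage is verified at 95% ± 2%); boundaries of weak-slope
periods should be read as conservative inner bounds.

For the sex comparison, a second model adds sex intercepts and separate
age smooths per sex level (factor-`by` smooths, no age-by-sex tensor), and
the two models are compared by BIC computed from the Gaussian likelihood at
the penalized fit with the total effective degrees of freedom (plus the
scale) as the parameter count — one of several reasonable BIC conventions
for smooth models, applied identically to both models so the comparison is
fair.

Percentile growth curves ("cognitive growth curves") are the GAM mean fit
plus empirical quantiles of the fit residuals in a sliding 10-year age
window. Quantiles at each age come from a single residual sample, so the
family is monotone in percentile by construction; quantile-regression
splines would be the natural model-based alternative if crossing-free
smoothness mattered more than simplicity. Extreme percentiles are flagged
as unstable below 200 observations.

## Correlations

Pairwise relationships between measures are assessed on standardized GAM
residuals (residual / REML scale estimate), which removes the common age
trend, using Spearman rank correlations (average ranks for ties). P-values
use the exact null distribution for n ≤ 30 (the residuals are continuous,
so ties are not a concern) and the t-approximation otherwise. No
multiplicity correction is applied by default, matching the usual
`p < 0.05` display convention for such matrices; Holm adjustment is
available by argument.

## Synthetic cohorts and ground truth

`generate_cohort()` draws ages uniformly over 5–93 (deliberately simple:
even coverage for the change-point analysis, rather than the
young-adult-skewed recruitment typical of real cohorts), assigns sex at
equal frequency, MoCA scores to 80% of adults (mean declining mildly with
age so that below-cutoff scores occur), validation accuracies, and a 4%
fraction of poor-compliance participants (strongly elevated eye-loss and
non-compliance rates) so the QC stage has realistic work to do. Participant
parameters come from trajectory curves evaluated at each age with lognormal
between-participant noise (multiplicative, keeping positive parameters
positive), and each participant's session is simulated from a deterministic
counter-based substream of the global seed, so cohorts are reproducible
under any generation order.

The default lifespan trajectory moves the voluntary-process shift along a
piecewise-linear U: −7 ms/year from age 5 to a change point at 18, flat to
60, then +2 ms/year to 93 — rates on the order of those reported for
voluntary override measures — with express-pathway probabilities declining
over development. The change-point ages are recorded alongside the cohort
as recovery ground truth. What the cohort generator does not emulate:
longitudinal (within-person) structure, recruitment skew, practice and
fatigue effects, and any covariance between trajectory parameters beyond
what the shared curves induce.

## Problem sizes used in the test suite

The shipped tests run the statistical experiments at sizes chosen to give
stable verdicts at interactive runtimes: detection-oracle equivalence on
1,000 randomized traces; trace round trips on 960–1,920 rendered trials;
VOT recovery on 200 simulated participants of 120 ANTI trials; simultaneous
band coverage on 500 replicates of a 40-point Gaussian-process toy with
1,200 draws each; change-point recovery on 30 cohorts of 600 participants
(with 40 null cohorts for false-detection calibration) using 1,500
posterior draws per fit; and 10,000 property cases for the ratio/logit
invariants. The acceptance script runs the full pipeline at the study scale
(604 participants, 10,000 posterior draws, 0.1-year grid).
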