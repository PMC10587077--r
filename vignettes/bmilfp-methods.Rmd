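---
title: "Models and methods in bmilfp"
author: "bmilfp maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in bmilfp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models implemented in `bmilfp`, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices that were genuinely open.

# The setting

A subject performs a two-dimensional, self-initiated, eight-target
center-out task under two control types — manual reaching, and
brain–machine interface (BMI) control in which binned motor-cortical spike
counts drive a cursor through a Kalman-filter decoder — with a four-minute
baseline rest period in between. Local field potentials (LFP) are recorded
simultaneously from three regions: primary motor cortex (M1), dorsolateral
prefrontal cortex (DLPFC) and the caudate nucleus (Cd). One *day* is the
triple of sessions (manual, baseline, BMI); all statistics are computed
within day and compared across days.

# Signal conditioning and referencing

`conditionLfp()` low-passes at 250 Hz, notches 60 and 120 Hz, and
down-samples to 1 kHz. Because every downstream analysis is event-locked,
filtering is zero-phase (forward–backward). The low-pass is a Chebyshev
type-II design (order 8, 60 dB stopband from 260 Hz): applied twice it
attenuates above-250 Hz content by well over 40 dB while the 4–150 Hz
analysis range stays flat to within 1 %. The notches are second-order
Butterworth band-stops at ±2 Hz.

`commonMedianReference()` implements the four-step day-level procedure
described in the package README: z-score within channel and session,
subtract the cross-channel median at each timepoint, restore the original
scaling, then z-score each channel with mean and SD pooled **across all
three sessions of the day**. The median (rather than mean) resists
outlier channels. Two interpretation points were open and are resolved as
follows:

* the step-4 pooling covers all three sessions of the day, including
  baseline — "all recording sessions within a day" is read literally;
* a channel with zero variance in any session makes step 1 undefined, so
  the function refuses by channel name rather than guessing.

The median of *n* z-scored channels carries sampling noise of roughly
`sqrt(pi/2n)` per timepoint; with realistically dense arrays (tens of
channels) the injected noise is small, which is why validation scenarios
use array-scale channel counts (27/22/8) rather than the generator's
small desk-scale default.

# Band power and features

`welchBandPower()` integrates a Welch power-spectral-density estimate over
the five canonical bands, half-open intervals `[low, high)` so no bin is
counted twice: theta 4–8, alpha 8–13, beta 13–35, gamma 35–75, highgamma
75–150 Hz. Welch parameters are not dictated by the analysis itself and
were fixed once: Hann window, 250-sample segments, 50 % overlap,
per-segment demeaning. A 500 ms epoch at 1 kHz therefore yields three
averaged segments on a 4 Hz frequency grid. Consequences worth knowing:

* the theta band contains a single 4 Hz bin — its lower edge coincides
  with the resolution floor; integration includes the first bin at or
  above each band's low edge;
* off-grid components (e.g. a 6 Hz tone, half a bin from the grid) leak
  part of their energy into the neighboring bin across the theta/alpha
  edge. Band *contrasts* are unaffected (leakage is proportional), but
  absolute single-bin powers should be read with this in mind.

`roiAverage()` takes the arithmetic mean over member channels per band,
preventing regions with more channels from dominating classifiers; M1
averaging is restricted to channels flagged as carrying the decoder's
direct units (`m1DirectOnly = TRUE`). The canonical single code path is:
per-channel band power → region average → (optionally) normalization to
each region's total power. Normalized fractions are used for descriptive
power summaries; classifier features are the un-normalized region-averaged
powers, since nothing in the analysis requires scale invariance and the
normalization couples bands within a region.

# Classification

`fitEvalDiscriminant()` implements Gaussian discriminant analysis
directly: class means and covariances, class-specific (QDA, used for
task-type models whose class variances differ) or pooled (LDA, used for
the 8-class target-direction models where per-class counts are an eighth
of the data). Supporting choices:

* **equal priors** — classes are balanced to the day's minimum class
  count (`balanceClasses()`) before fitting, so empirical priors are
  uniform by construction;
* **stratified, seeded folds** — every class appears in every test fold
  (proportions within one sample); plain k-fold could drop a class from
  a fold at these sample sizes;
* **ridge fallback** — a numerically singular covariance receives
  `1e-6 × trace/dim` on the diagonal (escalated tenfold while needed) and
  the event is logged; small per-class counts with 15 features make this
  reachable;
* **deterministic ties** — equal posteriors resolve to the lowest class
  index;
* per-day accuracy entering across-day statistics is the mean of fold
  accuracies.

Chance is calibrated per model and day by re-running the full
cross-validation on label-shuffled data (1000 permutations by default);
`compareAccuracy()` then applies paired or one-sample t-tests with
Bonferroni correction, with documented degenerate rules (identical
vectors: t = 0, p = 1; constant non-zero shift: p reported as 0 and
flagged).

The target-direction study excludes the first five recording days (early
BMI sessions have too few successes per direction) and matches trial
counts per direction across control types before fitting; days in which
any direction lacks successful trials in either control type are skipped
with a message, and the fold count is reduced to the matched per-direction
count when that count falls below ten.

Learning-stage splits (`stageSplit()`) take the first and last thirds of
days (floor division) as early and late stages; the middle absorbs the
remainder, and the three stages always partition the day set.

# Directed connectivity

`grangerPair()` is the Geweke log residual-variance ratio: the target
series is regressed on p of its own lags (reduced) and additionally p lags
of the source (full), both by least squares over the same estimation
sample after per-segment demeaning, and `G = ln(RSS_red/RSS_full) ≥ 0`.
The default order is p = 13; `selectArOrder()` minimizes the mean BIC of
bivariate VAR fits over a common sample when the true order is unknown.
Pairwise (bivariate) rather than conditional GC is computed — all six
ordered region pairs are analyzed independently; conditional and spectral
GC are out of scope.

Small-sample bias makes G strictly positive even for independent series,
so raw significance is calibrated against the **cross-task artifact
null** (`artifactNull()`): target segments from the baseline rest period
are paired with source segments recorded at a different time during the
task. Any apparent interaction across such a pairing is spurious by
construction, and the within-task day mean is compared to this null by an
unpaired t-test.

Task-specific flow uses the baseline-normalized value
`(G_task − G_baseline)/G_baseline` — positive means stronger directed
interaction than at rest — and the **net** normalized value of a
reciprocal pair, `net(a→b) = norm(a→b) − norm(b→a)`, which is
antisymmetric by construction. An edge is *significantly directed* when
the across-day one-sample t-test of its net values survives Bonferroni
correction and the mean is positive in that direction. Interpretations
fixed here: baseline G is computed once per day and direction (baseline
windows carry no task events) and shared by both event types; the number
of baseline windows is matched to the smaller task trial count; the null
uses channel-averaged region series, as do all GC computations.

# The BMI simulator

The decoder is a velocity Kalman filter: state `x = [px, py, vx, vy, 1]`,
bin width 0.1 s, state-transition model `x(t+1) = A x(t) + w` and
observation model `y(t+1) = C x(t) + q`. `fitKfMl()` estimates A and C by
least squares and W, Q as residual covariances; the constant row of A is
fixed and, per the velocity-KF convention, the position columns of C are
zero — spikes inform velocity, position integrates. `kfStep()` is the
standard predict–update recursion; in closed loop the belief's position
components are re-anchored to the true cursor each bin (position
feedback).

`cldaSmoothBatch()` re-estimates only the observation model from a batch
of *intended* kinematics — intent being the current speed redirected along
the cursor-to-target unit vector, zero inside the target hold region — and
blends: `C ← λ C + (1−λ) C_batch`, likewise Q. Defaults λ = 0.5 with
40-trial batches give an adaptation horizon of a few minutes of task time
at 100 ms bins.

The task engine (`runCenterOut()`) runs the center-out state machine:
center acquisition (self-initiation), 0.25 s center hold, go cue, reach
within a 3 s timeout, 0.25 s target hold; failed targets repeat up to 10
presentations; directions are pseudo-randomized in blocks of eight. Hold
durations and the timeout are surfaced in `taskParams()` — they are
engine parameters, not measured quantities. A session time budget ends a
run whose controller cannot initiate trials.

`runCldaExperiment()` wires these into a learning experiment: fit the
decoder from a manual block (kinematic arm model + cosine-tuned Poisson
encoder), rotate the encoder's preferred directions by 0.9 rad to emulate
the tuning changes seen between manual and BMI control, then measure
closed-loop performance before and after three SmoothBatch updates. The
rotation default was chosen so the pre-adaptation decoder is impaired but
functional (success fraction near 0.5); smaller rotations leave no room
for improvement, larger ones prevent trial initiation altogether.

# The synthetic-data generator

`simulateStudy()` emulates a multi-day study with known ground truth:

* **latent layer** — one series per region at 1 kHz from a vector
  autoregression (shared AR(2) self-dynamics, default coefficients
  0.35/0.2) with configurable directed cross-coupling per task type.
  Configurations whose companion spectral radius reaches 1 are refused.
  Acyclic coupling graphs are generated by exact recursive filtering in
  topological order; cyclic graphs fall back to a sample-by-sample
  recursion.
* **channel layer** — each channel is its region's latent signal plus one
  oscillation per band (center frequency at the band's geometric mean,
  random phase per channel, stochastic AR(1)-smoothed amplitude
  modulation of ±50 % with ~2 Hz bandwidth) plus independent white noise,
  optionally plus an identical common-mode artifact on all channels.
  Amplitude modulation matters: deterministic constant-amplitude tones
  are phase-locked across channels for an entire session, which
  manufactures spurious bidirectional Granger causality.
* **task structure** — oscillation amplitudes depend on task type
  (default: theta elevated and beta suppressed during both control types
  relative to baseline, with a mild BMI/manual contrast), an extra
  DLPFC modulation at the go cue and M1 modulation at target acquisition
  distinguish the control types, and inside the 500 ms event windows the
  M1 beta/gamma amplitudes are cosine-modulated by target direction
  (depth 0.5, band-specific preferred angles so the two bands jointly
  identify all eight directions).
* **behavior** — manual success probability 0.92 with ~0.7 s reaches;
  BMI success rising from 0.60 by 0.02/day and acquisition time falling
  from 2.2 s by 0.04 s/day — qualitative learning curves, not fitted
  values.

Effect sizes are not reported quantities; they were chosen once so that
recovery is comfortable at roughly the study's per-day trial counts, and
they are deliberately arbitrary. Each session draws from its own RNG
stream derived from (seed, day, task type), so any single session can be
regenerated independently.

What the generator does **not** emulate: 1/f spectral shape (white noise
plus band oscillations only), biophysical dynamics, electrode drift,
artifacts other than the optional common-mode tone, spike-sorting noise,
and any dependence of LFP on the decoded cursor. Passing tests therefore
demonstrate correctness of the analysis pipeline on data with the stated
structure — not that real recordings satisfy that structure.

# Problem sizes used in validation

The test suite and `scripts/acceptance.R` run the full pipeline at sizes
chosen for a single-CPU desk run, stated here as the package's validation
design: referencing checks use one day with the 57-channel array;
classifier calibration uses 66 windows of one stationary session with
interleaved class labels (1000 permutations) — labels are exchangeable by
construction there, whereas a one-session-per-class layout embeds session
identity in the labels, a real signal the permutation null cannot
represent — plus twenty two-day studies for the contrast-localization
check; connectivity recovery uses forty 20-day replicates of a
stripped one-channel-per-region configuration (no oscillations,
noise SD 0.3, 10 trials/session) and a 1000-replicate zero-coupling
false-positive run at 6 days × 3 segments; decoder consistency uses 10^4
bins; closed-loop adaptation uses 20 seeds × 24-trial blocks. Defaults in
the generator itself (12 days, 120 trials/session, 18 channels) are the
emulated study conditions and are independent of these validation sizes.

# Known limitations

* Bivariate GC cannot distinguish direct from common-source influence;
  with three regions a strong A→B and A→C coupling can induce apparent
  B↔C structure. The artifact null calibrates bias, not confounding.
* The Welch grid makes theta a single-bin band; analyses that need finer
  low-frequency resolution should lengthen the window.
* QDA with 15 features needs tens of trials per class; below that the
  ridge fallback activates and accuracy estimates become conservative.
* The simulator's closed-loop learning is driven entirely by decoder
  adaptation; it does not model neural plasticity, so "learning stages"
  in synthetic studies reflect the configured behavioral drift only.
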