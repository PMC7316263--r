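---
title: "Methods: posturographic features, nested-CV risk models, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posturographic features, nested-CV risk models, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallrisk)
```

This vignette is the package's account of its science: what each quantity
is, which conventions were chosen where several are in use, what the
synthetic-data generator does and does not emulate, and which design
decisions were genuinely open.

## The measurement setting

A balance-assessment session on a robotic platform produces multichannel
time series at 30 Hz: the vertical force `fz` and the two horizontal torque
components `mx`, `my` from a 6-axis force-torque sensor under the foot
platform; the platform tilt angles `theta_ml`, `theta_ap`; trunk roll and
pitch and 3-axis trunk acceleration from a torso-worn IMU; and, in the
sit-to-stand test, the vertical force under the seat. Seven exercises are
assessed in fixed order: limits of stability (1), quiet standing with eyes
open (2) and closed (3), standing on an unstable platform that follows the
subject's sway up to ±10° (4), standing on a platform moving along a
pre-programmed circle (5), random toes-down/left/right perturbation pulses
(6), and five repetitions of sit-to-stand (7).

Coordinates: x mediolateral, positive right; y anteroposterior, positive
forward; trunk pitch positive in forward flexion; a toes-down platform
pitch is negative `theta_ap`. The simulator and the detectors share these
conventions.

## Stabilometric indicators

**Center of pressure.** CoP_x = mx/fz, CoP_y = my/fz, converted from
metres to cm. The ratio requires a loaded platform: any sample with
`fz` at or below the load floor (default 10 N) aborts with an
unloaded-platform error naming the first offending sample, rather than
producing arbitrarily large ratios.

**Sway area.** "The surface containing an individual point of the
statokinesigram with 95% probability" is implemented as the 95%
*prediction* ellipse under a bivariate normal model: area
$\pi\,\chi^2_{0.95,2}\,\sqrt{\det\hat\Sigma}$ with $\hat\Sigma$ the 2×2
sample covariance (divisor $n-1$). This is the standard posturographic
convention; SD-scaled ellipses exist in the literature but are a different
(smaller) object, and the coverage interpretation singles out the
prediction ellipse. A numerically negative determinant (collinear traces)
is clamped to zero. The coverage level is exposed as `conf`.

**Sway path** is the chord sum of the trajectory. It is invariant under
rigid motions, scales linearly, never decreases under refinement of a
sampled smooth curve, and converges to arc length — all verified as
property tests.

**Oscillation ranges** are max − min of the relevant coordinate: CoP x/y
for exercises 2–3 and 5, the platform projection for exercise 4, trunk
roll/pitch for the trunk ranges.

**Trunk variability** is the SD (divisor $n-1$) of the Euclidean norm of
the per-sample mean-centered 3-axis acceleration. The axis-combination
rule is not fixed by common usage, so the choice is pinned by a test (a
single-axis square wave has centered-norm SD 0, while per-axis SDs do
not vanish) and the per-axis SDs are emitted as auxiliary outputs.

**Exercise-4 source trace.** In the unstable condition the statokinesigram
is the *projection of the platform's angular displacement*. The package
maps angles to a planar trace by the small-angle arc length $d = R\theta$
with lever arm $R$ = 0.5 m by default, so the exercise-4 metrics carry
cm/cm² units like the others. $R$ is a scale convention, not physiology;
it multiplies all exercise-4 lengths by a common factor and is
configurable. For exercise 5 the platform moves by position control
independently of the subject, so its angle projection carries no subject
information; the CoP is used as the source trace there.

**Limits of stability.** The trace is re-zeroed to the mean of an initial
quiet window (default 2 s, configurable) and the four directional reaches
are the clamped extremes of the re-zeroed coordinates.

**Analysis durations** default to 80 s for exercise 1 and 30 s for
exercises 2–5. The protocol description mentions 20 s balance trials while
the processing description analyzes 30 s; the package follows the
processing convention and treats the 20 s figure as display/protocol
wording. Both are overridable via `duration_s`.

## Perturbation epochs and sit-to-stand phases

Onsets are detected on the total platform tilt magnitude relative to the
pre-task baseline, with threshold 0.5° and back-tracking to the last
sub-threshold sample; supra-threshold runs closer than 2 s are merged
(pulses are spaced ≥ 4 s by protocol). Direction comes from the dominant
signed axis at the excursion peak. Each event carries the epoch
[onset − 0.25 s, onset + 1.5 s]; range and peak features use the 1 s
analysis window, the stabilization time may use the full 1.5 s epoch
(whether the cap is 1.0 or 1.5 s is genuinely open; the package caps at
1.5 s, both configurable). Epochs extending past the recording end are
flagged truncated and excluded from aggregation rather than zero-filled.

With a Gaussian pulse of width $\sigma = t_{peak}/3$, the 0.5° crossing
sits ≈ 2 samples after the nominal onset at 30 Hz, which bounds the
detector's onset accuracy; epoch counts and window features are
unaffected.

**Stabilization time** (oscillation time): from the onset to the first
instant after the peak deviation at which the baseline-referenced trunk
angle stays within 20% of the peak deviation for 0.25 s continuously,
capped at the epoch end. No stabilization criterion is in common
circulation for this measure, so both the band fraction and the hold are
explicit parameters with these defaults. The baseline is the mean over
the 0.25 s pre-onset epoch segment.

**Sit-to-stand segmentation** alternates four boundary conditions: stand
start at the first trunk pitch above 15° while seated; stand end at the
first subsequent sample with at least 95% of the total vertical load on
the base platform and pitch back under 15°; sit start at the next
supra-threshold pitch; sit end when the seat load is back within 10% of
its seated baseline (mean over the first second) with pitch under 15°.
"Load completely on the base platform" had to be operationalized — 95% of
total load — as did the seat-return tolerance (10%); both are parameters.
A valid trial has exactly five cycles; fewer is an invalid-trial error,
mirroring the protocol's repeat rule. Durations are phase-boundary
differences; the total is first stand onset to last seat return.

## The risk model

Faller status (≥ 1 fall in the 12-month follow-up) is classified by
L1-penalized logistic regression, chosen for the p ≈ n regime where a
sparse linear model is both stabler and more interpretable than trees or
unpenalized logistic fits. Validation uses two nested loops of stratified
5-fold cross-validation: the inner loop evaluates a fixed penalty grid (25
values log-spaced over $[10^{-3}, 10^2]$ on standardized features) by mean
validation ROC AUC and resolves ties toward the larger penalty (sparser
model); the winning penalty is refit on the full outer-training partition
and scores the held-out fold. Standardization statistics are computed on
the training partition only; 0/1-encoded variables pass through unscaled;
zero-variance columns are dropped with a warning. Every subject is scored
exactly once per repetition by a model that never saw it — the fold
bookkeeping is asserted in the tests, and the permutation-null experiment
(AUC ≈ 0.5 on permuted labels) checks it empirically.

Metrics are computed on the probabilities pooled across outer folds
(one ROC curve), with per-fold AUCs reported for dispersion; a
`n_repeats` option averages reports over repartitions. The suite:

- **ROC AUC** by the Mann–Whitney statistic with ties counted ½, variance
  and 95% CI by the DeLong structural-components method (implemented in
  the package; cross-checked in the tests against both a bootstrap and an
  independent implementation).
- **Youden cutoff** over midpoints of adjacent distinct probabilities
  (rule: prob ≥ cutoff is positive), ties broken toward the lower cutoff,
  i.e. toward sensitivity; a degenerate all-equal prediction set is
  flagged.
- **Sensitivity, specificity, PPV, MCC** at that cutoff, with the usual
  MCC-is-zero rule when a denominator factor vanishes.
- **Mean precision** as average precision, the step-wise area under the
  precision–recall curve. This interpretation (rather than PPV at the
  operating point, which is also reported) matches the precision–recall
  curve the summary is paired with; it is flagged as an interpretation in
  the documentation.

Whether published operating points derive from pooled or per-fold cutoffs
is generally unstated; pooled is the default here and per-fold values are
recoverable from `tidy()`.

## Model comparison

NRI is computed in its continuous (category-free) form because no risk
categories are predefined in this setting: up/down movements are strict
probability increases/decreases (exact ties move neither way), and the
p-value is the asymptotic z-test with per-group variance
$(p_{up}+p_{down}-(p_{up}-p_{down})^2)/n$. Categorical NRI with
user-supplied thresholds is available as an option. IDI is the difference
in discrimination slopes with a paired z-test. Both take the
cross-validated out-of-fold probabilities, never in-sample refits.
Antisymmetry and the monotone-invariance of NRI (and its failure for IDI)
are property-tested.

## The synthetic-data generator

The generator defines the study conditions for every test: raw sessions
at the protocol's parameters and a feature-level cohort with the published
group structure.

**Platform trajectories.** Exercise 5:
$\theta_{ML} = A\sin(2\pi f t)$, $\theta_{AP} = A\sin(2\pi f t - \pi/2)$
with A = 2.5°, f = 0.2 Hz. Exercise 6: Gaussian-profile pulses peaking at
6° 330 ms after onset, three per direction in seeded random order, onset
gaps from a normal(4.7 s, 0.6 s) truncated below at 4 s (so the long-run
mean gap is 4.84 s, the truncation-adjusted value). Pulse width
$\sigma = t_{peak}/3$ puts the visible onset ≈ 3σ before the peak; the
peak-rate implied by these figures (6°/0.33 s ≈ 18°/s) sits slightly above
the nominal mean pulse velocity of ~16.5°/s quoted for such protocols, a
discrepancy the generator exposes via `pulse_sigma` rather than resolves.
The post-peak return (not specified anywhere) is the symmetric Gaussian
decay, completed within the epoch. Exercise 4 is a seeded bounded random
walk clipped at ±10°.

**Sessions.** The CoP is a stationary first-order autoregressive planar
process (1 s mean-reversion time; stationary SDs 0.30/0.40 cm ML/AP times
the subject's `instability`) — the simplest stationary process with
tunable variance, not a physiological model. Torques are back-computed
from the target CoP and the noisy vertical force, so `compute_cop`
recovers the generated CoP to machine precision (an exact round-trip used
as a test oracle). Trunk angles are a scaled copy of the CoP plus
independent noise; trunk acceleration is white noise scaled by
instability. Exercise 6 adds per-pulse critically-damped responses
$g\,(s/\tau)e^{1-s/\tau}$ whose analytic band-crossing time is the
settling-time oracle; exercise 7 emits piecewise-linear pitch/load
profiles whose continuous-time boundary solutions are the segmentation
oracle.

**Cohorts.** Outcomes are Bernoulli(1/3), matching a typical
community-dwelling one-year faller rate. Clinical variables are drawn per
group from the published baseline summaries (fallers vs non-fallers): age
N(79.1, 6.6) vs N(76.2, 6.3); gait speed N(0.95, 0.22) vs N(1.08, 0.28)
truncated above 0.2 m/s; fall history Bernoulli(0.875) vs (0.625); drug
count rounded N(3.88, 2.17) vs N(3.73, 2.61) clipped at 0; sex (female)
Bernoulli(0.688) vs (0.625); TUG, POMA and SPPB from the corresponding
summaries clipped to instrument ranges. The 46 robotic features (the
canonical catalogue: 4 LOS reaches, 7 indicators × 4 balance exercises,
11 perturbation features, 3 sit-to-stand durations) are standardized
multivariate normal with exchangeable correlation ρ = 0.2 and
faller mean shifts given by `effect_sizes`. The default shift pattern
follows the observed direction of group differences — positive 0.5 SD on
the exercise-4/5 ranges and variabilities and the ML perturbation tilt,
negative 0.5 SD on the forward LOS reach — 0.5 SD being a moderate
posturographic group difference. The generative truth (shift vector,
optimal discriminant $\Sigma^{-1}\delta$, theoretical AUC
$\Phi(\sqrt{\delta'\Sigma^{-1}\delta/2})$) is attached to the table.

**What the generator does not emulate.** Nonstationary fatigue or
learning effects; non-Gaussian heavy-tailed sway; frequency structure of
real CoP spectra; missing sessions and artifacts; any dependence between
clinical and robotic blocks beyond the shared outcome. Passing tests
therefore certify the *pipeline* — definitions, windows, thresholds,
cross-validation plumbing, estimator correctness — not the clinical
effect sizes obtainable on real cohorts, and the published cohort-level
AUCs are not reproducible desk-side because the patient data are not
public.

## Validation experiment sizes and numerical choices

Chosen as the package's own validation design: the ellipse-area oracle
uses $10^5$ bivariate normal draws (Monte-Carlo error well under the 5%
assertion); the DeLong-vs-bootstrap check uses $10^4$ replicates at
n = 100; the permutation null averages 20 seeded repartitions at n = 500;
the generative-AUC recovery experiment uses five replicate n = 500
cohorts with uncorrelated features and the model restricted to the
planted-signal variables — that way the sparse logistic class contains
the optimal rule and the theoretical AUC (0.80) is actually attainable,
while averaging over cohorts controls the ≈ 0.02 SD of a single cohort's
empirical optimum. The Fisher-exact oracle sweep enumerates every 2×2
table with N ≤ 60 up to row/column-swap symmetry (the exact p is
invariant under those swaps). Ties in the hypergeometric two-sided sum
use the conventional $(1+10^{-7})$ relative slack. Equality tie-breaks:
inner-loop penalty ties go to the sparser model; Youden ties to the lower
cutoff; AUC ties in menu selection to the smaller variable count
(tolerance 0.005 by default). Degenerate inputs (single-class prediction
sets, unloaded platforms, missing channels, sub-5-cycle trials) raise
classed conditions rather than returning quiet NAs.

## Known limitations

- The exercise-4 lever arm and the trunk-variability axis rule are
  conventions; absolute exercise-4 areas/lengths and VA magnitudes are
  comparable within the package, not across instruments.
- The stabilization-time defaults (20% band, 0.25 s hold) shift the
  absolute oscillation times; comparisons across parameterizations are
  not meaningful.
- Continuous NRI is sensitive to arbitrarily small probability movements
  by construction; the IDI and the categorical NRI option are the
  magnitude-aware complements.
- The asymptotic NRI/IDI p-values rely on normal approximations that thin
  out below ~20 subjects per group (the bootstrap agreement test runs at
  100 subjects).
- With strongly correlated feature blocks the lasso's selection is
  unstable in p ≈ n regimes; the nested design keeps the *performance
  estimate* honest, but the selected variable identities should be read
  with the usual caution.
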