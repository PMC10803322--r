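---
title: "Whole-body kinematic networks: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body kinematic networks: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinectome)
```

## The kinectome model

Marker-based gait analysis usually reduces a recording to segmental
summaries (a joint angle, a stride time). The kinectome instead treats
the walking body as a network: the nodes are 21 reflective markers on
anatomical landmarks (head, C7, T10, acromions, lateral elbows and
wrists, iliac crests, greater trochanters, lateral knees and ankles,
heels, fifth metatarsals), and the edge between markers $i$ and $j$ on a
movement axis is the Pearson correlation $W_{ij}$ between their
acceleration time series over a gait cycle. Per trial this gives three
$21 \times 21$ symmetric matrices (mediolateral ML, anteroposterior AP,
vertical VT), each with unit diagonal and $N(N-1) = 420$ ordered
off-diagonal edges. Over a patient's two medication conditions (off =
overnight withdrawal of antiparkinsonian treatment, on = after a
levodopa dose) that is six kinectome types per trial.

The topological summary is the nodal strength
$$S_i = \sum_{j \ne i} |W_{ij}|,$$
bounded by $N-1$: how synchronised one body landmark's acceleration is
with the rest of the body. Strengths are averaged across a condition's
trials (four by default) before any statistics.

Downstream, the package provides (i) a paired, per-node, per-axis
two-sided Wilcoxon signed-rank comparison of trial-averaged strength
between conditions with Benjamini–Hochberg false discovery rate control,
and (ii) an ordinary least squares model predicting the clinical motor
change $\Delta\mathrm{UPDRS\text{-}III} = \mathrm{UPDRS}_{off} -
\mathrm{UPDRS}_{on}$ from nodal-strength changes of selected nodes plus
nuisance covariates (age, gender, education, disease duration), with
variance inflation screening and 5-fold cross-validation repeated 100
times.

## Processing chain and its conventions

The preprocessing order is fixed and deliberate:

1. **Gap interpolation.** Occluded runs of at most 10 frames are filled
   by a cubic interpolating spline (FMM end conditions, exact for
   polynomials up to cubic) through the valid frames of each axis;
   longer gaps, or gaps touching the trial boundary, reject the trial
   with a report. No extrapolation is ever performed.
2. **Axis remapping.** Laboratory axes are mapped onto ML/AP/VT by an
   explicit, possibly sign-carrying bijection. The acquisition system's
   axis convention is configuration, not a guess.
3. **Low-pass filtering** of the whole trial with a 4th-order
   Butterworth design, 10 Hz cutoff, applied forward and backward.
   Zero-phase filtering is the field's standard because phase lag would
   shift event timing; the effective magnitude response is the square of
   the single-pass response and the nominal cutoff is kept at 10 Hz
   without a double-pass correction. Edges are padded by odd reflection
   long enough (thirty filter orders) for each pass to settle; each pass
   is initialised at the steady state of its first padded sample, so a
   constant signal is reproduced exactly and filtering commutes with
   time reversal to numerical precision. Filtering the complete trial
   *before* segmentation keeps edge transients outside the analysis
   window.
4. **Heel-strike detection and segmentation.** Heel strikes are local
   minima of the heel marker's VT coordinate that coincide (within ±5
   frames) with the heel's AP velocity crossing from positive to
   non-positive — the forward motion of the heel stopping at ground
   contact. Candidates closer than a 0.4 s refractory period are merged,
   keeping the lower minimum. This detector is an explicit algorithmic
   stand-in for manual event identification; curated events can be
   supplied from a file and bypass it. The analysis window runs from the
   first strike of the leading foot to the second subsequent strike of
   the contralateral foot: one complete gait cycle per leg.
5. **Double differentiation** of the segmented window by a
   first-derivative operator applied twice (central differences, with
   second-order one-sided stencils at the endpoints so the length is
   preserved). The scheme is exact for quadratics; for a 1 Hz tone at
   120 frames/s the truncation error is below 0.1 % of the acceleration
   amplitude.

Whether accelerations should be computed before or after segmentation,
and whether filtering should be zero-phase, are genuinely open
conventions in this kind of pipeline; the choices above are fixed and
documented rather than configurable, because changing them mid-study
would silently change every downstream number. Correlations are
computed over the full segmented window (both cycles) per trial rather
than per single cycle; the per-trial window uses all available samples
and keeps one correlation estimate per trial to average.

## Statistical conventions

* A Kolmogorov–Smirnov screen of standardized values against the
  standard normal is reported per node/axis, but it is advisory: the
  comparison always proceeds nonparametrically. Standardizing with
  sample moments makes the screen conservative, which is acceptable for
  a screen that never gates anything.
* The signed-rank test drops zero differences (Wilcoxon's original
  treatment) and uses the exact null distribution when at most 25
  untied non-zero differences remain — the n = 23 cohort sits in the
  exact regime when untied — otherwise the normal approximation with
  continuity and tie correction.
* The FDR family is the 21 nodes within one axis, matching per-axis
  reporting; a pooled family across axes is available as an option.
  Benjamini–Hochberg is the default; Benjamini–Yekutieli is offered for
  arbitrary dependence.
* VIF flags predictors above 5 (a common rule of thumb) but never drops
  them automatically; a perfectly collinear predictor is reported as
  infinite VIF rather than crashing.
* Cross-validation partitions subjects into folds whose sizes differ by
  at most one (23 subjects, k = 5 gives {5,5,5,4,4}), without
  stratification. The per-repetition summary is the pooled out-of-sample
  predicted-vs-actual Pearson correlation and RMSE, reported as mean ±
  SD over repetitions; raw and standardized coefficients are both
  reported because either scale may be wanted. If a binary covariate is
  constant within a training fold its coefficient is inestimable there;
  it then contributes nothing to that fold's held-out predictions.

## What the synthetic cohort emulates

Clinical motion-capture data of this kind are not publicly
distributable, so validation runs on a synthetic cohort with known
ground truth. The generator reproduces the study design — 23 subjects ×
2 conditions × 4 trials of two consecutive gait cycles, 21 markers ×
3 axes at 120 frames/s — and a mechanistic caricature of the clinical
phenomenon:

* Each marker/axis carries a deterministic private waveform: a sinusoid
  at the subject's stride frequency (drawn uniformly from 0.8–1.1 Hz)
  and/or its first harmonic, with anatomically motivated phases (left
  and right limbs anti-phase; arms anti-phase to the ipsilateral leg;
  trunk sway at stride frequency; pelvis and trunk AP/VT at step
  frequency). Heel, ankle and toe AP waveforms are stride-locked to the
  walking speed (1.1 m/s by default) so that heel-strike events exist at
  known phases; the heel's AP velocity crosses zero exactly at the
  planted strike phase, which is what the detector looks for.
* Two body groups receive an additive shared latent component (a sum of
  five random sinusoids in 0.6–5 Hz with equal acceleration weight):
  the trunk markers on ML, weighted by `trunk_coupling`, and the
  elbow/wrist/knee markers on AP, weighted by `limb_coupling`. Defaults
  are off = 0.9 / on = 0.3 for the trunk and the mirror image for the
  limbs: medication relaxes trunk hypersynchronisation and improves
  limb coordination. Because the coupling is an additive shared
  component, the noise-free correlations — and hence true nodal
  strengths — are computable directly from the generator's analytic
  accelerations.
* Coupling weights get per-subject, per-condition, per-marker Gaussian
  jitter (SD 0.15, clipped to [0,1]). This is the between-subject
  heterogeneity that gives nodal-strength deltas non-zero variance
  across subjects; without it the clinical regression would have
  constant predictors. Private amplitudes carry a mild per-subject
  log-normal anatomical jitter (SD 0.1), except the stride-locked
  components above.
* White measurement noise (SD 0.3 mm, ~2 % of a typical waveform
  amplitude) is added to every coordinate. Noise on positions is
  amplified strongly by double differentiation, which is exactly why
  the 10 Hz low-pass stage exists; the generator reproduces that
  trade-off.
* The clinical change is generated from the truth:
  $\Delta\mathrm{UPDRS} = \beta_0 + \sum_k \beta_k \Delta S^{true}_k +
  \varepsilon$, with designated nodes RLELB (−1.0), LLELB (−0.8), RWRB
  (+0.9) on AP, a baseline response $\beta_0 = 10$ points (so off/on
  score levels resemble a realistic levodopa response), and
  $\varepsilon \sim N(0, 0.8)$ points. Off and on scores are then
  chosen consistent with the delta and non-negativity. Age, gender,
  education and disease duration are drawn from distributions matching
  a typical cohort of this size and act as nuisance covariates only.

One global seed governs everything; measurement noise lives on a
derived sub-stream so that ground truth and the clinical table are
bit-identical whether or not trajectories are materialised. The
generator can therefore serve two validation regimes: the full chain
(trajectories → preprocessing → kinectomes → statistics) and a fast
analytic regime operating on true strengths.

**What passing tests do and do not show.** The synthetic cohort has
band-limited, phase-locked, stationary waveforms, no soft-tissue
artefact, no marker relabelling errors, gaps only where tests plant
them, and coupling that enters as a literal shared additive component.
Real gait violates all of these to some degree. Passing the validation
suite shows that the pipeline's arithmetic and inference behave as
specified under a known truth — not that the biological effect sizes or
the regression's $R^2$ on real patients would match. One consequence is
visible already in synthetic data: pipeline-estimated strength deltas
correlate ~0.5–0.8 with the true deltas at this window length, so
regression coefficients on estimated deltas are attenuated and, with
correlated predictors, individually unstable at n = 23, even though the
same model on true deltas recovers every coefficient sign. Another is
that the shared-component mechanism produces secondary true effects
beyond the planted groups: adding shared variance to the trunk changes
trunk–limb correlations too (absolute-value strength is positively
biased by any shared variance), so on some seeds more ML nodes than the
five trunk markers differ genuinely between conditions. The paired test
is reporting the synthetic model faithfully, not false-positiving.

## Validation suite and problem sizes

The test suite validates every statistical primitive against an
independent brute-force oracle: correlation matrices against a textbook
double loop (≤ 1e−12, 1000 random instances), nodal strength against
explicit row sums, Benjamini–Hochberg against the literal step-up
definition, VIF against normal-equations auxiliary regressions, and the
exact Wilcoxon branch against full $2^n$ sign enumeration. Signal
processing is checked analytically (quadratic → constant acceleration;
a 30 Hz tone attenuated > 40 dB by the 10 Hz zero-phase filter;
time-reversal symmetry).

The replicate studies use the study-design size of 23 subjects: 50
full-pipeline cohorts for detection power of the trunk contrast (T10 on
ML, off > on at pFDR < 0.05), 200 cohorts with equal couplings for
false-positive calibration, and 50 cohorts each at n = 23 and n = 100
for clinical coefficient sign recovery. The calibration and recovery
replicates run on the generator's analytic true strengths — the null
holds by construction on either route, and the full signal-processing
chain is already exercised by the 50 power replicates — which keeps the
whole suite's run time modest.

## Known limitations

* The heel-strike detector assumes a forward-progressing heel with a
  clear AP velocity reversal; shuffling gait or treadmill data may need
  curated event files.
* C3D files are not parsed; trials must be exported to the tabular
  dialect (`write_trajectories()` documents it precisely).
* The edge-thresholding in `render_network_figure()` (top 15 % of
  ordered edges, i.e. the ceiling half as undirected edges with ties
  broken by matrix order) is purely presentational; statistics always
  use all 420 edges.
* Nodal strength is the only graph statistic implemented; betweenness,
  clustering or modularity summaries are out of scope.
* The regression is deliberately plain OLS: no regularisation, no model
  selection, no bootstrap intervals.
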