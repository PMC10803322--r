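# kinectome

Whole-body kinematic network analysis of marker-based gait recordings,
with a focus on quantifying how levodopa changes movement coordination
in Parkinson's disease.

Conventional gait metrics are segmental: a stride time, a joint angle, a
trunk sway amplitude. This package instead treats the walking body as a
network. The nodes are 21 reflective markers on anatomical landmarks
(head, C7, T10, acromions, elbows, wrists, iliac crests, trochanters,
knees, ankles, heels, fifth metatarsals); the edge between markers *i*
and *j* on a movement axis is the Pearson correlation *W<sub>ij</sub>*
of their acceleration time series over a gait cycle. Per trial this
yields three symmetric 21×21 matrices — the **kinectomes** for the
mediolateral (ML), anteroposterior (AP) and vertical (VT) axes — with
unit diagonal and N(N−1) = 420 ordered off-diagonal edges. The nodal
strength

&nbsp;&nbsp;&nbsp;&nbsp;*S<sub>i</sub>* = Σ<sub>j≠i</sub> |*W<sub>ij</sub>*|

summarises how synchronised landmark *i* is with the rest of the body,
and is averaged across a condition's trials before inference.

The package covers the full workflow for a within-subject medication
study (off vs on state):

* **trajectory IO** — a plain-text tabular trajectory dialect with YAML
  sidecars, marker alias maps, explicit lab-axis → ML/AP/VT remapping;
* **preprocessing** — cubic-spline gap filling (max 10 frames),
  zero-phase 4th-order Butterworth low-pass at 10 Hz, algorithmic
  heel-strike detection (with curated-event override), segmentation to
  one complete gait cycle per leg, double differentiation to
  accelerations;
* **network construction** — per-axis kinectomes, nodal strength, trial
  averaging;
* **group statistics** — paired two-sided Wilcoxon signed-rank tests
  per node (exact branch for ≤ 25 untied pairs), Benjamini–Hochberg FDR
  within each axis, directions by median difference;
* **clinical prediction** — OLS of ΔUPDRS-III (off − on) on
  nodal-strength deltas plus age, gender, education and disease
  duration, with VIF screening and 5-fold cross-validation repeated 100
  times;
* **synthetic cohorts** — a generator that reproduces the study design
  (23 subjects × 2 conditions × 4 trials × two gait cycles at 120
  frames/s) with known coupling structure and clinical scores tied to
  the true nodal-strength changes, so every stage can be validated
  against ground truth.

## Worked example

Simulate a cohort at the study design size, run the pipeline, and
compare conditions:

```r
library(kinectome)

coh <- generate_cohort(cohort_config(seed = 7))
cs  <- cohort_strengths(coh$trajectories)   # preprocess + kinectomes + strengths
cmp <- compare_conditions(cs$strengths, alpha = 0.05)
head(subset(cmp, significant & axis == "ML"), 5)
#>   axis node n_pairs W_statistic        p_raw median_off median_on        p_fdr significant direction
#> 1   ML   HE      23         276 2.384186e-07   6.308703  3.657621 1.668930e-06        TRUE    off>on
#> 2   ML   C7      23         276 2.384186e-07   6.355315  3.602444 1.668930e-06        TRUE    off>on
#> 3   ML  T10      23         274 7.152557e-07   6.183327  3.682421 3.004074e-06        TRUE    off>on
#> 4   ML  LAC      23         276 2.384186e-07   6.219769  3.870677 1.668930e-06        TRUE    off>on
#> 5   ML  RAC      23         275 4.768372e-07   6.480984  3.865881 2.503395e-06        TRUE    off>on
```

The five trunk nodes (HE, C7, T10, LAC, RAC) are flagged on the ML axis
with higher strength in the off state — the generator's planted trunk
hypersynchronisation, relaxed by the simulated medication — at false
discovery rate below 0.05 on 23 paired subjects (`W_statistic` is the
sum of positive ranks; 276 is its maximum at n = 23, i.e. every subject
decreased).

The clinical stage regresses ΔUPDRS-III on the designated arm nodes'
AP strength deltas. On the generator's analytic ground-truth strengths
the planted coefficients (−1.0 RLELB, −0.8 LLELB, +0.9 RWRB) are
recovered:

```r
d  <- assemble_deltas(coh$ground_truth$true_strengths, coh$clinical,
                      c("RLELB", "LLELB", "RWRB"), axis = "AP")
fit_multilinear(d)
#> <clinical_model> n = 23, R^2 = 0.931
#>                 predictor      beta beta_std  p_value
#> 1             (Intercept) 11.046049       NA 2.00e-08
#> 2             delta_RLELB -1.093565  -0.8004 3.71e-08
#> 3             delta_LLELB -0.740695  -0.4421 1.23e-04
#> 4              delta_RWRB  0.733730   0.3766 4.81e-04
#> ...
```

Fitting the same model on the *pipeline-estimated* deltas instead gives
R² ≈ 0.26 with unstable individual coefficients: strength deltas
estimated from a 1.5-stride window carry measurement error that
attenuates a 23-subject regression. The package reports both routes so
this attenuation is visible rather than hidden; see the methods
vignette (`vignettes/kinectome-methods.Rmd`) for the full discussion.

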