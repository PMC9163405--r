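---
title: "Dynamic functional-connectivity states: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional-connectivity states: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`dynfc` implements a complete dynamic functional-connectivity (dFC)
analysis for resting-state network time courses: post-ICA time-course
cleaning, tapered sliding-window covariance estimation with
graphical-LASSO regularization, k-means decomposition of windowed
connectivity into recurring whole-connectome *states*, temporal-occupancy
metrics of those states, binarized graph-theory metrics with their
variance over time, and the group-comparison / brain-behavior correlation
statistics that sit on top. Because studies of this kind rarely deposit
subject-level data, the package also ships a generative model of
state-switching network time courses, so every stage of the pipeline is
testable end to end against a known ground truth.

The intended user is a neuroimaging researcher who has already run group
ICA and has, per subject, a timepoints x networks matrix of component
time courses (here: 14 networks x 170 retained volumes at TR = 2 s) plus
a table of subject covariates.

## Time-course cleaning

`preprocess_timecourse()` applies, in order:

1. **Polynomial detrending** (`detrend_poly()`): joint least squares on
   an orthogonal polynomial basis up to cubic order. Joint fitting makes
   the result independent of the order in which trends are removed.
2. **Despiking** (`despike()`): a running-median filter (window 11
   TRs) with clipping at 4 local MADs. The local MAD is floored at 1e-9
   so that constant stretches still pull an isolated spike back to the
   running median. This is a transparent, parameter-explicit surrogate
   for AFNI-style despiking, which does not publish a closed-form rule.
3. **Nuisance regression** (`regress_nuisance()`): least-squares
   residuals on an intercept plus confound columns (typically the six
   rigid-body motion parameters).
4. **Low-pass filtering** (`lowpass_filter()`): order-5 Butterworth at
   0.15 Hz, applied forward and backward (zero phase) with odd
   reflection padding. Zero-phase filtering preserves the timing of
   windows relative to the underlying signal.

## Windowed FC estimation

`tapered_window_spec()` defines the window: a 22-TR rectangle (44 s at
TR = 2 s) convolved with a Gaussian (sigma = 3 TRs, truncated at 4
sigma, 'same' mode), normalized to sum 1, slid by 1 TR. With 170
timepoints and the drop-last placement convention this yields 148
windows; the alternative `n_minus_w_plus_1` convention is available by
configuration. 20- and 30-TR windows are the conventional robustness
settings (`run_config("val20")`, `run_config("val30")`).

Per window, `dynamic_fc()` computes the taper-weighted covariance,
regularizes it with the graphical LASSO, converts the regularized
covariance to correlations, and applies the Fisher r-to-z transform
(with r clipped to 1 - 1e-7 so z stays finite). Edges are stored in a
fixed upper-triangle row-major order shared by all subjects, windows and
files.

The graphical-LASSO solver (`graphical_lasso()`) is a block
coordinate-descent implementation of the Friedman-style estimator in
which the L1 penalty also applies to the diagonal (the regularized
covariance is `S + rho I` on the diagonal); this is the convention of
the toolbox lineage this pipeline follows. The subject-level penalty is
chosen by `select_penalty()`: 50 random splits of the windows, fitting
on the mean training-window covariance over a small grid and scoring
held-out Gaussian log-likelihood. Choosing one penalty per subject
(rather than per window) keeps the sparsity pattern comparable across a
subject's windows.

`residualize_covariates()` removes age, sex, education and mean
framewise displacement from every (window, edge) cell by across-subject
linear regression on z-scored covariates, returning residuals plus the
grand intercept. Per-cell regression is the only dimensionally
consistent way to residualize subject-level covariates out of
window-level data.

## State decomposition

`kmeans_l1()` clusters all subjects' windowed edge vectors with the
Manhattan (L1) distance and element-wise-median centroid updates — the
median is the exact minimizer of summed L1 distance, making the
objective non-increasing at every step. The two-pass scheme (100 random
initializations keeping the best objective, then a final re-clustering
of all windows from those centroids) mirrors standard dFC practice.
Assignment ties go to the lowest state index; empty clusters are
re-seeded from the window farthest from its centroid; final labels are
renumbered by descending occupancy so "State 1" is always the most
visited.

`elbow_select_k()` scans k over a range (default 2:10), computing the
ratio of within- to between-cluster distance, and locates the elbow by
a first-plateau rule: k is increased while the ratio still improves by
more than a small fraction (`rel_tol`, default 0.5%) of its current
value, and the last k that brought a real improvement is returned. The
rule was chosen over curvature-based formalizations because in windowed
FC data the within-cluster noise radius is comparable to the
between-state separation, so the ratio declines only gently and then
levels off (or rises) right after the true k — a plateau onset, not a
sharp bend — while the absolute sizes of the early drops carry no
information about k. The scan is best run on `exemplar_windows()` —
windows at local maxima of each subject's connectivity deviation, which
fall mid-dwell and away from state boundaries — rather than on the
full, transition-diluted pool; large inputs are additionally subsampled
(default cap 5000 windows, deterministic given the seed).

Temporal metrics (`temporal_metrics()`) are fractional windows
(occupancy), mean dwell time (mean length of maximal consecutive runs,
in windows) and the number of transitions (adjacent label changes).
They satisfy exact identities — fractions sum to 1, dwell times times
run counts sum to the window count, transitions equal runs minus one —
which the test suite checks on random sequences.

`subject_state_centroid()` uses the element-wise median over a
subject's windows in a state (missing, not zero, if the subject never
visits it); group centroids average the subject centroids.
`match_states()` aligns centroid sets from different runs (e.g. window
lengths) greedily by highest Pearson correlation, warning when the
greedy match is not a bijection. `top_fraction_edges()` keeps the
strongest 5% of edges by absolute value (ceiling convention, ties by
the fixed edge order) for display.

## Graph metrics over time

`binarize_sparsity()` keeps the `round(S x E)` largest strictly positive
edges (round half-to-even; ties by the fixed edge order) across a
sparsity grid of 0.20 to 0.30 in steps of 0.01. Negative correlations
are never used. `global_metrics()` computes global efficiency, local
efficiency, clustering coefficient and characteristic path length on
the binary graph; path length averages over *connected* pairs only
(with the disconnected-pair count reported), while global efficiency
handles disconnection naturally through zero inverse distance.
`normalized_metrics()` forms gamma, lambda and sigma = gamma/lambda
against 100 degree-preserving Maslov-Sneppen rewirings (10 x |edges|
swap attempts each, seeded); when a graph admits no rewiring, or both
the observed and null values are zero, the ratio is defined as 1.
`auc_over_grid()` integrates each metric over the grid (composite
trapezoid; a rectangle rule is available), and
`dynamic_metric_variance()` takes the unbiased sample variance of the
per-window AUCs over time — the quantity whose group differences index
the flexibility of network topology. Because the normalized metrics
require a null ensemble per window and threshold, they are optional in
the variance sweep (`n_null = 0` skips them); the four unnormalized
metrics are computed by a compiled all-pairs-BFS core fast enough for
hundreds of thousands of windowed graphs.

## Statistics layer

`kruskal_wallis()` (tie-corrected, chi-square reference) and
`ancova_edge()` (partial F of the group factor over nuisance
covariates) are the omnibus tests; `fdr_bh()` applies Benjamini-
Hochberg step-up correction; `posthoc_pairwise()` runs pairwise
Wilcoxon rank-sum (after Kruskal-Wallis) or pairwise two-group ANCOVA
(after ANCOVA) with FDR over the pairwise family;
`partial_correlation()` correlates residuals after removing covariates,
with a two-tailed t test on n - p - 2 degrees of freedom.

Disease duration is undefined for healthy controls yet belongs to the
patient-comparison covariate set. `ancova_edge()` therefore supports two
modes: `impute_centered` (duration centered within patients, zero for
controls; the default, flagged in the output) and `drop`. Neither is
asserted to be "the" field convention — the choice is exposed because
the underlying design question is genuinely ambiguous.

## The synthetic cohort generator

`synth_spec()` defines a hidden-Markov covariance-switching model: at
every timepoint a latent state (k = 4 by default) evolves by a per-group
transition matrix; observations are drawn from the active state's
correlation matrix, smoothed by an AR(1) filter
(`y_t = phi y_{t-1} + sqrt(1 - phi^2) e_t`, preserving the marginal
covariance) and perturbed by isotropic noise. Defaults: 14 networks, 170
timepoints, TR 2 s, `noise_sd = 0.2`, `ar_coeff = 0.3` (typical BOLD
smoothness at TR = 2 s). States switch per timepoint rather than per
window because overlapping windows make a per-window truth ill-defined;
windows inherit the majority label (ties toward the lowest state index),
and `ground_truth_temporal_metrics()` maps the per-timepoint truth onto
the window grid as the oracle for recovered metrics.

The four default states (see `default_block_design()`) realize a
segregation/integration contrast: a modular state of positive cliques, a
triangle-free hub state, a saturated DMN-dominant state whose strong
positive edges fill the binarization threshold, and a weakly connected
state whose windowed graphs are noise-dominated. This serves two
purposes. First, the states are far apart in edge space (L1 centroid
separations of roughly 12-20 z-units), so clustering can recover them.
Second, they differ in binarized-graph topology and in the *stability*
of their thresholded edge set, so that switching between states — and
dwelling in the saturated state — moves the efficiency metrics and
their variance over time. A subtlety worth knowing: with 22-TR windows
the extreme order statistics of the ~70 null edges rival individual
signal edges, so windowed binarized graphs regress toward a common noise
baseline; states therefore need many strong (or deliberately few)
positive edges for their topological character to survive windowing.

Group effects are configuration, not hard-coded science: per-group
leave rates give healthy controls the most state switching and
hemodialysis patients the least, with State 3 progressively stickier
(longer dwell, higher occupancy) across the same gradient; within-DMN
edges of State 3 are multiplicatively weakened in patients (factor 0.8
non-dialysis, 0.6 hemodialysis); and cognitive scores are linear in
each subject's true switch count and State-3 occupancy with additive
Gaussian noise, with coefficients anchored so that group means land near
typical clinical values. The transition calibration was chosen jointly
so that (a) the windowed transition counts fall across the group
gradient with wide relative gaps, (b) State-3 occupancy rises across
the gradient, and (c) scans stay smooth enough for windowed states to
remain recoverable — windows that straddle a state boundary are
genuinely ambiguous, and their share grows with the switch rate. What
the generator does *not* emulate: voxel-level BOLD, hemodynamic
responses, scanner noise spectra, head-motion artifacts, spatial maps,
or within-state covariance drift (states are fixed matrices). Passing
recovery tests on this model therefore demonstrates correctness of the
pipeline, not performance on real scanner data.

Raw block designs need not be positive definite; `build_state_covariances()`
applies a nearest-SPD repair (eigenvalue clipping with rescaling to unit
diagonal, escalating jitter if needed) and records the Frobenius repair
distance on each matrix.

## Numerical choices and degenerate inputs

* Fisher z clips r at 1 - 1e-7; correlations of identical signals stay
  finite (z about 8.4).
* The glasso duality gap is reported for the diagonal-penalized problem
  (`tr(S Theta) - p + rho ||Theta||_1`); non-convergence raises an error
  with the gap value.
* Window weights are renormalized to sum 1; correlation is
  scale-invariant, but the weighted mean removal requires normalized
  weights.
* k-means ties (assignment and majority votes) resolve to the lowest
  index; the binarization tie-break is the fixed edge order; edge counts
  use round-half-to-even.
* Constant covariates are dropped from residualization (only the
  intercept is fitted); collinear nuisance designs raise an error naming
  the columns.
* Empty binarized graphs (no positive edges) warn and return isolated
  nodes.

## Validation experiments and problem sizes

Two simulation experiments are packaged as functions so they can be
rerun directly. `cohort_state_recovery()` simulates the default
50/50/64-subject cohort, runs the full windowed-FC pipeline (CV-selected
penalty, residualization) and scores recovered window labels against
the windowed ground truth by adjusted Rand index, alongside an elbow
scan over k = 2..10 on subsampled pooled windows.
`effect_recovery_trial()` runs a scaled-down replicate (26/26/30
subjects, unregularized windowed FC, 5 k-means restarts) of the whole
analysis and reports which qualitative group findings are recovered:
the group gradient in transition counts and in E_glob/E_loc AUC
variance, and the signs of the dwell-cognition and
transitions-cognition partial correlations. Gradient recovery is
reported in two forms: the direction of the monotone trend over the
ordinal group levels (the quantity a group-trend test estimates) and
the strict ordering of the three sample group means. The strict form is
brittle by construction: with 170 timepoints a scan realizes only about
six state visits, so per-subject occupancy — and hence the variance of
the efficiency AUCs — fluctuates strongly around its group expectation,
and one noisy group mean breaks the triple ordering even when the trend
is clearly recovered. The scaled sizes are the package's own choice of
experiment design: large enough that trend directions are determined by
the injected effects rather than sampling noise, small enough that a
hundred replicates run in minutes. The
statistics layer is additionally calibrated on null simulations (type-I
error of Kruskal-Wallis and ANCOVA at alpha = 0.05 over 2000 draws with
50 subjects per group).

## Known limitations

* The windowed-majority ground truth and the blend-tipping point of an
  estimated window do not coincide exactly at state boundaries
  (taper weighting, AR(1) lag), so label recovery has an intrinsic
  error floor proportional to the switch rate; recovery quality should
  be read with that in mind.
* Only one penalty per subject is selected; window-specific sparsity is
  not modeled.
* Normalized small-world metrics on near-empty or star-like graphs fall
  back to documented conventions (ratio 1) rather than failing.
* The statistics layer treats windows as exchangeable within a subject;
  it does not model the strong overlap-induced autocorrelation between
  neighboring windows beyond working at the subject level.
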