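---
title: "Models and methods behind numdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind numdecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

numdecode implements the group-analysis chain of a two-group numerosity
fMRI study — univariate ROI tests, multivoxel decoding at three spatial
scales, and seed-based functional connectivity — together with a synthetic
cohort generator that makes every stage testable and calibratable without
scan data. This vignette explains the models, the defaults and why they
were chosen, the numerical decisions, and what the synthetic results do and
do not show about real data.

## The experimental design being modelled

A run is a short-block design: 8 conditions (numerosities 2/4/6/8 shown as
digits or as dot arrays), each presented in 6 blocks of 4, 5 or 6 s; an 8-s
fixation block opens and closes the run and one interleaved fixation block
follows every 8th experimental block. The published totals (48 experimental
blocks, 7 fixation blocks, 280 s per run) only pin down the block
*durations* up to a balancing rule, which the sources leave unstated. We
adopt the unique symmetric choice: each condition's six blocks use the
multiset {4, 4, 5, 5, 6, 6} s (two copies of the {4, 5, 6} triple, so every
condition totals 30 s), and the five interleaved fixations use
{4, 4, 5, 5, 6} s (24 s total), giving 2 x 8 + 240 + 24 = 280 s exactly.
Block order and the assignment of durations to blocks are seeded random
permutations; `generate_run_schedule()` is bit-reproducible given its seed.
Impossible balancing requests (duration sets that cannot reach the target
sum) raise a configuration error rather than silently unbalancing.

## First-level model

`build_design_matrix()` represents each condition as the fraction of every
TR interval occupied by that condition's blocks, convolved with a canonical
double-gamma HRF (response gamma peaking at 6 s, undershoot at 16 s with
1/6 amplitude — the standard parameterization). Occupancy integration
rather than onset sampling makes the unconvolved column sum equal the
condition's total seconds divided by the TR, whatever the block/TR phase.
The design holds 8 condition columns, a fixation column, six motion
parameters and an intercept (16 columns).

`fit_glm()` is plain OLS per voxel — no prewhitening or AR noise model, as
nothing in the study's description constrains one; degrees of freedom are
`volumes - rank(design)` and a rank-deficient design falls back to the
minimum-norm solution with a warning. `condition_t_patterns()` computes
`t = c'beta / sqrt(sigma^2 c'(X'X)^- c)` with the baseline contrast
realized as condition-regressor minus fixation-regressor (fixation is
explicitly modelled, so "condition vs. baseline" has a natural algebraic
reading). Voxels with numerically zero residual variance (relative
tolerance 1e-12 of the data scale) are flagged `NA` rather than returned as
infinities. Smoothing is deliberately the caller's concern: the univariate
branch of such studies smooths at 8 mm FWHM and the multivariate branch at
4 mm, so the estimator itself stays smoothing-agnostic.

## ROI hierarchy and gated FDR

Subject-level ROIs are the intersection of an anatomical mask with voxels
whose localizer statistic exceeds the one-sided uncorrected p < 0.001
threshold; an empty intersection marks the ROI undefinable for that
subject. An ROI undefinable in five or more subjects is excluded outright
(this reading of the ambiguous "could not be defined in at least five
subjects" is the one consistent with the published exclusion of the
supramarginal gyrus, superior occipital gyrus and angular gyrus, which
leaves 8 level-III seeds); subjects merely lacking a retained ROI are
skipped for that ROI only.

`gated_level_test()` descends the four-level tree (whole cortex, lobes,
regions, IPS subparts) top-down. Group differences use two-sided
pooled-variance two-sample t-tests. Two design choices deserve note:

* FDR is computed across the nodes *actually tested* at a level, not all
  nodes at the level — closed gates contribute no p-values, which is the
  natural reading of correcting "across that level" after gating.
* Gating is per-parent: children of a significant parent are testable even
  when a sibling parent fails its test.

The IPS subparts, delineated manually from anatomical coordinates in the
original workflow, are represented in synthetic mode as labelled sub-boxes
of the parent ROI; real-data use accepts user-supplied masks.

## Decoding

Patterns are standardized per condition and run by subtracting the mean
across voxels and dividing by the *population* SD (divisor n, matching the
(1, 2, 3) -> (-1.2247, 0, 1.2247) convention); constant patterns are an
error because they carry no decodable shape. The classifier is a C-SVC SVM
with C = 1. The published description is self-contradictory (a "linear"
SVM alongside an RBF kernel with gamma = 1, which are LIBSVM defaults); we
default to linear and expose RBF(gamma = 1) through `classifier_spec()` for
sensitivity analysis.

The 70/30 split is over *runs*: only a run-level split makes "test data
averaged to one response pattern per condition" well-defined. A
non-integer 70% rounds to nearest while keeping at least one test run, and
at least 4 runs are required. Each condition pair is scored on the two
averaged test patterns; 100 splits are averaged per cell of the 8 x 8
matrix, and within-format accuracy is the plain mean of the 6 same-format
cells (no pair-difficulty weighting). Decision-boundary ties are broken by
deterministic label order; they are measure-zero under noise.

Subject classification uses leave-one-pair-out cross-validation — one
subject from each group held out per fold so training folds stay balanced —
averaged over 1000 random pairings. The permutation test permutes group
labels globally, once per iteration, and applies the identical LPOCV; the
p-value is the published `#{null >= observed} / N`, which can be exactly 0,
so a `(b+1)/(N+1)` correction is available behind a flag. Because a full
1000 x 1000 nesting is rarely needed to estimate the null, the number of
LPOCV repeats inside each permutation iteration is configurable (default
20). No standardization is applied to subject features: the sources
describe standardization only for ROI-based decoding.

## Searchlight

The stencil is every integer offset with squared norm at most r^2 in
*voxel* units (33 offsets at r = 2, hence "max. 33 voxels": edge and
mask-boundary centers use the in-mask intersection). Accuracy maps are
smoothed with a mask-aware Gaussian (sigma = FWHM / 2.3548): each source
voxel distributes its value over the in-mask voxels it reaches with weights
renormalized to 1, so no accuracy mass leaks out of the brain and the
in-mask mean is preserved exactly. Implementation-wise this is two
separable convolutions (`conv(m / conv(mask, k), k)`), verified against a
definitional nested-loop oracle.

Second-level group comparison uses voxel-wise pooled t-statistics with
family-wise error controlled by max-statistic permutation over group
relabelings. The original workflow used parametric random-field FWE from
its analysis software; permutation FWE is self-contained and exact under
exchangeability, and this substitution is intentional. Maps enter the
t-test after subtracting the 0.5 chance level, which leaves the t-values
unchanged (shift invariance) but makes the maps directly interpretable.

## Connectivity

The six preprocessing steps run in their published order: (1) band-pass
0.01-0.2 Hz (zero-phase order-4 Butterworth via forward-backward
filtering — the band is all the sources specify, the realization is ours);
(2) regression of motion parameters and their first derivatives; (3)
regression of tissue signals and derivatives (generator-provided columns in
synthetic mode — no segmentation is performed); (4) regression of the
HRF-convolved task regressor; (5) scrubbing; (6) smoothing, which applies
only to volumetric data and is skipped for ROI time-course tables. At
TR = 3 s the 0.2 Hz upper edge sits above the Nyquist frequency (1/6 Hz),
so the band degenerates to a high-pass at 0.01 Hz; `bandpass()` warns and
applies exactly that, and errors only when the *low* edge reaches Nyquist.

Scrubbing uses framewise displacement (sum of absolute translation
differences plus rotations scaled by a 50-mm head radius) with a default
threshold of 0.5 mm, removing each flagged volume plus 1 preceding and 2
following volumes. The sources cite only a method for this step; these
defaults are documented as ours and are configurable. Connectivity is the
Pearson matrix over retained volumes; Fisher z = atanh(r) with the diagonal
excluded and |r| = 1 clamped at 1e-7 under a warning. Edge-wise inference
follows the two published families: one-sample t vs 0 within group
(BH-FDR at 0.001 across edges) and two-sample t between groups (BH-FDR at
0.05), with directions reported.

## Summary statistics

Group matching tables are reproduced from printed means and SDs with the
pooled two-sample t (df = n1 + n2 - 2) and Cohen's d with pooled SD (for
equal n, sqrt((s1^2 + s2^2)/2) — numerically consistent with the printed
d values, which is why that convention is adopted). The behavioral 2 x 2
ANOVA treats each subject-by-format score as an independent observation,
reproducing the published (1, 92) df layout for 48 subjects x 2 formats;
this is a faithful-but-questionable convention (a repeated-measures model
would be the modern choice) and is kept because the goal is reproduction.
DTI tract metrics are compared per tract with BH-FDR across tracts within
each metric; correcting across all tract-by-metric cells is available by
flag.

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture. Its defaults are
the study conditions: 2 groups x 24 subjects, 8-12 runs (default 10),
TR = 3 s, 280-s runs. Condition prototypes sit at the vertices of a regular
simplex spanned by random orthonormal directions, scaled so pairwise
prototype distance equals the separation parameter; per-run observations
add i.i.d. Gaussian noise (SD 1). Default separations — symbolic 0.8 in
both groups, non-symbolic 2.0 (control) vs 1.0 (dyscalculia) — were chosen
once so that within-format decoding reproduces the qualitative pattern of
the target study (non-symbolic clearly decodable and group-separated,
symbolic weakly decodable and group-equal) with a group effect large
enough for a 24 + 24 design to detect reliably. Seed-region time courses
are multivariate Gaussian draws with the group's target correlation matrix
(background r = 0.35; PVC-IOC and PVC-FG raised to 0.6 in the dyscalculia
group, the published hyper-connectivity direction) plus a shared
HRF-convolved task component and random-walk motion. All sub-generators
derive child seeds deterministically from one master integer.

What the generator does *not* emulate: spatial autocorrelation and
anatomical structure of real BOLD noise, physiological confounds,
inter-subject anatomical variability, and any systematic relation between
pattern separability and connectivity. Passing calibration tests therefore
demonstrates that the *pipeline* is unbiased and correctly powered under
its own assumptions — not that real data would yield these effect sizes.

## Calibration and problem sizes

The test suite runs the pipeline at sizes chosen to give stable Monte Carlo
estimates while staying at desk scale: chance calibration uses 50
zero-separation subjects (grand-mean accuracy within 3 SEs of 0.5) and 400
null datasets for the permutation test's type-I error, each at the study's
24 + 24 sample size with 39 permutations — chosen so the rejection rule
p < 0.05 has an attainable level of exactly 2/40 = 0.05 under a continuous
null. Sample size matters here beyond power: LPOCV accuracy lives on a
1/(2n)-spaced lattice, and ties between the observed statistic and the
discrete permutation null can only depress the attained level. At 8 + 8
subjects with single-repeat LPOCV we measured attained levels of
0.02-0.025; at the study's 48-subject scale the lattice is fine enough
that the test sits near its nominal level (the published procedure's
1000-repeat averaging removes the discreteness entirely). The
dissociation recovery check simulates 50 cohorts of 24 + 24 subjects
(6 runs, 24 voxels, 3 cross-validation repeats) and requires the gated
root-level test to flag the non-symbolic and clear the symbolic contrast in
at least 80% of them. FWE calibration for the searchlight second level uses
repeated small-grid null simulations against the 0.05 + 3 SE bound.

## Known limitations

* The package ingests ROI time-course tables and voxel arrays; it does not
  perform image preprocessing (slice timing, realignment, normalization,
  segmentation) or tractography — those stages belong to dedicated tools.
* The CLI surface is R-functional: `run_pipeline()` orchestrates
  simulate -> decode -> classify -> connect with a serialized config
  snapshot; there is no standalone shell executable because the natural
  entry point for this audience is the R session.
* Permutation FWE replaces random-field FWE at the searchlight second
  level (see above); results agree in level but not in mechanism.
* The hierarchical gate is a testing procedure, not a model: it controls
  FDR within levels conditional on the path taken, and inherits the usual
  caveats of gatekeeping procedures when effects are borderline at high
  levels.
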