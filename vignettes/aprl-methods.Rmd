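---
title: "Automated paramagnetic rim lesion detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated paramagnetic rim lesion detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aprl)
```

## The problem

Chronic active multiple sclerosis lesions — paramagnetic rim lesions
(PRLs) — show a curvilinear hypointensity at the lesion edge on
T2\*-phase MRI, produced by iron-laden phagocytes at the rim of the
lesion. PRLs mark ongoing tissue damage and are tedious and unreliable to
rate by eye, so `aprl` automates the whole chain from a voxel-wise lesion
probability map to a per-lesion PRL call. The package consumes volumes
that are already preprocessed (bias-corrected, registered into phase
space, skull-stripped, intensity-normalized); none of those steps are
re-implemented here. Phase intensities are treated as unitless and no
assumption is made about their numeric range beyond being roughly
zero-centred in normal-appearing tissue.

## Lesion instance labelling

The labelling stage turns a probability map plus auxiliary masks into
distinct lesion instances:

1. **Threshold selection.** Candidate thresholds (default 0.05–0.95 in
   steps of 0.05) are scanned and the one maximizing the Sørensen–Dice
   overlap with a gold-standard lesion mask is kept, ties going to the
   smallest threshold so results are reproducible. A fixed `threshold`
   bypasses the gold mask entirely for unsupervised runs.
2. **Binarization** with the `>=` convention (a voxel exactly at the
   threshold is lesion).
3. **One-voxel dilation** with the 3×3×3 box element. "One voxel in each
   direction" is read as including diagonals, which matches the box
   element on an isometric grid; connectivity elsewhere is 26 for
   consistency (a 6-connectivity switch exists for components).
4. **Tissue exclusion.** CSF and grey-matter voxels are removed from the
   *newly added* ring only: rim signal often sits just outside the
   segmentation, but a lesion voxel already present before dilation is
   never taken away.
5. **Centre detection.** The probability map is smoothed with a Gaussian
   (`smooth_sigma_vox`, default 1.0 voxel) and the 3×3 Hessian of the
   smoothed field is computed by central differences; voxels whose
   Hessian is negative definite (checked via Sylvester's criterion, with
   no eigendecomposition needed) are peak-like. Their 26-connected
   components are the centres, numbered by the lexicographic order of
   each component's smallest voxel triple. If nothing qualifies — e.g. a
   perfectly flat map — the masked voxel with the highest smoothed
   probability becomes the single centre, so at least one lesion always
   exists.
6. **Nearest-neighbour assignment.** Every masked voxel takes the label
   of the centre component with the closest member voxel (Euclidean, in
   voxel units; centres are extended regions, not centroids). Squared
   distances between integer voxel coordinates are exact in doubles, so
   the tie rule — smaller label wins — is deterministic. The core loop is
   a small C++ kernel.
7. **Confluence.** If a 26-connected component of the final mask holds
   two or more labels, all lesions in it are flagged confluent.
8. **PRL truth transfer.** A lesion is PRL-positive if it overlaps the
   manual line annotation by at least one voxel; a line straddling two
   lesions marks both.

The order of stages follows the published pipeline (dilation before
instance labelling). Since the output support is exactly
`original ∪ (ring \ CSF \ GM)`, the per-lesion sizes always sum to the
final mask size — an identity the tests check on every run.

## First-order radiomic features

Each lesion is summarized by 44 first-order statistics of its phase
intensities over the final (dilated, tissue-excluded) support. The roster
covers location/spread (mean, median, mode, extremes, twelve
percentiles, trimmed mean, ...), distribution shape (population
variance/SD, absolute deviations, skewness, kurtosis, quartile
skewness), and magnitude/diversity (energy, total energy = energy ×
voxel volume, RMS, uniformity, entropy, distinct-value fraction, ...).
The full column list is `prl_feature_names()`; only a handful of these
statistics have a single canonical printed definition, so the exact
roster is a documented package convention rather than a community
standard.

Conventions that matter:

* **No binning.** Empirical probabilities `p(x)` behind uniformity
  (`sum p^2`) and entropy (`-sum p log2 p`) are relative frequencies of
  *exact* distinct values (an optional `bin_width` exists for
  sensitivity analyses and is off by default). On continuous data every voxel value is
  distinct, so uniformity collapses to `1/n` and entropy to `log2 n` —
  both become monotone functions of lesion size. That is not a bug: with
  PRLs systematically larger, these two features carry the size signal,
  which is precisely how they become top predictors. (Note the algebra:
  `log2 n` *increases* with lesion size, so on unbinned data entropy is
  necessarily *higher* in the larger, rim-positive lesions; claims of
  the opposite direction are not achievable under the no-binning
  definition.)
* **Population normalization** (`1/n`) for variance and higher moments,
  `sd = sqrt(variance)`, skewness and kurtosis defined as 0 for a
  constant sample.
* Ratio features guard zero denominators by returning 0, and the robust
  mean absolute deviation is 0 when no value falls inside the 10th–90th
  percentile window (only possible for very small samples), so the
  feature table never contains missing cells.

## Classification

* **Split by subject** (16 train / 4 test by default), redrawn until both
  sides hold at least 100 lesions, so no subject leaks across sides.
* **SMOTE.** PRLs are oversampled by the reciprocal of their prevalence
  (`oversample_factor = "auto"`); each synthetic row is
  `x + u (x_nn - x)` with `u ~ U(0,1)` and `x_nn` one of the `k = 5`
  nearest minority neighbours. The majority class is never undersampled
  and majority rows pass through bit-identical. SMOTE is applied *inside*
  each cross-validation training fold by default, so synthetic points
  never leak into validation folds; `smote_inside_folds = FALSE` gives
  the single-shot alternative.
* **Random forest.** A probability forest (ranger engine) with 500
  trees; 10-fold CV tunes `mtry` over `{sqrt(p), p/3, p/2}` by
  out-of-fold AUC. The published description does not say whether CV
  tuned hyperparameters or only estimated error; tuning is the choice
  here and is recorded in the fitted object (`tidy()` returns the CV
  trace).
* **Operating point.** Youden's J (sensitivity + specificity − 1) is
  maximized over all distinct scores under the `>=` rule; ties go to the
  smallest threshold. All eight reported measures (accuracy, PPV, NPV,
  FPR, FNR, sensitivity, specificity, plus AUC by the Mann–Whitney rank
  statistic with ties counted ½) derive exactly from the confusion
  table, an identity asserted for every report.
* **Uncertainty.** `resample_ci()` repeats split → SMOTE → train → Youden
  → evaluate with counter-derived seeds and reports empirical 2.5/97.5
  percentile intervals as order statistics (inverse ECDF, so two
  replicates give exactly their min/max). The published protocol uses 1000 resplits;
  any `n_iter >= 2` is supported and the package's own checks run the
  protocol at 50 iterations with a single-fold, 300-tree forest so each
  iteration stays cheap.
* **Importance.** Permutation importance is the percent increase in MSE
  of predicted probabilities after permuting one feature column,
  averaged over repetitions; the scaled variant divides by the
  across-repetition standard deviation.
* The non-confluent subset analysis refits nothing: it filters
  `is_confluent` rows and recomputes everything *including its own
  Youden threshold*, mirroring the distinct operating points reported
  for full and subset analyses.

## The phantom: what it emulates, and what it does not

`phantom_spec()` defaults describe the emulated cohort: 20 subjects,
about 50 lesions each (counts drawn ±30%), 12% rim-positive, on a 72³
grid of 0.65 mm isometric voxels. Each subject provides every input the
pipeline consumes: phase volume, gold lesion mask, blurred-truth
probability map, CSF/GM slabs abutting a third of the lesions (so
tissue exclusion has real work), and single-slice line annotations
through each rim lesion's centre along its longest in-plane axis —
annotations are deliberately lines, not lesion masks, to force the
overlap-based label transfer to be exercised.

Key modelling choices, with rationale:

* **Rim model.** Lesions are randomly oriented ellipsoids (semi-axes
  2.5–4.5 voxels) with non-negative interior offsets; rim lesions carry
  an inner shell of thickness 1.5 voxels whose mean intensity offset is
  `rim_contrast = -2` background standard deviations. No quantitative
  rim contrast or thickness is published; these are calibration choices
  of the generator, not claims about the imaging physics.
* **Rim visibility varies.** Real rims range from unambiguous to barely
  ratable, and some PRLs carry too weak a signal to detect; a generator
  whose every rim is a complete, full-strength ring would make the
  classification task artificially easy (every intensity feature becomes
  a perfect separator, and importance rankings degenerate). Each rim
  therefore draws a strength multiplier in [0.25, 1.75] (mean 1, so the
  average shell offset equals `rim_contrast`) and an angular coverage in
  [0.3, 1] (a contiguous cap of the shell is left unmarked). These
  ranges were fixed once, as the realism calibration of the generator.
* **Rim lesions are larger** (`rim_radius_boost = 1` voxel of extra
  semi-axis), reflecting the observation that PRLs tend to be larger
  than other lesions; this is also what routes the size signal into
  uniformity/entropy under the no-binning convention.
* **Confluence.** A fraction (default 0.2) of lesions is placed touching
  a partner at centre distance `r1(u) + r2(u) - 1` along a random
  direction, at most one rim per pair, mirroring clusters that
  connected components merge while instance labelling splits.
* **Determinism.** Everything derives from one seed;
  per-subject/per-iteration seeds use a counter scheme
  (`derive_seed()`), so any subject or resampling iteration is
  reproducible in isolation.

Not emulated: central veins, phase wrapping, EPI artifacts, anisotropic
voxels, registration error, or physically realistic susceptibility
fields. Passing the phantom-based checks therefore demonstrates the
pipeline's *logic* — instance labelling, feature algebra, class
rebalancing, operating-point selection — not clinical performance on
scanner data, which can only be established against rated patient
cohorts.

## Numerical choices and degenerate inputs

* Thresholds and Youden scans break ties toward the smallest candidate.
* Dice of two empty masks is 0; binarization uses `>=`.
* Hessian negative-definiteness uses Sylvester's criterion on the
  central-difference Hessian; the outermost voxel planes can never be
  centres.
* Gaussian smoothing uses a separable kernel truncated at 3σ with zero
  padding.
* Centre detection guarantees K ≥ 1 via the argmax fallback; nearest
  neighbour assignment is exact-integer arithmetic.
* Grid agreement between volumes requires identical shapes and voxel
  sizes within 1e-6 mm; anisotropy beyond 1% warns and proceeds with the
  mean spacing.
* Masks are stored as uint8, label maps as uint16, intensities as
  float32 (double-precision values are quantized on write).

## Problem sizes used by the packaged checks

The package's own verification runs a 20-subject cohort at the default
spec (~1000 lesions, 12% PRL), a single 16/4 split with the full
CV-tuned 500-tree forest, and the 50-iteration resampling protocol with
the single-fold 300-tree configuration; oracle-equivalence checks use
random instances up to 10⁴ voxels and 100-sample feature batches. These
sizes were chosen to exercise every code path at the emulated study
scale while remaining comfortable on a single CPU.

## Known limitations

* The 44-feature roster is a package convention; other first-order
  catalogues order or name features differently.
* The centre detector is a concrete instantiation (Gaussian smoothing +
  negative-definite Hessian + connected components) of a method that is
  only cited, not specified, in the source description of the pipeline.
* Count correlations and performance measures on the phantom reflect the
  generator's assumptions; absolute values are not comparable to
  patient-cohort results.
* Second-order (textural) features and gadolinium-enhancement handling
  are out of scope.
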