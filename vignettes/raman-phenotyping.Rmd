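---
title: "Label-free Raman phenotyping of metastatic potential: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free Raman phenotyping of metastatic potential: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanpheno)
```

## The problem

Isogenic mouse mammary tumor lines (67NR, FARN, 4T07, 4T1) share a genetic
background but arrest at successive steps of the metastatic cascade: 67NR
fails to intravasate, FARN intravasates but does not extravasate, 4T07
extravasates but cannot grow macrometastases, and 4T1 completes all steps.
Fingerprint-region Raman spectra (600–1800 cm⁻¹) of excised tumors carry
biomolecular signatures — most prominently lipid- and collagen-associated
bands — that track this phenotype. `ramanpheno` implements the full analysis
chain for such data: preprocessing, constrained bilinear unmixing (MCR-ALS),
leave-one-mouse-out random-forest phenotype prediction, importance-based
spectral-marker discovery, and nonparametric score statistics. Because raw
spectra of this kind are rarely deposited, the package ships a synthetic
cohort generator with known ground truth, so every stage is testable end to
end.

## The synthetic cohort generator

Each component spectrum is a sum of Gaussian bands (default FWHM 12 cm⁻¹) on
a 600–1800 cm⁻¹ grid at 2 cm⁻¹ spacing, scaled to unit Euclidean norm. The
default library has five components: `lipid_like` (bands at 1078, 1302,
1440, 1656, 1745 cm⁻¹ — C–C/C–N stretches, CH₂ twist and scissor, C=C
stretch, ester carbonyl) and `collagen_like` (856, 938, 1246, 1454, 1667
cm⁻¹ — proline/hydroxyproline, amide III and I) built from standard
band-assignment positions, a `formalin_like` fixation contaminant (907,
1041, 1238, 1492 cm⁻¹) and two mixed protein/nucleic-acid profiles. Band
positions are configuration, not constants.

A cohort design draws, per mouse, mean component abundances around its group
mean (between-mouse SD, default 0.05), then jitters per-spectrum abundances
around the mouse mean (within-mouse SD, default 0.08, truncated at zero).
Each spectrum is the abundance-weighted sum of profiles plus a random
5th-order polynomial fluorescence baseline with positive offset and additive
Gaussian noise (default SD 0.01), clipped at zero. The default group means
make `lipid_like` rise (0.30 / 0.48 / 0.60 / 0.80) and `collagen_like` fall
(0.85 / 0.68 / 0.55 / 0.38) across 67NR / FARN / 4T07 / 4T1, with the
formalin and mixed components phenotype-neutral. The study-design defaults
are 8/6/5/8 mice and ~235 spectra per tumor (Gaussian count, SD 25,
truncated at 1). External "gene-silenced" analog cohorts (TWIST-KO n = 8,
FOXC2-KD n = 7, FOXC2-VC n = 7, CXCR3-KD n = 6, CXCR3-VC n = 6) reuse the
4T1 means with a lipid-down / collagen-up shift for knockdown analogs and
zero shift for vector controls.

The within/between-mouse SDs are simulation parameters, not estimates: no
published within- vs between-tumor variance decomposition of such scores
exists, so they were fixed once at values that make mouse-level
classification challenging but solvable. The generator deliberately omits
instrument effects (cosmic rays, detector binning), spatial structure within
a tumor map (spectra are exchangeable within a mouse), and any non-bilinear
chemistry. Passing tests therefore demonstrate correctness of the *analysis*
under the bilinear model with realistic noise and nuisance structure — not
performance on real tissue.

## Preprocessing

The chain is crop → background subtraction → median filter → vector
normalization, applied per spectrum, with no randomness anywhere.

* **Wavenumber calibration** (`calibrate_wavenumber`) fits a least-squares
  polynomial (default degree 1) from detected channel positions of reference
  peaks (acetaminophen is the conventional standard) to their known
  positions, and refuses non-monotone axes. It is exercised on synthetic
  channel maps, since the generator emits calibrated axes.
* **Crop** retains 600–1800 cm⁻¹ inclusive.
* **Background subtraction** (`subtract_background`) is the modified-polyfit
  scheme: fit a 5th-order polynomial, clip every intensity above the fit
  down to the fit, refit, and iterate until the fitted curve changes by less
  than `tol` (default 1e-4 relative, judged per spectrum; `max_iter` 200);
  the final fit is subtracted. Exact polynomials of the fitted order map to
  zero, and the map is equivariant under adding any such polynomial. Small
  negative residuals are retained so normalization stays unbiased; the MCR
  stage clips them instead.
* **Median filter** default window is 5 channels (10 cm⁻¹) with replicated
  edges. With 12 cm⁻¹-FWHM bands this flattens band tops by a few percent —
  the residual distortion of the whole chain on clean mixtures is under 2 %
  of the peak amplitude, which we consider the relevant scale for spectra
  whose information lives in band heights.
* **Vector normalization** divides by the Euclidean norm, making score
  comparisons insensitive to acquisition intensity.

Background precedes median filtering because a spike-robust polynomial fit
is not needed on the smooth fluorescence background, and filtering first
would bias peak heights before the envelope is estimated.

## MCR-ALS decomposition

The pooled matrix `D` (spectra × channels, negatives clipped) is factorized
as `D ≈ C Sᵀ` with `C ≥ 0` (scores, the concentration surrogates) and
`S ≥ 0` (component spectra), `k = 5` by default. Both half-steps are exact
non-negative least squares via an in-package Lawson–Hanson active-set solver
working on the shared Gram matrix, so the thousands of small per-spectrum
and per-channel problems in each half-step reuse one crossproduct. After
each iteration rows of `S` are rescaled to unit norm with the magnitude
absorbed into `C`; this scale convention is what makes score distributions
comparable across groups. Convergence is monitored by the lack of fit,
`LOF(%) = 100 √(Σ E² / Σ D²)`, which is non-increasing across iterations;
iteration stops when it changes by less than 1e-6 percentage points or at
`max_iter = 500`.

Initialization is a deterministic SIMPLISMA-style purest-variable selection:
channels with high relative standard deviation, mutually decorrelated via a
determinant weight, seed the initial scores. On mixtures whose components
have selective channels — true for the default library — this starts the
ALS essentially at the true scores, which is why noiseless recovery is exact
(component cosines and abundance correlations of 1.0 in the acceptance run).
A seeded random non-negative initialization is available as a fallback
(`init = "random"`). Rotational ambiguity is the fundamental caveat of MCR:
with heavily overlapping components and no selective channels, the
non-negativity constraints alone need not pin down the factors.

Components are labeled by greedy injective cosine matching against a
reference library (threshold 0.7, below which a component is `"mixed"`).
`project_scores` regresses new spectra on a fitted `S`, supporting the
fit-once / project-later workflow as well as the joint-fit workflow; the
pipeline defaults to fitting the primary cohort and projecting externals,
but both routes are exposed.

## Classification

`lomo_random_forest` implements grouped (leave-one-mouse-out)
cross-validation: all spectra of one mouse form the test fold, everything
else the training pool, so no subject-level leakage is possible — the
returned `folds` record makes this auditable structurally. Within a fold,
classes are equalized by random undersampling to the minimum class count,
re-drawn for each of `n_balance_iter` iterations (default 100), and a
forest of `n_trees` (default 100) Breiman-default trees (√p features per
split, unlimited depth, bootstrap on) is trained per iteration via `ranger`.
Each test spectrum receives the mode of its ensemble predictions
(hard-label mode; probability averaging was considered and rejected as the
default because the mode matches the ensemble-voting description this
design follows); each mouse receives the majority label over its spectra.
Mouse-level ties — possible in binary schemes with even spectrum counts —
are broken toward the class with the higher mean ensemble vote fraction,
then by scheme class order. Everything is deterministic given the seed,
including prediction tie-breaks.

Four built-in labelings map the cascade: `multiclass` (each line its own
class), `intravasation` (67NR negative), `extravasation` (67NR + FARN
negative), `growth` (only 4T1 positive). `confusion_metrics` reports overall
accuracy and one-vs-rest sensitivity/specificity per class, as percentages
rounded half-up to one decimal — the precision at which such tables are
conventionally printed.

`feature_importance` trains a single seeded forest (default 500 trees) on
the class-equalized full dataset with out-of-bag permutation importance per
wavenumber channel. `top_peaks` then selects the `n` most important
channels greedily under a non-neighboring constraint (default minimum
separation 16 cm⁻¹ ≈ 8 channels; "non-neighboring" is not quantified in
standard usage, so this is an explicit, configurable choice).
`train_full_predict_external` applies the same balanced-ensemble
construction, trained once on all training mice, to external cohorts.

## Statistics

Group differences in component scores are tested per spectrum with a
two-sided Wilcoxon rank-sum test: exact enumeration when the combined
sample size is at most 12 with no ties, otherwise the normal approximation
with tie and continuity corrections. Effect sizes use the Wendt
rank-biserial correlation `r = 1 − 2·min(U₁, U₂)/(n₁n₂)`, an unsigned
magnitude in [0, 1]; direction is reported separately as the sign of the
median difference. `compare_scores` tests every group against a reference
(67NR by default) with no multiplicity adjustment, each comparison flagged
at α = 0.05. Testing per spectrum rather than per mouse follows the
dispersion visible in per-spectrum box plots; note that clustered spectra
make the per-spectrum test anticonservative for *mouse-level* claims — a
per-mouse aggregation is a one-liner on `score_table` output if subject-level
inference is wanted. Box summaries use type-7 (linear interpolation)
quartiles and 1.5·IQR whiskers; the Wilcoxon/Wendt results do not depend on
the quartile rule.

## Numerical choices and degenerate inputs

* NNLS: active-set iterations on the k×k normal equations, with a QR
  fallback for singular passive sets and an anti-cycling iteration budget;
  verified against an independent active-set implementation in tests.
* Dead MCR components (all-zero spectra) are reseeded from the worst-fit
  residual; LOF monotonicity is preserved.
* Zero spectra cannot be vector-normalized and raise an error naming the
  spectrum; empty datasets pass through the preprocessing chain vacuously.
* A class that would vanish from some training fold (fewer than 2 mice)
  raises an error naming the fold rather than silently shrinking the label
  space.
* Seeds: one global seed spawns per-stage seeds by a fixed affine rule
  modulo 2³¹ − 1, so stages are independently re-runnable yet reproducible.

## Problem sizes used by the tests and acceptance script

The generator's defaults are the study conditions (27 mice, ~235 spectra
per tumor). The test suite and `scripts/acceptance.R` run the same designs
scaled to 60 spectra per mouse, with classifier ensembles at 10 balance
iterations × 50 trees, and the noiseless MCR recovery check at ~2000
spectra × 601 channels; these sizes are the package's choice of a
desk-scale workload and are stated here so results can be reproduced
exactly.

## Known limitations

* The generator's bilinear world contains no baseline model mismatch, no
  wavenumber miscalibration drift, and no spectral saturation; real-tissue
  performance claims cannot be made from it.
* MCR component identity relies on selective channels; heavily collinear
  chemistry would require rotational-ambiguity analysis that is out of
  scope here.
* The classifier is the fixed balanced-ensemble random forest described
  above — no alternative learners, no hyperparameter search, no probability
  calibration.
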