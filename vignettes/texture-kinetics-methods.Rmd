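---
title: "Texture and kinetic analysis of dynamic breast MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture and kinetic analysis of dynamic breast MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texnac)
```

## The problem

When breast cancer is treated with neoadjuvant chemotherapy (NAC, systemic
therapy given before surgery), a substantial fraction of patients do not
benefit: their tumour shrinks by less than 30 % at pathology. Identifying
likely non-responders (NR) *before* treatment would let clinicians consider
alternatives early. The working hypothesis of this package is that the
pre-treatment dynamic contrast-enhanced MRI (DCE-MRI) of the lesion carries
that information in two complementary forms:

* **enhancement kinetics** — how fast and how strongly the lesion takes up
  contrast agent (amplitude, wash-in, wash-out of the signal–time curve);
* **texture** — the spatial organization of grey levels inside the lesion on
  the subtracted image, summarized by grey-level co-occurrence matrix (GLCM)
  and run-length matrix (RLM) statistics.

`texnac` implements the full analysis chain — synthetic data generation,
subtraction imaging, kinetic parameters, automated lesion segmentation,
texture features, mono-parametric statistics, and multi-parametric
classification with leave-one-out cross-validation (LOOCV) — so that every
stage is testable without access to clinical images.

## Dynamic series and kinetic parameters

A `dynamic_series` is a stack of 2D frames with acquisition times: one
pre-contrast frame and typically five post-contrast frames at ~60 s
resolution. All analysis operates on *enhancement*, i.e. differences
relative to the pre-contrast frame, which makes every output invariant to a
constant intensity offset.

The three semi-quantitative curve descriptors are defined directly on the
ROI-mean enhancement curve:

* **amplitude** (AU): the maximum enhancement over the post-contrast points;
* **wash-in** (AU/s): the up-slope between the enhancement peak and the
  immediately preceding time point;
* **wash-out** (AU/s): the ordinary-least-squares slope over the final three
  (time, signal) points, reported *signed* — positive for a rising/plateau
  tail, negative for true washout.

Ties at the peak resolve deterministically to the earliest frame. The
subtraction image is computed as post-contrast minus pre-contrast, so that
enhancement is positive; the default post-contrast frame is the second one,
the usual enhancement peak of malignant lesions. Amplitude is absolute
enhancement in arbitrary units, not percent over baseline.

```{r kinetics}
kinetic_params(list(times = c(0, 60, 120, 180, 240, 300),
                    signal = c(0, 50, 80, 70, 65, 60)))
```

## The synthetic-data generator

No public DCE-MRI dataset accompanies this problem, so the package ships a
first-class phantom generator whose defaults *are* the study conditions the
rest of the package assumes.

**Enhancement curve family.** Piecewise linear: baseline 0 at the
pre-contrast frame, a linear rise whose final step into the configured peak
frame has slope `wash_in`, the configured `amplitude` at the peak frame, and
a linear tail of slope `wash_out`. This family was chosen deliberately over
a pharmacokinetic model: the analysis measures only amplitude, up-slope and
late slope, so the ground truth is expressed in exactly the measured
parameterization and recovery can be asserted exactly on noise-free
phantoms.

**Default lesion wash-out is −0.04 AU/s.** Clinical plateau-type curves can
have a mildly *positive* late slope of similar magnitude, but under a
piecewise-linear tail a positive slope relocates the global enhancement
maximum to the last frame, so the measured wash-in would degenerate to the
tail slope and no longer reflect the configured value. A mild negative tail
keeps the configured peak frame as the measured peak, i.e. keeps the ground
truth in the measured parameterization. Configure `wash_out > 0` explicitly
to emulate plateau/persistent curves — the kinetic code handles them; only
exact ground-truth recovery is then no longer meaningful.

**Texture heterogeneity.** The lesion enhancement is multiplied, pixel-wise,
by `exp(texture_sigma * F)` where `F` is a zero-mean, unit-variance Gaussian
random field with correlation length `lesion_texture_corr_len` (pixels,
implemented as Gaussian smoothing of white noise with edge renormalization).
The multiplier is renormalized to unit mean over the lesion, so the mean
lesion kinetics stay at their configured values regardless of the texture
settings. Larger correlation lengths give smoother, more homogeneous
lesions — measurably: homogeneity and inverse difference moment increase,
entropy decreases (a tested monotonicity).

**Background.** Parenchyma enhances weakly (default amplitude 15 AU);
fat regions (a configurable fraction of the background, default 0.35,
placed by thresholding a smooth random field) do not enhance; additive
zero-mean Gaussian noise of configurable sd is applied independently to
every frame. Gaussian rather than Rician noise is appropriate because the
analysis operates on subtracted images at high SNR, where the Rician
distribution is well approximated by a Gaussian.

**Cohorts.** `generate_cohort()` produces a labelled cohort with fixed class
counts (defaults 19 NR / 36 PR / 14 CR, a 69-patient cohort), biomarkers
drawn from class-conditional probabilities estimated from published
frequencies (molecular subtype as a categorical draw; ER, PgR, Ki67 > 14 %,
HER2 and BI-RADS mass enhancement as independent binaries given class), and
lesions whose parameters differ by class: non-responders are generated
*more homogeneous* (correlation length 3.0 vs 1.2 px) with *lower* wash-in
(0.55 vs 0.75 AU/s) and amplitude (68 vs 75 AU) than responders, matching
the direction of published group differences. The published study reports
only medians measured on unavailable images, so these magnitudes are a
design choice of the generator: large enough that a planted signal is
detectable in a 69-patient cohort, with 10 % log-normal between-patient
jitter providing overlap. Partial and complete responders share one
setting, since the discrimination task is NR vs PR+CR.

What the phantoms do **not** emulate: acquisition physics (coil profiles,
bias fields), motion, multi-slice anatomy (generation is single-slice 2D by
design, matching a single-subtracted-image analysis), pharmacokinetics, and
any correlation between biomarkers and image phenotype beyond the response
class. Passing tests therefore demonstrate that the *pipeline* measures
what it claims on data with known truth — not that real lesions are
classifiable at any particular accuracy.

## Automated lesion segmentation

`segment_lesion()` reproduces a kinetic-map segmentation: per-pixel
(amplitude, wash-in) maps over a rectangular search region, k-means with
k = 2 over the two features, the higher-mean-amplitude cluster taken as
lesion, a morphological opening, then the largest connected component.

Design choices the procedure leaves open, resolved as follows:

* **Feature scaling**: amplitude (AU) and wash-in (AU/s) are z-scored within
  the search region before clustering — they carry different units and
  unscaled Euclidean clustering would be dominated by amplitude.
* **Lesion cluster identification**: the cluster with higher mean raw
  amplitude.
* **Opening**: disc structuring element (pixels at Euclidean distance
  ≤ radius), default radius 1; radius 0 disables it. Note that an opening
  legitimately removes convex corners not covered by a disc translate.
* **Order of cleanup**: opening first, then largest component. The
  alternative reading (component first, then opening) differs only when the
  opening splits the largest region; the implemented order is the
  conventional "remove isolated groups, then keep the main region".
* **Connectivity**: 4-connectivity for "contiguous", configurable to 8.
* **Restarts**: best of 10 k-means replicates by within-cluster inertia,
  seeded and deterministic.

Degenerate inputs fail loudly: a search region with no enhancing pixels
(constant feature maps) or an emptied cluster raises an error rather than
returning a meaningless mask. Agreement with a reference mask is scored by
the Dice coefficient, defined as 1 when both masks are empty.

One practical caveat found during development and now documented: the
per-pixel wash-in map uses the slope into the per-pixel *argmax* frame.
When the lesion curve is near-plateau (|wash_out| small relative to noise),
the argmax is unstable and the wash-in map becomes bimodal inside the
lesion, degrading the clustering non-monotonically in noise. The
segmentation recovery tests therefore use phantoms with a clearly peaked
curve (wash-out −0.15 AU/s) and mild heterogeneity, so that every lesion
pixel retains ≥ 10× contrast over the noise sd — the regime the recovery
guarantee speaks about.

## Texture features

Images are quantized to `2^bits` grey levels (default 5 bits = 32 levels)
by linear min–max binning *within the analysed mask*; the in-mask maximum
maps to the top level. Min–max binning makes every texture feature exactly
invariant under positive affine rescaling of the intensities — a desirable
property for arbitrary-unit MR data. A constant region maps to level 0.

**GLCM.** Ordered pairs of in-mask pixels at distance 1 are counted in the
four principal directions (0°, 45°, 90°, 135°), each directional matrix is
symmetrized with its transpose, the four are pooled and normalized to sum 1
(after normalization, pooling and averaging the directions coincide up to
the per-direction pair counts). Only pairs with *both* pixels in the mask
count, so irregular ROIs are handled exactly. Nine features are computed
with grey levels indexed 1..G (the classical convention): energy, entropy
(base 2, with 0·log 0 = 0), contrast, homogeneity, correlation, inverse
difference moment, sum average, sum variance (centred on the sum average —
one of the two historical variants, fixed here), and difference variance
(the variance of the |i−j| margin). For a constant region the matrix is a
single cell and correlation is reported as 0 with a `degenerate` flag
instead of NaN.

**RLM.** Maximal runs of equal level are counted along each of the four
directions, with runs broken at mask boundaries; each in-mask pixel belongs
to exactly one run per direction, a tested accounting identity. Grey levels
are re-indexed 1..G so the low/high grey-level weights (1/i², i²) are well
defined. The eleven classical features follow: SRE, LRE, GLN, RLN, RP
(number of runs over total run-length mass), LGRE, HGRE, SRLGE, SRHGE,
LRLGE, LRHGE. Raw formula values are reported on their natural scales;
published tables in this area are often renormalized to a 0–255 display
range, which is available only in `texture_map()` and never applied to
feature values.

Both matrix constructions and all 20 features are verified against
independent brute-force oracles (explicit pair/run enumeration,
literal-formula summation) to 10⁻¹⁰ on hundreds of random masked images.

## Statistics

* **Wilcoxon rank-sum** (`wilcoxon_ranksum`): midranks, tie-corrected
  normal approximation with continuity correction; p = 1 with a flag when
  every value is tied.
* **D'Agostino–Pearson omnibus** (`dagostino_pearson`): K² = Z²(skew) +
  Z²(kurt) against χ²(2), using the standard finite-sample transformations;
  requires n ≥ 8. Verified against an independent implementation to 10⁻¹⁰.
* **Mid-P Fisher exact** (`fisher_midp`): hypergeometric enumeration;
  one-sided mid-P = P(strictly more extreme) + ½·P(observed); the two-sided
  value doubles the smaller one-sided mid-P, capped at 1. The doubling
  convention (rather than probability-ordering summation) is the one that
  reproduces the published 2×2 p-values this package uses as fixed
  verification points. Zero-margin tables return p = 1 with a flag.
* **ROC** (`roc_analysis`): the empirical curve over all thresholds;
  trapezoid AUC, which equals the Mann–Whitney U statistic divided by
  n₁n₂ (a tested identity at 10⁻¹²); the reported cut-off maximizes the
  Youden index J = Se + Sp − 1 with ties resolved toward higher
  sensitivity, because detecting non-responders is the clinical priority;
  AUC vs 0.5 is tested with the Mann–Whitney normal approximation. Marker
  orientation is chosen automatically so AUC ≥ 0.5 and recorded.
* **Paired AUC comparison** (`compare_auc`): DeLong's placement-value
  method. Markers are compared in the orientation given — re-orienting each
  marker by its own observed AUC would truncate the null distribution of
  the difference and was measurably anticonservative in calibration, so it
  is deliberately not done.

No multiple-testing correction is applied anywhere: the mono-parametric
screen is descriptive, and the package takes the position that the
universal null hypothesis is not the question of interest.

## Multi-parametric prediction

The candidate set is 26 parameters: 20 texture, 3 kinetic, and 3 binaries
(mass enhancement, Ki67 > 14 %, HR−/HER2+). Two classifiers are provided
through one fitting interface, `nr_model()`:

* **Logistic regression**: maximum likelihood with intercept on z-scored
  features; prediction NR at fitted probability ≥ 0.5. Complete separation
  triggers a ridge-penalized fallback (λ = 0.05 on the slopes) with a
  warning. Constant features are dropped with a warning.
* **L1 k-means**: 2 clusters, initial centroids drawn as 2 random training
  observations, 30 replicates keeping the lowest within-cluster L1
  dispersion, L1 (city-block) assignment with component-wise median
  updates (the L1-optimal centre); an emptied cluster is re-seeded with the
  worst-fitted point. Each cluster is labelled by the majority outcome of
  its training members, ties toward NR (the sensitivity priority); a new
  observation takes the label of its L1-nearest centroid. Features are
  z-scored on the training data — mandatory, since L1 distances mix units.

**LOOCV** (`loocv`) re-estimates *all* preprocessing (optional natural-log
transforms with a data-driven positivity offset, and the z-scoring) on each
training fold, so nothing about the held-out patient leaks into its own
prediction; this is verified by replicating folds manually in the tests.
Sensitivity is the percentage of NR predicted NR, specificity the
percentage of PR+CR predicted PR+CR, accuracy the raw proportion correct
(not class-weighted — consistent with confusion-count bookkeeping).

**Subset search** (`subset_search`) enumerates all subsets of the requested
sizes and ranks by accuracy, ties toward sensitivity, then smaller subsets.
A full scan over sizes 2..26 of 26 parameters is 2²⁶ − 27 ≈ 6.7 × 10⁷
LOOCV evaluations; the search refuses beyond a configurable cap (default
10⁶) and reports the count, so desk-scale behaviour stays honest.

**Permutation null** (`permutation_null`) re-evaluates the LOOCV under
random label permutations. For the k-means classifier this is exact and
cheap: the clustering depends only on the features, so the per-fold cluster
assignments are computed once and each permutation merely re-derives the
majority-vote labels and the held-out prediction — identical to a naive
re-run, at a thousandth of the cost (a tested equivalence).

## Problem sizes and numerical conventions used by the test suite

The suite generates everything it needs at run time: random masked images
of 6–16 pixels per side for the oracle equivalences (260 images against
brute force), 2 000 random curves for the OLS identity, 4 000-replicate
null simulations for test calibration (nominal level asserted within
[0.035, 0.065]), 10⁴ label permutations for the AUC chance level, phantom
grids of 40–64 px, and the default 69-patient cohort (48 px grid, ~1.5 s to
generate and featurize) for the end-to-end classification checks, with
1 000 label permutations for its null. Fixed seeds appear throughout; every
random quantity in the package flows from explicit seed arguments, with
per-fold and per-replicate streams derived from a single master seed, and
the caller's RNG state is always restored.

## Known limitations

* Single-slice 2D only; no 3D texture or segmentation.
* The phantom texture model (log-Gaussian multiplicative field) controls
  heterogeneity smoothly but is not a histological model; absolute feature
  values on phantoms are not comparable to clinical tables.
* The generator draws binary biomarkers independently given class, so
  subtype–receptor consistency (e.g. a Luminal-A patient with ER−) is not
  enforced except through the derived HR−/HER2+ flag.
* The published headline operating points (Se = 84 %/Sp = 62 % and
  neighbours) are properties of a specific clinical dataset and are not
  reproducible from synthetic data; the package asserts direction and
  detectability of planted effects instead.
* The k-means classifier has no probability output; risk calibration is out
  of scope.
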