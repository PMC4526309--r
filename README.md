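# texnac

Texture and kinetic analysis of pre-treatment dynamic contrast-enhanced
(DCE) breast MRI for predicting **non-response to neoadjuvant
chemotherapy** (NAC).

A substantial fraction of breast-cancer patients gain little from NAC:
at surgery their invasive tumour has shrunk by less than 30 %
(pathological non-response, NR, versus partial/complete response,
PR+CR). `texnac` implements, as a tested and reusable R pipeline, an
image-analysis chain that asks whether the *baseline* MRI already
separates these groups:

1. **Kinetics** — from the signal–time curve S(t) of a small ROI on the
   most enhancing part of the lesion (1 pre-contrast + 5 post-contrast
   frames, Δt ≈ 60 s):
   amplitude `A = max_t S(t)` (AU), wash-in
   `(S(t_peak) − S(t_peak−1)) / Δt` (AU/s), and wash-out, the signed OLS
   slope over the last three points (AU/s).
2. **Segmentation** — per-pixel (amplitude, wash-in) maps over a
   rectangle covering the breast, k-means with k = 2, morphological
   opening, largest 4-connected component → automatic lesion mask,
   scored against a reference by the Dice coefficient.
3. **Texture** — the subtracted image (2nd post-contrast − pre-contrast)
   quantized to 32 grey levels within the lesion; 9 grey-level
   co-occurrence (GLCM, distance 1, four directions pooled and
   symmetrized) and 11 run-length (RLM) features: energy, entropy,
   contrast, homogeneity, correlation, inverse difference moment, sum
   average, sum variance, difference variance; SRE, LRE, GLN, RLN, RP,
   LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE.
4. **Statistics** — Wilcoxon rank-sum, D'Agostino–Pearson normality,
   mid-P Fisher exact tests of 2×2 biomarker-by-response tables,
   empirical ROC with Youden cut-offs (AUC = U/(n₁n₂), a tested
   identity) and DeLong paired AUC comparison.
5. **Prediction** — two classifiers over subsets of 26 parameters
   (20 texture + 3 kinetic + mass enhancement, Ki67 > 14 %, HR−/HER2+):
   logistic regression and an L1-distance 2-cluster k-means classifier
   (2 random training observations as initial centroids, 30 replicates,
   majority-vote cluster labels), both evaluated by leave-one-out
   cross-validation (Se = % NR detected, Sp = % PR+CR detected), with an
   exhaustive feature-subset search.

Because no clinical images ship with the package, a first-class
**synthetic-data module** generates dynamic-series phantoms (piecewise
linear enhancement, log-Gaussian texture heterogeneity with controllable
correlation length, parenchyma/fat background, Gaussian noise) and
labelled 69-patient cohorts (19 NR / 36 PR / 14 CR) with
class-conditional biomarkers, in which non-responders are planted more
homogeneous and slower-enhancing than responders. Every stage is tested
against brute-force oracles and ground truth on these phantoms; see the
methods vignette (`vignettes/texture-kinetics-methods.Rmd`) for the
model, the defaults and their rationale, and known limitations.

## Worked example

```r
library(texnac)

## phantom with known ground truth, automated segmentation
ph  <- generate_phantom(phantom_config(seed = 8))
seg <- segment_lesion(ph$series, params = segmentation_params(seed = 8))
dice(seg, ph$truth$lesion_mask)
#> [1] 0.8387547

## texture + kinetic features of the segmented lesion
f <- extract_features(ph$series, unclass(seg))
round(f[c("homogeneity", "inv_diff_moment", "gln", "lrhge",
          "wash_in", "amplitude", "wash_out")], 4)
#>     homogeneity inv_diff_moment             gln           lrhge
#>          0.3594          0.2702         32.7987        165.9631
#>         wash_in       amplitude        wash_out
#>          1.3750        141.8412         -0.0594

## association between Luminal-A subtype and non-response
## (2x2 counts: 8/19 NR vs 5/50 PR+CR are Luminal A)
fisher_midp(rbind(c(8, 5), c(11, 45)))
#> <nac_test> mid-P Fisher exact: statistic = 8, p = 0.005343

## synthetic 69-patient cohort, 4-parameter k-means model, LOOCV
coh <- generate_cohort(cohort_config(seed = 11))
ft  <- build_feature_table(coh)
loocv(ft, c("inv_diff_moment", "gln", "lrhge", "wash_in"),
      method = "kmeans", seed = 4)
#> <nr_cv:kmeans> inv_diff_moment + gln + lrhge + wash_in
#>   Se 95% (18/19 NR), Sp 78% (39/50 responders), accuracy 83%
```

The Dice score says the automatic mask overlaps the true lesion well at
the default noise and heterogeneity; the Fisher p-value reproduces the
published association between Luminal-A subtype and non-response; and on
the synthetic cohort the four-parameter model detects 18 of the 19
planted non-responders, with specificity and accuracy as printed —
numbers that describe the *planted* effect sizes, not clinical
performance.

A thin command-line wrapper over the same functions is provided at
`inst/cli/texnac.R` (subcommands `simulate`, `kinetics`, `segment`,
`features`, `fisher`, `run`).

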