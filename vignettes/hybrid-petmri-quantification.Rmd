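---
title: "Hybrid PET/MRI quantification of breast lesions: methods and design"
author: "petmriq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid PET/MRI quantification of breast lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmriq)
```

## The problem

Invasive ductal carcinoma (IDC) of the breast is routinely graded and
profiled from biopsy tissue: tumour grade, estrogen and progesterone
receptor percentages (ER, PgR), the Ki67 proliferation index, and HER2
status together determine the surrogate molecular subtype (luminal A,
luminal B, ...) that guides therapy. Biopsies sample a small part of a
heterogeneous tumour, so quantitative imaging is attractive as a
complementary, whole-lesion readout. Simultaneous PET/MRI delivers three
co-registered measurements per lesion in one session:

* **PET**: [18F]FDG uptake as body-weight-normalized standardized uptake
  values (SUVmax, SUVmean) over a lesion volume of interest (VOI);
* **DCE-MRI**: a six-phase dynamic series (one pre-contrast phase, five
  post-contrast phases 90 s apart) summarized by the VOI-mean
  time–intensity curve (TIC);
* **DWI**: a two-point diffusion acquisition (b = 0 and 1000 s/mm²)
  yielding an apparent diffusion coefficient (ADC) map.

`petmriq` implements the quantification of 9 single-modality parameters
and 14 *hybrid* PET/MRI parameters per lesion, and the univariate
statistical battery relating them to the tissue biomarkers. Because
clinical PET/MRI cohorts are not publicly deposited, the package ships a
first-class synthetic cohort generator so that every stage — segmentation,
quantification, classification, statistics — is testable end to end.

## Parameters extracted per lesion

From the VOI-mean TIC values SI0 … SI5 (SI0 pre-contrast):

| Parameter | Definition | Invalid when |
|---|---|---|
| E1 | $100\,(SI_1-SI_0)/SI_0$ | $SI_0=0$ |
| ESER | $100\,(SI_1-SI_0)/(SI_2-SI_0)$ | $SI_2=SI_0$ |
| Slope | $100\,(SI_5-m)/m$, $m=\mathrm{mean}(SI_1,SI_2)$ | $m=0$ |
| SPER | $(SI_{peak}-SI_0)/(SI_5-SI_0)$ | $SI_5=SI_0$ |
| SFER | $(SI_1-SI_0)/(SI_5-SI_0)$ | $SI_5=SI_0$ |

The TIC is classified by its late slope: **wash-out** below −10%,
**plateau** in [−10, 10]%, **persistent** above 10%. The plateau interval
is closed on both sides — the rule is stated as "between −10% and 10%"
without strictness, and closing it makes the three classes a total
partition with explicit boundary behaviour. `SI_peak` is the maximum over
*all six* phases, pre-contrast included (the verbatim reading of "peak
enhancement between the six phases"); a non-enhancing curve can therefore
produce SPER ≤ 0, which is reported as-is, never clamped.

PET contributes SUVmax and SUVmean over the VOI; DWI contributes ADCmin
and ADCmean over the valid voxels of the ADC map (reported in
10⁻⁶ mm²/s, the unit that makes the SUV/ADC hybrids land on the
magnitude scale of the reported estimates, e.g. SUVmax/ADCmin ≈ 0.005).

**Hybrid construction.** Malignant breast lesions tend to have high SUV,
low ADC, strong early enhancement (E1, ESER, SPER, SFER up) and a
falling late slope. To make a single score that increases with
malignancy, SUV is *multiplied* by the enhancement parameters and
*divided* by the decreasing ones (Slope, ADCmin, ADCmean):
SUVmax × E1, SUVmean × E1, SUVmax × ESER, SUVmean × ESER, SUVmax/Slope,
SUVmean/Slope, SUVmax × SPER, SUVmean × SPER, SUVmax × SFER,
SUVmean × SFER, SUVmax/ADCmin, SUVmean/ADCmin, SUVmax/ADCmean,
SUVmean/ADCmean — 14 hybrids, 23 parameters in total. Direction metadata
(used only to orient ROC analyses) is −1 for ADCmin and ADCmean and +1
for everything else.

An invalid component (zero denominator, no valid ADC voxel) invalidates
only the parameters that depend on it; the lesion is retained for the
rest, and every statistic is computed on the valid subset per parameter
(pairwise deletion). A lesion missing a whole modality is excluded with a
machine-readable reason, mirroring a selection flowchart
(`cohortFlowSummary()`).

## Segmentation and map computation

* `segmentPetVoi()` applies the fixed-threshold rule: voxels at or above
  40% of the maximum uptake in the search region, restricted to the
  26-connected component containing the maximum voxel. 26-connectivity
  is the standard choice for 3D hot-spot VOIs; ties at the maximum are
  seeded deterministically at the first maximal voxel in array order.
  The interactive "manual adjustment" step of clinical practice is
  replaced by an optional explicit search region, for reproducibility.
* `dceSubtraction()` forms post-minus-pre subtraction images (default:
  second post-contrast phase).
* `applyRigidToMask()` applies a *known* rigid transform (e.g. the
  eddy-current re-alignment between DWI b-values) by nearest-neighbour
  pull resampling; transform estimation is out of scope. Rotation is
  about the world centre of the source grid; identity on a shared grid
  returns the input unchanged.
* `adcMap()` computes the two-point mono-exponential ADC,
  $\ln(S_{low}/S_{high})/(b_{high}-b_{low})$, flagging voxels invalid
  (`NA`) when either signal is non-positive or the ADC is negative.

Voxel indices are 1-based in R arrays with world coordinates
`origin + (index − 1) · spacing`; masks live on the grid of their
reference modality and cross-modality transfer is always explicit (the
identity for the scanner-co-registered PET/DCE case).

## The statistical battery

`runUnivariateBattery()` reproduces the analysis plan:

* **Spearman correlations** of each of the 23 parameters with ER%, PgR%
  and Ki67%, Bonferroni-corrected with factor 9 + 14 = 23, and the
  9 × 14 single-vs-hybrid correlation matrix corrected with factor 126.
  The correlation is Pearson on average ranks; p-values come from
  `stats::cor.test` (exact for small untied samples, t-approximation
  otherwise).
* **Mann–Whitney comparisons** for five contrasts — G1 vs G2, G1 vs G3,
  G2 vs G3, Ki67-positive vs negative, luminal A vs luminal B — with
  factor-23 correction. The test is exact (full enumeration) when the
  combined sample size is ≤ 20 without ties, otherwise the normal
  approximation with tie and continuity correction. Each comparison
  carries the Hodges–Lehmann estimate (median of all pairwise
  differences) and its Moses order-statistic confidence interval at
  level 1 − 0.05/23 (≈ 99.78%, displayed as 99.8%); the unrounded level
  is used internally. The estimate is consistently (less-aggressive
  group) − (more-aggressive group): G1 − G2, G1 − G3, G2 − G3,
  Ki67-negative − positive, luminal A − B — the sign convention that
  matches the reported tables for every contrast, including the Ki67
  one where the column label order differs from the numeric convention.
* **ROC analysis** per parameter and contrast with the more aggressive
  class as positive: trapezoidal AUC, DeLong variance for the CI, and
  the operating cutoff maximizing Youden's J (midpoints between adjacent
  distinct oriented scores; ties broken toward higher sensitivity, then
  the lower cutoff). Orientation comes from the direction metadata and
  is never auto-flipped, so an AUC below 0.5 is possible and reported
  honestly. Sensitivity, specificity, PPV and NPV at the cutoff are
  reported in percent.

The Moses interval uses the exact null U distribution (`stats::pwilcox`)
when $n_1 n_2 \le 400$ and the continuity-corrected normal approximation
above that; when even the outermost order statistics cannot reach the
tail probability (tiny samples) the degenerate interval (min difference,
max difference) is returned. A Kolmogorov–Smirnov normality screen is
deliberately omitted: every downstream test here is nonparametric, so a
normality gate would have no consumer.

## The synthetic cohort generator

`generateCohort()` draws, per lesion, a single latent *aggressiveness*
score that drives everything the analysis expects to be associated:

* **Grade** is a noisy copy of the axis (loading 0.7) cut at the
  configured proportions (default 52/76/31 over G1/G2/G3), which makes
  median aggressiveness strictly increase across grades in any
  reasonably sized cohort.
* **Ki67** has a log-normal marginal whose coefficient of variation
  matches the reported 21 ± 14.3% and whose location is pinned so that
  P(Ki67 ≥ 20%) = 71/159 = 44.7%.
* **SUV** is log-linear increasing and **ADC floor** linear decreasing
  in their latent channels. The configured Spearman targets (defaults
  0.4607 for Ki67–SUVmean, −0.2833 for Ki67–ADCmin) are converted to
  latent Pearson correlations via $\rho = 2\sin(\pi r_s/6)$ and split
  between the Ki67 channel (loading 0.8) and the SUV/ADC channels, so
  the rank correlations are met in expectation; SUVmean is the exact
  monotone transform of its channel (the calibrated quantity) while
  SUVmax adds mild VOI-shape noise and is thus slightly attenuated —
  matching the reported ordering of the two correlations.
* **ER/PgR** are near-saturated positive (156/159 and 157/159), HER2 3+
  is rare (14/159) and no 2+ lesion is FISH-amplified by default — the
  class imbalance the battery must tolerate is part of the conditions.
* **TIC archetypes** (wash-out/plateau/persistent, default mix
  0.38/0.23/0.39 with the persistent rate matching the reported 62/159;
  the wash-out/plateau split is not reported and was fixed once at a
  typical malignant-lesion value) are drawn *independently* of
  aggressiveness, encoding the finding that no DCE semi-quantitative
  parameter discriminated any contrast.
* The `subtypeAucTarget` field (default 0.720) adds an extra luminal-B
  shift on the SUV channel only when the requested AUC exceeds the value
  already implied by the correlation structure (a truncated-bivariate-
  normal closed form, ≈ 0.72 at the defaults — so the default shift is
  essentially zero).

Absolute scales are free choices typical of malignant breast lesions
(SUV roughly 2–12, ADC roughly 700–1600 × 10⁻⁶ mm²/s, baseline SI ≈ 300):
no per-group SUV/ADC summaries are available to calibrate against, so
only directions and correlation magnitudes are calibrated.

`renderLesionVolumes()` turns a cohort row into co-registered phantoms on
a ≤ 32³ grid (default 24³, 2 mm isotropic — seconds-scale tests): an
ellipsoidal lesion whose PET profile peaks at the true SUV at the core
and stays ≥ 45% of it inside the lesion (so the whole ellipsoid survives
the 40% threshold at zero noise), DCE phases equal to the lesion TIC
inside the lesion, and a DWI pair whose ADC equals the configured floor
at the core. MR noise is Rician (magnitude of complex Gaussian); PET
noise is zero-mean Gaussian with SD ∝ √signal — the standard desk-scale
acquisition-physics approximations. Not emulated: anatomical breast
background, motion (and the per-phase VOI re-drawing it triggers in
clinical practice, whose trigger criterion is unstated), scanner PSF /
partial-volume effects, and bilateral-lesion patient structure. Passing
tests therefore demonstrate the correctness and calibration of the
*pipeline*, not clinical performance on real data.

## Reproducibility and problem sizes

Everything is deterministic under the mandatory config seed (fixed seed
⇒ byte-identical cohorts, volumes and output tables). The validation
suites use: 200 cohorts of 159 lesions for correlation-target recovery
(tolerance ±0.05 on the mean), 500 null cohorts for the family-wise
type-I check of the 23 corrected tests, 1000 replicates at n = 30 + 30
for the 99.8% CI coverage check (required to stay within 2% of nominal),
100 random 16³ phantoms against an independent flood-fill oracle, and
full Mann–Whitney enumeration for all group sizes with n₁ + n₂ ≤ 12.

```{r example}
run <- runPipeline(syntheticConfig(seed = 1, nLesions = 159))
run$flow$retained
head(subset(run$stats$roc, contrast == "Luminal A vs luminal B",
            select = c(parameter, auc, sensitivity, specificity)))
```

## Known limitations

* The generator encodes a single-axis dependence structure; real tumours
  have richer (and partly discordant) biology, so absolute p-values and
  AUCs from synthetic runs characterize the method, not the disease.
* Only application of rigid transforms is supported, not estimation.
* Radiomics, MTV/TLG, and pharmacokinetic DCE modelling (Ktrans, kep,
  Ve — unattainable at 90 s temporal resolution) are out of scope, as is
  any multivariate analysis of the 23 parameters.
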