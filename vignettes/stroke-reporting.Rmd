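---
title: "Atlas-based stroke quantification and automated reporting: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-based stroke quantification and automated reporting: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

strokescribe turns a binary infarct-core mask in a common template space
into a quantitative, interpretable radiological report. This vignette is
the package's account of the underlying methods: the quantities computed,
the models fitted, the choices made where the design was genuinely open,
and what the synthetic phantoms do and do not establish.

## Inputs and coordinate conventions

All volumes in one case — the infarct mask, optional ADC map, and the
parcellation atlases — must share a single sampling grid
(`grids_compatible()`, shape equality and affine agreement within
1e-4 mm). The package never resamples; registration to the template is
assumed done upstream. Voxel indices are 0-based in the affine
convention, world space is RAS, and world x > 0 is the right hemisphere.
That convention drives hemisphere attribution, so inputs in a different
orientation must be reoriented before use.

## Quantitative feature vectors

For a parcellation with regions $r$ of $|r|$ voxels, the feature for
region $r$ is the injury fraction

$$q_r = \frac{|\{v : \text{mask}(v) = 1 \wedge \text{label}(v) = r\}|}{|r|},$$

and the lesion volume enters as $\log(\text{ml})$, with
ml = voxel count × voxel volume (mm³) / 1000. Choices worth stating:

* **Log base.** Natural log (configurable via `log_base`). Lesion
  volumes span roughly three orders of magnitude, so the log scale is
  what the models should see; the base only rescales the feature.
* **Unlabeled lesion voxels** count toward the volume but toward no
  fraction; their count is reported as `unassigned_voxels` so a large
  value can flag a mask/atlas mismatch.
* **Counts vs mm³.** Fractions are voxel-count ratios. On an isotropic
  1 mm template grid these coincide with volume ratios; on anisotropic
  grids the count ratio is still used, since both numerator and
  denominator live on the same grid.
* **Display rounding** is two decimals; every computation uses full
  precision.
* **Quality control** is the Dice coefficient between the subject and
  atlas brain contours, flagged below a configurable threshold
  (default 0.90). It is a deliberately simple overlap index: low values
  mean the atlas overlay, and hence every fraction, is suspect.

An empty mask is an error throughout: the reporting pipeline is defined
for a detected infarct, and log-volume is undefined at zero.

## Ventricular CSF ratios

Two strips of `width` voxel layers (default 5) are built around the
union of the lateral-ventricle sub-regions: OLV outside (dilation minus
union) and ILV inside (union minus erosion). The structuring element is
a 3D box, so "5-voxel width" means exactly five voxel layers under the
Chebyshev metric; the literature rarely pins down the metric, and the
box element makes the strip-size arithmetic exact and testable. The
sub-regions are merged before strip construction so shared walls are not
counted twice.

With a CSF threshold of 0.0018 mm²/s on the ADC map (both inequalities
strict; voxels exactly at the threshold count as neither phase):

* $\gamma_{OLVR}$ = fraction of OLV voxels *below* the threshold
  (non-CSF). Enlarged ventricles push CSF into the outside strip, so a
  value below the cohort mean suggests enlargement.
* $\gamma_{ILVR}$ = fraction of ILV voxels *above* the threshold (CSF).
  A compressed or shifted ventricle drains CSF from the inside strip,
  so a low value suggests compression or midline shift.

ADC maps are expected in mm²/s. If the 99th percentile exceeds 1.0 the
map is almost certainly in a scaled convention (e.g. ×10⁻⁶); the package
refuses to guess and asks for an explicit `adc_scale`.

The binary hydrocephalus *finding* is produced by a classifier over
$(\gamma_{OLVR}, \gamma_{ILVR}, \log \text{ml})$. The exact feature set
feeding a hydrocephalus model is an open design point; these three are
the quantities this module computes that plausibly carry the signal, and
the choice is configurable at the cohort-construction level. The BT
family (below) cannot produce a hydrocephalus call at all, because it
thresholds a region's own QFV component and hydrocephalus has none; its
prediction is reported as NA.

## Classifier families and selection protocol

One independent binary classifier per region, over the full concatenated
feature vector (both schemes' fractions + log volume + the two CSF
ratios). Families: BT, LDA, QDA, RF, KNN, SVM, MLP, implemented on
`MASS`, `randomForest`, `class`, `e1071` and `nnet`. Regions with fewer
than two training cases in either class become constant prevalence
predictors and are flagged in the model card rather than silently fitted.

**BT.** The one-parameter baseline: region $r$ is injured when
$q_r \ge t_r$. The threshold is the *smallest* grid value (grid 0–1,
step 0.01) maximizing the cross-validated sum BACC + F1. Because the
rule has no fitted state, cross-validation reduces to scoring each
candidate on every validation fold and averaging; the tie-break toward
the smallest maximizer is part of the definition, read as the minimum
injury level that explains the expert labels.

**Hyperparameter selection** is two-stage: a single stratified 5-fold CV
scores every grid point by held-out BACC + F1; the top three advance to
a 10-repeat 5-fold CV whose mean score picks the winner. Ties keep the
earlier grid entry at both stages, and a one-entry grid skips stage 2.
Fold scores are aggregated as the mean of per-fold scores (not a pooled
confusion matrix): with stratified folds the two aggregations are close,
and per-fold means keep the repeat structure of stage 2 meaningful.
Folds are stratified per region label so severe imbalance still yields
usable validation folds.

**Metrics.** Sensitivity, precision, BACC, F1 and Cohen's kappa, with
zero-denominator ratios defined as 0 under a warning — the convention
that makes all-negative predictors score BACC 0.5, F1 0 rather than
erroring on degenerate folds. Inter-rater agreement uses ICC(3,1), the
two-way mixed single-rater consistency form, computed from the two-way
ANOVA decomposition.

## Interpretation

* **MDI** is averaged over `n_models` (default 100) independently seeded
  forests, normalized within each forest to sum to one; dispersion is
  the standard deviation over repeats (a choice — error bars need some
  definition, and SD over repeats is the simplest honest one).
* **Permutation importance** (default 100 iterations) is the drop in
  BACC when one feature column is permuted; negatives are possible and
  meaningful for irrelevant features.
* **Shapley explanations** use an ordering-sampling estimator: for a
  sampled feature ordering, features are switched one at a time from
  background values to the case's values and the change in mean
  predicted probability is credited to the switched feature. Because
  every ordering telescopes from the background mean to the case's
  prediction, `base_value + sum(contributions) = predicted_probability`
  holds *exactly* for any number of orderings — efficiency is
  structural, not approximate — and sampling noise only affects how
  credit is split among features. `exact = TRUE` enumerates all
  orderings (practical up to 7 features), which additionally guarantees
  the symmetry property; the estimator is model-agnostic, so one code
  path explains every family, including the tree ensembles. The default
  background is a seeded sample of about 100 training cases.

## Report generation

Hemisphere attribution splits lesion voxels by world x at the midline;
the minor side must hold at least 10% of the lesion (configurable) for a
bilateral call. MCA-ASPECTS is 10 minus the number of the ten ASPECTS
regions whose injury fraction reaches `tau` (default 0.05). No published
rule fixes the involvement threshold; 0.05 — five percent of a small
region — is a deliberately sensitive default, configurable per site, and
the score is monotone: growing a lesion can only lower it.

The report text is a pure function of the structured fields. Positive
territories with probability at or above 0.70 are asserted; below it
they are qualified with "possibly" (the band reproduces the reference
rendering in which a 0.98 territory is asserted and a 0.54 one is
qualified). Structures are listed in atlas-table order. The template is
injective over its field domain, and `parse_report()` inverts it, which
the tests use as a round-trip property.

## The synthetic phantom and what it shows

`make_phantom_atlas()` builds an ellipsoidal brain carrying two
space-filling bilateral parcellations (Voronoi regions of
midline-mirrored seeds, one shared label per mirrored pair, plus one
unpaired midline region per scheme) and a five-part lateral-ventricle
volume. Voronoi geometry preserves what matters for the method: regions
tile the brain, have spatial neighbours, and homologous halves have
near-equal volumes.

`make_lesion()` grows a connected, roughly ball-shaped lesion outward
from a seeded voxel until targeted regions reach requested overlap
fractions within ±0.02, while untargeted regions may receive at most
that tolerance — the spillover that makes phantom lesions coalescent,
like real infarcts crossing atlas boundaries.

`make_cohort()` emulates the training table: per case a primary
arterial-like region (drawn by prevalence weights, default uniform), a
primary overlap in U(0.15, 0.85), each spatial neighbour co-targeted
with probability 0.6 at U(0.08, 0.40), CSF ratios drawn per case
(γ_OLVR ~ U(0.5, 1), γ_ILVR ~ U(0.6, 1)) with the hydrocephalus truth
defined by γ_OLVR < 0.78 — the generator draws the ratio features
directly rather than synthesizing an ADC volume per case, since the
imaging path from ADC to ratios is exercised separately by
`make_adc_phantom()`. Labels follow the overlap rule
fraction ≥ 0.05 and are flipped with probability 0.05 (annotator
error); hydrocephalus prevalence lands near the ~28% typical of acute
stroke cohorts. The pre-noise truth is kept in `meta$labels_clean`, so
*recovery* of the generating rule can be measured on held-out cases:
the headline property checks (random forest held-out BACC ≥ 0.90 and
binary-threshold ≥ 0.85 per region, forest at least matching the
threshold baseline) are evaluated against that clean truth. Against the
noisy labels themselves, BACC is capped by the flip rate in a
prevalence-dependent way (a region at 15% prevalence with 5% flips
cannot exceed ≈ 0.88 even for a perfect rule), which would measure the
noise, not the model.

What passing these tests does *not* show: the phantom has none of the
hard parts of real data — registration error, partial-volume effects at
region boundaries, anisotropic clinical voxels, lesion shapes with
vascular geometry, or expert labels whose errors correlate with lesion
size and location. Performance numbers on the phantom characterize the
implementation, not clinical accuracy.

## Problem sizes and numerical choices

The test suite and the acceptance script run the cohort analyses at
n = 400 cases on a 64³ phantom (300 train / 100 test, the generator's
default study conditions), MDI at 10 forests per region, and Shapley
checks at 25 sampled orderings — sizes chosen so the full suite
completes in minutes on one CPU while leaving the measured margins far
from their bounds. Further conventions: probability 0.5 is the
label cut for probabilistic families; BT emits hard 0/1 probabilities so
a fraction exactly at its threshold classifies as injured (≥ rule);
seeded operations restore the caller's RNG state, so results do not
depend on call order; derived child seeds stay below 2³¹.

## Known limitations

* The QC index is a brain-contour Dice, a simple stand-in for a richer
  registration-quality battery.
* Probabilities are not calibrated; the "possibly" band is a reporting
  convention, not a calibrated confidence.
* SVM probability fitting (Platt scaling inside libsvm) has internal
  randomness that is not fully controlled by the R seed; the
  determinism guarantees are stated for the other families.
* Per-hemisphere split features are out of scope: regions are bilateral
  by design (except the midline region), and laterality enters only
  through the report's hemisphere attribution.
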