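---
title: "Methods: multi-level agreement analysis of NIRS-IVUS and CTA plaque metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-level agreement analysis of NIRS-IVUS and CTA plaque metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqueagree)
```

## The problem

Coronary CT angiography (CTA) is the first-line non-invasive test for
coronary artery disease, but calcium blooms on CT: bright deposits bleed
into neighbouring voxels, blurring the lumen border and distorting plaque
quantification. Combined near-infrared spectroscopy / intravascular
ultrasound (NIRS-IVUS) does not suffer from blooming and serves as the
invasive reference standard. `plaqueagree` implements the full analysis
chain needed to quantify how calcium affects CTA's agreement with
NIRS-IVUS, at three nested resolutions:

* **segment level** — one vessel segment imaged by both modalities;
* **lesion level** — contiguous stretches of high plaque burden;
* **cross-sectional (frame) level** — individual matched cross-sections.

Inputs are *annotation tables*, one row per analysed cross-section with
lumen and vessel areas and circumferential tissue arcs; image analysis,
end-diastolic frame selection, and cross-modality co-registration happen
upstream and are out of scope. Frames arrive pre-matched.

## Metrics

With per-frame lumen area $L(z)$ and vessel (EEM / outer wall) area
$V(z)$ along pullback position $z$ (mm, proximal → distal):

* plaque area $P(z) = V(z) - L(z)$, plaque burden
  $\mathrm{PB}(z) = 100\,P(z)/V(z)$;
* volumes by trapezoidal integration over the *actual* positions
  (end-diastolic gating makes spacing irregular, so frame count times a
  nominal spacing would be biased);
  $\mathrm{TAV} = \int V - \int L$ and
  $\mathrm{PAV} = 100\,\mathrm{TAV} / \int V$;
* the spread-out plot unrolls the segment into an angular-bin ×
  frame grid (360 one-degree bins by default). Cells are multi-label: a
  bin may carry lipid (from the NIRS chemogram) and calcium (from the
  IVUS arc) simultaneously, because NIRS detects lipid irrespective of
  overlying calcium — exclusive labels would force an arbitrary
  precedence;
* LCBI and CaBI are flagged cells over total cells × 1000; every grid
  cell counts in the denominator (no guide-wire exclusion — callers who
  need one can mask upstream);
* maxLCBI$_{4\mathrm{mm}}$ scans all *maximal* 4 mm windows of columns —
  windows that cannot be extended at either end without exceeding 4 mm.
  Maximality at both ends makes the scan invariant to reversing the
  pullback direction; scanning only start-anchored windows would not be,
  because right-edge-truncated windows are not left-maximal. Segments
  shorter than 4 mm fall back to the whole-segment LCBI with a warning
  rather than an error, so batch runs keep going and the frames are
  flagged for audit;
* mean calcium area is calcium volume / segment length; mean calcium arc
  is $360 \times \mathrm{CaBI} / 1000$ degrees;
* CTA tissue classes (necrotic core / fibro-fatty / fibrotic / calcium)
  come from Hounsfield-unit cut-offs. The thresholds are *configuration*,
  not constants: the shipped 76 / 131 / 351 HU defaults are the
  implementer's choice from the histology-derived CT
  plaque-characterisation literature, and intervals are half-open with
  boundary values assigned to the upper class so classification is
  deterministic.

## Lesion rules

A lesion needs at least three *consecutive* frames with PB ≥ 40 %. Two
qualifying runs merge when the sub-threshold gap between them spans less
than 5 mm (measured last-frame-position to first-frame-position; a gap of
exactly 5 mm separates). Merging chains transitively. One- and two-frame
runs can be absorbed into a merged lesion but can never found one — the
three-consecutive-frames requirement applies to at least one constituent
run. Lesions are defined on NIRS-IVUS and transferred to the paired CTA
frames index-for-index, regardless of the CTA burden there.

Lesion geometry: MLA is the minimum lumen area over the span; the
reference on each side is the *least-diseased* (minimum-PB) frame within
5 mm of the lesion edge, excluding frames inside any lesion; reference
areas average the two sides (one-sided when only one side exists, fields
`NA` when neither does); the remodelling index is the vessel area at the
MLA frame over the reference vessel area. The literature does not fix a
single remodelling convention; this one (MLA-frame anchor, min-PB
references) is declared and configurable via the lesion-policy options of
`run_config()`.

## Agreement statistics

* **Paired comparison** — Wilcoxon signed-rank, two-sided; exact null for
  ≤ 25 untied non-zero differences, normal approximation with continuity
  and tie correction otherwise.
* **Bland–Altman** — parametric (mean ± 1.96 SD) at frame level where n
  is large; non-parametric at segment/lesion level where differences are
  few and skewed: median and 2.5th/97.5th percentiles as intercept-only
  quantile regressions. All quantiles in the package are the pinball-loss
  minimiser, with the *lower* endpoint taken when the minimiser set is an
  interval — one fixed, platform-independent convention for Bland–Altman
  bounds and tercile/decile cut-points alike (ties at a cut-point go to
  the lower group).
* **ICC** — two-way random-effects, absolute agreement, average of the
  k = 2 modalities:
  $\mathrm{ICC}(A,2) = \sigma^2_u / \left(\sigma^2_u + (\sigma^2_m +
  \sigma^2_e)/2\right)$, components by REML (`lme4`), floored at zero.
  For the balanced unadjusted layout (each unit measured once per
  modality) the REML solution coincides with the two-way ANOVA moment
  estimator, so `icc_mixed()` uses the closed form there (`engine =
  "auto"`) — this is what makes a 2000-resample cluster bootstrap and
  frame-level ICCs on tens of thousands of pairs affordable; the
  equivalence is itself under test. Adjusted ICCs add the calcium
  covariate as a restricted-cubic-spline fixed effect (3 knots at
  segment/lesion level, 5 at frame level) and always use the mixed
  model. Confidence intervals are cluster non-parametric bootstrap
  percentile intervals — there is no canonical closed-form CI for this
  clustered, unbalanced design, and the cluster bootstrap stays valid
  under it; the cluster defaults to the unit and should be the patient
  for multi-vessel data. Adjusted and unadjusted ICCs
  are called significantly different only when their CIs are disjoint.
* **RCS basis** — Harrell's truncated-power construction, k − 1 columns
  including the linear term, knots at the conventional quantiles
  (0.10/0.50/0.90 for 3 knots; 0.05/0.275/0.50/0.725/0.95 for 5). When a
  covariate is heavily tied — zero-inflated calcium areas tie the raw
  quantile knots — knots fall back to quantiles of the distinct values.
* **Stratified heterogeneity** — stratum ICCs are Fisher-z transformed,
  their z-scale SEs recovered from the CI widths, and homogeneity tested
  with inverse-variance Cochran's Q (χ², G − 1 df); the
  DerSimonian–Laird τ² is reported. The construction is declared: the
  source analysis says only "tau-based".
* **Interpretation bands** — < 0.50 poor, 0.50–0.75 moderate, 0.75–0.90
  good, > 0.90 excellent; boundary values 0.50 → moderate, 0.75 → good,
  0.90 → good.

## Interaction models

Does calcium modify the NIRS-IVUS ↔ CTA relationship? At segment and
lesion level, sample sizes are small and outcome distributions skewed, so
the NIRS-IVUS measurement is modelled as an *ordinal* outcome over its
distinct observed values — semiparametric cumulative-logit (proportional
odds) regression, avoiding arbitrary binning. With n distinct values the
model carries n − 1 ordered intercepts; the in-package maximum-likelihood
fit parameterises the intercepts by log-increments (ordering holds by
construction) and exploits the fact that each observation touches only
its two bracketing thresholds, so gradient evaluations are O(n) and fits
with hundreds of categories take well under a second. `MASS::polr` is the
independent cross-check on few-category data in the test suite.

The design: CTA value as RCS (3 knots at segment/lesion, 5 at frame
level), calcium area as RCS (3 knots), and the interaction as the product
of the two *linear* terms only — a 1-df test, deliberate at lesion-level
sample sizes; a full spline tensor would dilute power and destabilise the
fit. The interaction p-value is the likelihood-ratio test of that term.
At frame level an ordinary-least-squares fit with the same design is
used, with subject-clustered (CR0 sandwich) interaction inference by
default — frames within a patient are strongly dependent and model-based
standard errors would be anti-conservative. The proportional-odds fits
default to independent units (the pipeline's segment/lesion analyses);
a cluster-robust Wald option exists (`cluster =`) for multi-segment
patients. Predicted-median difference curves (`difference_curves()`)
evaluate the fitted NIRS − CTA difference over the observed 1st–99th
percentile calcium range at the CTA quartiles.

## The synthetic cohort generator

No patient imaging is distributable, so the generator *is* the study
condition for every end-to-end check. It emulates, at configurable scale,
the structure the statistical machinery assumes:

* cohort dimensions echoing the emulated design: 64 subjects × 3 vessels
  × ~120 matched end-diastolic cross-sections (≈ 23 000 pairs);
* log-scale areas with subject (SD 0.35) and vessel (SD 0.15) random
  effects and AR(1) longitudinal smoothness (coefficient 0.9) so lesions
  are contiguous, as the lesion definition requires; median vessel area
  13 mm², median plaque-burden fraction 0.38;
* multiplicative noise and modality bias: observed between-modality
  biases scale with vessel size, so additive noise would be wrong. CTA
  areas are truth × exp(δ₀ + δ₁·Ca): lumen δ₀ = −0.29, δ₁ = −0.015 mm⁻²
  (blooming shrinks the lumen more, the more calcium); plaque δ₀ = −1.2,
  δ₁ = +0.12 mm⁻² (CTA misses soft plaque but overestimates with
  calcium). CTA vessel = CTA lumen + CTA plaque, keeping geometry
  consistent;
* zero-inflated calcium (65 % calcium-free frames) with two-state Markov
  persistence along the pullback, gamma-distributed deposit areas, CTA
  blooming overestimation (+0.2 log) and small-deposit miss; lipid
  patches as a two-state Markov chain with a drifting contiguous angular
  block, attenuated on CTA in proportion to calcium.

Parameters were chosen once, at design time, to land in the realistic
range of the emulated cohort (vessel and plaque medians, calcium
prevalence, lesion frequency) and are not tuned against test outcomes.
What the generator does **not** emulate — and hence what green tests do
*not* establish about real data: image-level artefacts, co-registration
error, segment-length mismatch between modalities, analyst variability,
and non-stationary disease patterns along a vessel.

For the calibration and power simulations the package's checks use the
simpler unit-level generator the design prescribes
(NIRS = CTA + γ·Ca·CTA + noise) at n = 400 units: the null (γ = 0) and
the effect size γ = 0.04 mm⁻², the latter fixed by a design-stage pilot
power analysis (power ≈ 0.55 / 0.90 / 1.00 at γ = 0.02 / 0.03 / 0.04)
targeting at least 80 % power with margin. The proportional-odds LRT
carries ~n nuisance thresholds and is mildly anti-conservative in small
samples; its size is checked at the design's n = 400, where it sits
within the nominal band, and small-sample p-values near 0.05 should be
read with that in mind.

## Numerical choices and degenerate inputs

* Quantiles: pinball minimiser, lower endpoint on ties (above).
* Variance components floored at 0; ICC clipped to [−1, 1].
* Cumulative-logit fits start from the empirical cumulative logits and
  raise an estimation error on non-convergence (e.g. separation) rather
  than returning a doubtful optimum.
* Degenerate strata (all covariate values equal) collapse to one group
  with a warning; sub-4 mm segments warn and fall back (above);
  lesion-free segments return an empty table, not an error.
* All stochastic steps (bootstrap, simulation) consume an explicit seed;
  `run_pipeline()` refuses to run without one, and a manifest records
  seed, package version, and a configuration hash so a report bundle is
  reproducible byte-for-byte.

## Problem sizes used by the shipped checks

The test-suite simulations are sized for a laptop-class single core:
metric and lesion oracles at 1000 random fixtures; ICC recovery at 500
subjects with 500-resample bootstraps (100 replicates for CI coverage);
interaction-test calibration at 1000 null replicates and 200 power
replicates; the end-to-end determinism check runs the full "paper-like"
cohort twice. `scripts/acceptance.R` reruns the complete pipeline on the
full "paper-like" cohort and writes the headline numbers as JSON.

## Known limitations

* The remodelling-index and reference-segment conventions are declared,
  not canonical; alternatives (e.g. max-PB anchor) change lesion-level
  numbers.
* The proportional-odds interaction test treats segments/lesions as
  independent unless a cluster is supplied.
* Frame-level calcium strata can be effectively two groups when most
  frames are calcium-free: tercile cut-points tie at zero and the
  ties-to-lower rule empties the middle group. This mirrors real
  zero-inflated calcium distributions and is reported as such rather
  than silently re-binned.
* HU classification operates on caller-supplied HU samples; no image
  segmentation is attempted.
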