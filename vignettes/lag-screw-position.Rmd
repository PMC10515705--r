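---
title: "Lag-screw position metrics and cut-out risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lag-screw position metrics and cut-out risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtad)
```

This vignette is the package's account of its science: the geometric model
behind the six lag-screw position parameters, the synthetic-cohort
generator and its outcome model, the statistical pipeline, and the design
choices made where the underlying clinical constructions are ambiguous.

## Geometric model

Each radiographic view (AP, lateral) is treated as an independent 2-D
scene. The femoral head is modelled as a circle; the femoral neck central
axis and the lag-screw axis are lines with unit directions pointing
medially. The fixed frame is +x medial in both views, +y superior in AP
and +y anterior in LAT; left hips are mirrored in x at read time so the
conventions never branch on side.

**Calibration.** Radiographic magnification is unknown and differs between
views, so each view is scaled independently by
`true_diameter / measured_diameter`, using the 12.5 mm lag-screw diameter
visible in the image. Every metric is invariant under per-view uniform
magnification by construction (and by property test).

**The apex.** Clinical papers point at "the apex" on the image without a
geometric definition. We define it as the intersection of the neck central
axis with the head circle on the medial side — the construction implicit in
Baumgaertner's TAD, which makes the far screw-axis surface point coincide
with the apex exactly when the screw is central. This is a reconstruction:
an annotator who marks the apex freehand will differ from the circle model
by the local deviation of the head contour from circularity.

**The modified TAD.** With A the screw tip, B the far intersection of the
screw axis with the head circle, and C the apex, the AP part is
`AB + s·BC` where `AB` is measured along the screw axis, `BC` is the
straight chord from B to C (a chord, not an arc — these are ruler distances
on a radiograph), and `s` is +1/−1/0 as B lies superior/inferior/on the
neck central axis (|offset| < 1e−6 mm counts as "on"). The lateral part is
the ordinary lateral tip-apex distance. Consequences worth stating:

* central screws satisfy mTAD = TAD identically;
* reflecting the AP geometry across the neck axis preserves AB and BC and
  flips the sign, so mTAD(superior) − mTAD(inferior) = 2·BC;
* a tip beyond the far head surface gives AB < 0; it is flagged as
  penetration and reported, never turned into an error, because penetrated
  screws are clinically real and must not crash a batch.

**Comparators.** TAD is the two-view calibrated tip-apex sum. Cal TAD
translates the AP reference axis to run through a marked calcar point
(parallel to the neck axis) and measures the tip to that axis' far
intersection with the head circle. Parker's ratio is measured along the
head-circle diameter perpendicular to the neck axis, as
100 × (distance from the inferior (AP) / anterior (LAT) end to the
screw-axis crossing) / diameter; the original 1992 description (head versus
neck width) is ambiguous in the modern literature, so the choice is
isolated behind one operation and can be swapped. Cleveland zones use the
signed tip offsets from the neck axis in each view, cut into thirds of the
head radius; numbering is chosen so zone 1 is superior-anterior and the
classic safe zones are {5, 6, 8, 9} (centre-centre, centre-posterior,
inferior-central, inferior-posterior). The axis-blade angle is the signed
AP angle between neck and screw axes, negative for superior deviation, so
the protective rule "ABA > −10°" reads "at most 10° of superior deviation".

Metrics are stored at full precision; report tables round mm and percent to
one decimal and AUC to three, matching clinical table formats.

## Synthetic cohorts

No patient data ship with the package; the generator exists so that every
pipeline stage is testable end to end, including calibration and side
normalisation, and so that parameter-recovery checks can run against known
truth.

Per case, the generator draws a head radius (23 ± 2 mm, truncated to
17–30), then per view a screw-axis angular offset from the neck axis
(sd 6° AP, 5° LAT, truncated at ±25°), a perpendicular offset of the screw
axis from the head centre (−2 ± 5 mm AP — slightly inferior, reflecting how
surgeons aim — and 0 ± 4 mm LAT, truncated to ±0.72 r so the axis always
crosses the head), and a tip depth to the far surface (9 ± 3.5 mm AP,
10 ± 3.5 mm LAT, truncated to 1–25 mm). Truncation is by clamping, which
keeps the draws vectorised and deterministic; the distortion at the stated
sds is negligible. Covariates use the prevalences of elderly DHS series:
AO/OTA A1.2/A1.3/A2.2/A2.3 at .514/.257/.165/.064, reduction
Good/Acceptable/Poor at .532/.422/.046, Singh index mass concentrated on
grades 3–4 (80%).

Landmarks are written in image units after multiplying each view by its own
magnification factor (uniform 1.05–1.25) and randomly mirroring half the
cases to left hips, so reading them back exercises the full calibration
path. The latent true mTAD is computed analytically inside the generator
and is checked, in the tests, to agree with the measurement pipeline to
1e−9 mm — a deliberate dual route.

**Outcome model.** Cut-out is Bernoulli with
`logit p = −2.3 + 0.30·(mTAD_true − 25) + pattern effect + reduction effect`
(pattern effects 0/0.3/1.0/1.6 across A1.2–A2.3, reduction 0/0.6/2.0). The
published tables do not permit estimating real coefficients, so these were
chosen once to reproduce the qualitative study conditions — an overall
cut-out rate near 12% and population AUC for mTAD near 0.9 — and then
frozen. A step-risk alternative (`step_outcome_model()`: p jumps from 0.02
to 0.5 at 25 mm true mTAD) provides a known decision boundary for cut-off
recovery checks. A single seeded RNG stream with a fixed field order makes
cohorts byte-identical across runs for a given seed.

What the simulator does *not* emulate: real annotator noise in landmark
placement, non-circular head contours, correlated bone-quality effects,
and time-to-event structure of cut-out. Passing recovery tests therefore
demonstrates that the pipeline is correct and well calibrated under the
generative model, not that the published clinical effect sizes are
reproduced — those depend on the unavailable radiograph set.

## Statistical pipeline

AUC is computed by the Mann–Whitney pair-count formula via ranks, which
equals the trapezoidal area under the empirical ROC (asserted to 1e−12 in
tests against a brute-force pair count). Candidate cut-offs are midpoints
between adjacent distinct observed values; the Youden-optimal cut-off
maximises sensitivity + specificity − 1, with ties broken toward higher
specificity, and the reported clinical cut-off is additionally snapped to
the nearest integer millimetre, the resolution at which thresholds are
quoted. Risk direction is auto-detected (scores are negated when AUC < 0.5,
as for the axis-blade angle) with an explicit override.

Confidence intervals use the DeLong placement-value variance with a Wald
interval clipped to [0, 1]; published tables in this literature sometimes
show unclipped bounds above 1, which we deliberately do not reproduce.
Group comparisons use the Mann–Whitney test (exact for untied samples of at
most 20 per group, tie-corrected normal approximation otherwise). For
categorical associations a Pearson chi-square is used, switching the
p-value to Fisher's exact test whenever any expected count is below 5, with
the method recorded. No multiplicity correction is applied, matching the
univariate reporting style of the cut-out literature; users comparing many
parameters should adjust externally.

Degenerate inputs are first-class: outcomes without variation raise a
specific error; all-tied scores flag the cut-off as degenerate; malformed
landmark rows and cases missing a view are skipped with counted warnings;
per-metric failures inside a batch are recorded per case rather than
aborting.

## Problem sizes and checks

The property and recovery checks run at sizes chosen to keep the whole
suite quick while leaving comfortable statistical margins: 1000 random
geometries for the identity suite, 1000 circle-line instances and 200
score sets against independent oracles, cohorts of n = 5000 for cut-off
(±2 mm) and AUC (±0.03 against a 50 000-draw population reference)
recovery, 2000 null 3 × 3 tables for chi-square size (5% ± 1.5%), and 500
replicates for DeLong coverage (banded 92.5–97.5%). The 3 × 3 null design
for the size check avoids the discreteness of small 2 × 2 tables, which
makes the rejection rate at the nominal level unstable regardless of
implementation.

## Known limitations

* The circle model of the femoral head and the geometric apex are
  reconstructions of constructions that clinicians perform freehand.
* Parker's ratio follows the head-width reading; if the neck-width reading
  is wanted, only `parker_ratio()` needs replacing.
* The outcome model is a convenience for testing and power exploration;
  its coefficients are not estimates of any published effect.
* 2-D per-view geometry cannot capture out-of-plane screw obliquity; no
  3-D reconstruction from the biplanar pair is attempted.
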