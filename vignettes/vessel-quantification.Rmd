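---
title: "Standardized instance-level quantification of microvessels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized instance-level quantification of microvessels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselquant)
```

## The problem

Counting immunostained blood vessels (for example CD34-positive vessels in
lymph-node sections) from a segmentation mask is not the same problem as
producing the mask. Pixel-level overlap scores (Dice, IoU) reward a model
that paints roughly the right regions, but a pathologist asking "how many
vessels are in this node, and how large are they?" needs each vessel as a
separate, measurable object. That requires a reproducible chain:
mask → instances → cleanup → one-to-one comparison with a reference
annotation → count-agreement statistics. `vesselquant` implements that chain
as a fixed, auditable procedure, plus a synthetic vessel-field generator so
the entire chain can be validated end to end without any slide data.

## The model and its assumptions

**Calibration and morphometry.** All measurements are physical. A pixel
pitch $s$ (µm/px, default 0.137, a typical 40x scan) converts pixel counts
to areas ($A = n s^2$) and indices to centroids (pixel-centre convention:
pixel $(i, j)$, 0-based, sits at $((j+0.5)s, (i+0.5)s)$, y increasing
downward). Each instance carries its equivalent-circle radius
$r = \sqrt{A/\pi}$, the radius of the circle with the object's area; this
single length scale anchors every distance gate below.

**Fixed post-processing** (in this order, never reordered):

1. *ROI restriction.* A convex hull over the annotation point set serves as
   a proxy for the capsule-bounded region; an instance is kept iff its
   centroid lies inside or on the hull. Collinear annotation points are an
   error, not an empty region — a silently empty ROI would corrupt counts.
2. *Minimum area.* Objects with $A < 6\,µm^2$ (configurable) are removed;
   such fragments are typically staining noise. "Smaller than" is strict:
   an object exactly at the threshold survives.
3. *Non-maximum suppression.* Duplicate detections are resolved greedily
   over instances sorted by decreasing area (ties by ascending id): an
   instance is suppressed when its centroid lies within
   $0.7 \cdot \min(r_i, r_j)$ of an already retained instance. A single
   greedy pass is provably a fixed point, so "iterate to convergence" and
   "single pass" coincide. The default mode keeps the larger record
   unchanged; an optional union mode merges a cluster into one record with
   summed area and area-weighted centroid — a record-level approximation of
   a pixel union (the pipeline has no raster at that stage), so the merged
   perimeter is reported as missing rather than invented.

**Matching.** Predicted and reference instances are paired one-to-one by
the Hungarian method over a gated cost table. In the default geometric mode
a pair $(p, g)$ is admissible iff, strictly,
$$d(p,g) < \alpha \cdot \min(r_p, r_g) \quad\text{and}\quad |A_p - A_g| / A_g < \tau,$$
with $\alpha = 1$ and $\tau = 0.30$ by default; a reference mode instead
thresholds the closed-form IoU of the two equivalent circles at 0.50 (the
comparator, `>=` by default, is exposed because "approximately 0.50" does
not fix it). The assignment cost on admissible cells is the centroid
distance — the only pairwise dissimilarity the gates themselves define.
Forbidden cells are excluded through a sentinel cost larger than the sum of
all admissible costs, which makes the solver maximise matched pairs first
and minimise total distance second. Matched pairs are TP; unmatched
predictions FP; unmatched references FN.

The solver is a shortest-augmenting-path (Jonker–Volgenant style) algorithm
written for this package because no linear-assignment solver is available
in the dependency set; it is verified in the test suite against exhaustive
permutation enumeration on hundreds of random gated problems.

**Metrics and agreement.** Pixel level: Dice $= 2TP/(2TP+FP+FN)$ and IoU
$= TP/(TP+FP+FN)$, restricted to an ROI by the same centre-in-polygon rule
as instances. Instance level: precision, recall, F1 with Wilson score
intervals. A 0/0 ratio is reported as `NA` ("undefined"), never coerced to
0 or 1 — in a low-prevalence region the difference between "no vessels to
find" and "found nothing" is material. Count agreement at the ROI level:
bias (pred − gt), MAE, the two-way mixed single-measure *consistency*
intraclass correlation ICC(3,1) $= (MS_R - MS_E)/(MS_R + MS_E)$ for two
raters, Bland–Altman limits mean $\pm 1.96\,$SD (sample SD, $n-1$; 1.96
literally, not a t quantile), and proportional-bias OLS of the difference on
the mean count, adjusting for ROI area. With very few ROIs the joint
two-covariate fit has zero residual degrees of freedom, so its p-values are
undefined; both the joint and the two single-covariate fits are therefore
returned, labelled.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `microns_per_pixel` | 0.137 | µm/px | physical pixel pitch |
| `min_area_um2` | 6 | µm² | staining-noise floor (step 2) |
| `nms_factor` | 0.7 | — | duplicate gate multiplier (step 3) |
| `alpha` | 1.0 | — | centroid gate multiplier |
| `tau` | 0.30 | — | max relative area difference |
| `iou_threshold` | 0.50 | — | equivalent-circle IoU gate (reference mode) |

The sensitivity module sweeps each parameter one at a time (α over 0.1–1.0
step 0.1 — the step is this package's choice, uniform over the documented
range; minimum area over 2–8 µm² step 1; NMS over 0.3–0.7 step 0.1), holding
the others at base values, and recomputes the full pipeline per value. The
recommended minimum-area threshold minimises mean MAE across ROIs, with
ties broken by higher mean F1, then by the smaller threshold. Blocked
comparisons across ROIs use the Friedman rank test (tie-corrected
chi-square; a fully tied table carries no information and is reported as
statistic 0, p 1) and paired Wilcoxon signed-rank tests with a Bonferroni
adjustment always reported alongside the raw p. The Wilcoxon wrapper drops
zero differences, uses the exact null for n ≤ 25 without ties, and the
continuity-corrected normal approximation otherwise; the method used is
recorded in the output.

## What the synthetic generator emulates — and what it does not

`generate_field()` places non-overlapping parametric vessel profiles by
rejection sampling and rasterises them: filled discs (capillary
cross-sections), annuli (vessels with unstained lumina), and curved tubes
(longitudinal cuts), mixed 0.3/0.4/0.3. Instance areas follow a log-normal
with median 100 µm² and log-SD 1.2, truncated below 10 µm² and with a
separately injected large-vessel tail above 5,000 µm² — matching nodal
regions whose per-ROI medians sit near 63–128 µm² with maxima four orders
of magnitude above, at densities around 1.3·10⁻⁴ vessels/µm².
`degrade()` turns a truth field into a "prediction" with the realistic
error modes of a segmentation model: instance dropout, sub-threshold
false-positive specks, fragmentation of large vessels into dot-like pieces,
and centroid/area measurement noise — every event written to a truth ledger
so the expected TP/FP/FN after post-processing are known by construction.

Two deliberate conveniences keep the construction exactly analysable:
bounding circles of placed shapes are disjoint (so no NMS gate can fire
between true instances), and fragment radii are capped so a fragment can
never suppress, or be suppressed by, any other detection. A green
end-to-end test therefore establishes that the pipeline, matcher and
statistics do exactly what they claim on fields with known answers; it does
*not* establish anything about a particular stain, scanner or segmentation
model — real masks have touching vessels, partial-volume boundaries and
spatially correlated errors that the generator intentionally omits.
The paper-scale defaults are generated at a desk-scale calibration of
1 µm/px: a 500-vessel region at realistic density spans ~2×2 mm, which at
0.137 µm/px would be a ~14,000² px raster (~0.8 GB) — out of proportion for
a validation suite, and the procedure under test is calibration-invariant
by construction. No quantitative fragmentation rate is published for the
error modes emulated here; scenario defaults are synthetic conventions,
labelled as such.

## Numerical choices

* **Perimeter.** The boundary length of a rasterised instance is estimated
  by the 4-direction Cauchy–Crofton formula
  $P \approx (\pi/8)\,(n_h + n_v + (n_{d1} + n_{d2})/\sqrt{2})$ from
  boundary-crossing counts. The more obvious marching-squares polygon
  length was measured here to overestimate smooth boundaries by 6–8% (the
  classical staircase bias), which breaks the package's own accuracy bound
  (disc and ellipse perimeters within 5% of analytic values); Crofton meets
  it with ~0.5–2% error on those shapes. Perimeters of merged (union-mode)
  records are `NA`.
* **Connectivity.** Foreground components are 8-connected by default so
  slender diagonal vessel walls do not shatter; 4-connectivity is available.
* **Circle IoU.** Exact two-disc lens formula with containment and
  disjoint branches, `acos` arguments clamped against tangency roundoff; no
  numerical integration anywhere.
* **Strictness.** Both matching gates and the minimum-area rule are strict
  (`<`), so boundary cases are decided, not tolerance-dependent; the
  equivalent-circle IoU comparator defaults to `>=`.
* **Determinism.** Every stochastic operation consumes a locally seeded RNG
  stream and restores global state; identical seeds give bit-identical
  rasters and byte-identical outputs. Assignment and NMS tie-breaks are
  fixed (solver order; descending area then ascending id).
* **Degenerate inputs.** Fewer than 3 or collinear hull points, empty count
  tables, zero-trial Wilson intervals and self-intersecting polygons raise
  a typed input error; undefined statistics (0/0 metrics, ICC without
  between-ROI variance, all-zero Wilcoxon differences) are `NA` with the
  reason recorded, never silent zeros.

## Design choices where the design was open

* The equivalent radius is $r=\sqrt{A/\pi}$ — the only dimensionally
  consistent reading of an "equivalent radius" used inside a distance gate.
* The centroid gate defaults to $\alpha = 1$ ($d < \min(r_p, r_g)$); the
  stricter $\alpha = 0.5$ variant seen in some reports is one sweep value,
  not the default, and both are first-class configurations.
* "min(r)" in the NMS rule is the minimum of the two instances' equivalent
  radii, mirroring the pairwise matching gate it abbreviates.
* ROI membership is by centroid, the cheapest rule consistent with
  counting; partial-overlap rules would change counts without a reference
  definition.
* ICC(3,1) is the Shrout–Fleiss two-way mixed, single-measure,
  *consistency* coefficient; the convention is echoed in the report
  metadata because the name alone does not pin down the form.
* The per-ROI percent bias needs a denominator; the mean reference count is
  the default and the convention is labelled in the output
  (`pooled_mean` is the alternative).
* The probability threshold for probability-map input defaults to 0.5 and
  is configurable; fixed operating points from any particular model do not
  transfer.

## Known limitations

* Instance pixel masks are not carried through matching; the
  equivalent-circle representation under-scores elongated vessels, which is
  partly mitigated (as in the procedure this package standardises) by
  pairing centroid proximity with the relative-area gate.
* Union-mode NMS merges records, not pixels (see above).
* Whole-slide pyramid formats are out of scope; masks are single-channel
  TIFF rasters of cropped regions (PNG is not supported — no PNG codec
  exists in the dependency set).
* Many-to-one (fragment-aggregation) matching credit is deliberately not
  offered; fragmented large vessels are counted as FP + FN, which is what a
  fixed one-to-one procedure measures.

## A worked end-to-end run

```{r}
truth <- generate_field(field_spec(width_um = 900, height_um = 900,
                                   target_count = 90, seed = 5))
pred <- degrade(truth, degrade_spec(fn_rate = 0.1, fp_speck_rate = 0.15,
                                    seed = 6))
pp <- apply_fixed_pipeline(pred$instances, truth$roi_points)
pp$audit
det <- detection_summary(match_instances(pp$instances, truth$instances))
det
```

The audit table is the procedure's receipt: every removed instance is
attributed to the step that removed it, and the ledger inside `pred`
records why each prediction exists at all.
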