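---
title: "Quantifying amyloid plaque histology with PlaqueQuant"
author: "PlaqueQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amyloid plaque histology with PlaqueQuant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PlaqueQuant)
```

## The measurement problem

Amyloid-depositing transgenic mice (e.g. APP/PS1 lines) are the standard
in-vivo system for studying how amyloid-β is produced, aggregated and
cleared, and pharmacological modulation of the astrocytic water channel
AQP4 is one way of perturbing the perivascular clearance routes that drain
interstitial amyloid. The downstream readouts are histological: brightfield
whole-slide scans double-stained for total Aβ (4G8/DAB, brown) and for
vascular endothelium (CD31/Fast Red), confocal double immunofluorescence
for the Aβ40 and Aβ42 isoforms, and thioflavin-S (ThS) staining of the
fibrillar (β-sheet) amyloid fraction, quantified per animal and per
anatomical region (neocortex, hippocampus, striatum, thalamus) and compared
across treatment groups.

PlaqueQuant implements that whole measurement chain as reusable, tested R
functions: stain separation, plaque and vessel segmentation, per-plaque
morphometry (area, maximum diameter, integrated optical density, fractal
dimension), plaque–vessel spatial statistics with a 0-µm contact
convention, two-channel colocalization, fibrillar-fraction quantification,
a hierarchical statistics layer, and behavioral metrics for the open-field
and novel-object-recognition assays that usually accompany such studies.
Because real slide scans of this kind are rarely public, the package also
contains a synthetic histology generator with per-object ground truth, so
that every stage of the chain can be validated quantitatively.

## Stain model and unmixing

Brightfield chromogens follow Beer–Lambert attenuation. With per-pixel
stain densities $d_s \ge 0$ and unit optical-density colour vectors $v_s$
(one 3-vector per stain, $\|v_s\|_2 = 1$), transmitted intensity in channel
$c$ is

$$I_c = W \cdot 10^{-\sum_s d_s v_{s,c}},$$

where $W$ is the white level (255 for 8-bit scans). `separateStains()`
inverts this: per-channel optical density $OD_c = -\log_{10}(I_c / W)$
(intensities clamped at 0.5 to guard the logarithm) is projected onto the
stain basis by solving the 3×3 linear system, and negative densities are
clipped to zero. This is the reproducible counterpart of defining a
segmentation by sampling the RGB profile of DAB in a commercial package:
the stain vectors *are* the sampled profile, applied identically to every
image. Defaults are the standard published hematoxylin and DAB vectors and
a Fast Red vector from the chromogen's nominal colour; a study using other
chromogens supplies its own `StainProfile`.

A deliberate design choice: `renderBrightfield()` returns real-valued
intensities on the 0–255 scale, and quantization to 8-bit integers happens
only when an image is written to disk. The unmixing matrix inverse
amplifies per-channel errors by up to ≈5×, so 8-bit rounding alone injects
up to ≈0.03 OD of density error at strong staining; keeping the in-memory
pipeline real-valued means analysis accuracy is set by the optics model,
not by the file format, while files on disk remain ordinary 8-bit TIFFs.

## Segmentation

Plaques are segmented from the DAB density map by a fixed threshold
(default 0.15 OD), followed by a morphological closing (default radius
1 px) that merges a dense core with its surrounding corona, hole filling
(so pale plaque centres count as part of the deposit), 8-connected
component labelling, and a minimum-area filter (default 20 µm²). All
parameters sit in `SegmentationParams` and are applied identically to
every image of a study. Vessels use the Fast Red map at 0.20 OD with no
minimum size (capillary cross-sections are tiny); ThS images use an
intensity threshold (default 100 on the 0–255 scale) with the same
component logic. Segmentation is monotone in its threshold: raising the
cutoff can only shrink the segmented area.

## Morphometry

* **Area** – foreground pixel count × pixel area (µm²).
* **Maximum diameter** – the maximum pairwise distance between foreground
  pixel centres (a Feret diameter), computed on the convex hull; a single
  pixel has diameter 0. Sub-pixel boundary geometry is deliberately
  ignored: pixel-centre semantics are resolution-consistent and exactly
  checkable against a brute-force oracle.
* **Integrated optical density (IOD)** – ROI area × mean pixel intensity
  over the ROI. The intensity is the deconvolved DAB optical density by
  default, because OD is linear in stain amount and reproducible across
  scanners, whereas "average pixel intensity" in commercial packages is
  scale-ambiguous; a raw inverted-intensity variant is available via the
  pipeline's `iod_source` switch for comparability. The product form and
  the sum form $\sum_i OD_i \cdot a_{px}$ agree identically.
* **Fractal dimension** – box counting: the mask is cropped to its
  bounding box and padded into a power-of-two square (at least 16 px);
  boxes of size $s = 2, 4, \ldots, \mathrm{side}/2$ anchored at the
  bounding-box origin are scanned for foreground, and FD is the OLS slope
  of $\log N(s)$ on $\log (1/s)$. A single anchored grid is the default
  (offset averaging is available but off), and ROIs whose bounding box
  cannot support three box sizes raise an error advising to skip FD for
  tiny ROIs. On analytic fixtures the estimator recovers dimension 1
  (line), 2 (filled square), $\log_2 3 \approx 1.585$ (Sierpinski
  triangle) and $\log_3 8 \approx 1.893$ (Sierpinski carpet), and it is
  invariant under translation and 90° rotation. Absolute FD values from
  commercial implementations differ in grid policy, so only such
  controlled fixtures and rank behaviour are meaningful cross-package.

Per-region densities divide by the *region* area in mm² — not the field
area — matching the µm²/mm² and counts/mm² reporting convention.

## Plaque–vessel spatial statistics

The nearest-vessel distance of a plaque is the minimum over its pixels of
the exact Euclidean distance transform of the vessel mask, times the pixel
size. A vessel running through or directly touching a deposit is scored at
0 µm: operationally, contact means some plaque pixel overlaps or is
8-adjacent to a vessel pixel (centre distance ≤ √2 px). From the pooled
per-plaque records the module reports the vessel-association frequency
(percentage of contact plaques), the mean distance of non-contact plaques
(0-µm plaques disregarded), and the Pearson correlation between plaque
diameter and vessel distance. Whether 0-distance plaques belong in that
correlation is ambiguous in practice, so both modes are computed
(`includeContacts`). Correlations pool plaques within a treatment group
across animals, which matches the very large n such analyses carry;
per-animal correlation is available by subsetting the records.

## Colocalization and fibrillar fraction

Channel expression areas are supra-threshold pixel counts × pixel area;
the Aβ40/Aβ42 ratio is reported as a percentage of areas. The two-colour
overlap statistic is the Manders-style coefficient

$$R = \frac{\sum_i A_i B_i}{\sqrt{\sum_i A_i^2 \sum_i B_i^2}}$$

over pixels supra-threshold in either channel (sub-threshold values
zeroed). It is bounded in [0,1], equals 1 exactly for identical channels
and 0 for disjoint supports, and is invariant to positive rescaling of
either channel — properties a bounded "overlapping coefficient" must have.
A set-overlap alternative (Jaccard index of the supports) is switchable.
Channel thresholds default to per-channel Otsu; the pipeline uses a fixed
configured threshold so group comparisons share one threshold pattern. The
coefficient is evaluated per plaque ROI (padded bounding window) and
averaged per region, since per-plaque analysis is what a several-hundred-
plaque study implies; a per-field value is one function call away. The
ThS/IHC ratio compares ThS-positive area density against immunostained
area density at the region-per-animal level, mirroring consecutive-section
practice.

## Statistics layer

The aggregation order treats the animal as the experimental unit:
mean-type metrics (diameter, FD, overlap, distances, per-plaque IOD) are
averaged per animal and region, cumulative metrics (total IOD, areas,
counts) are summed per animal and region, and group summaries are means ±
SEM over animal-level values (SEM = sd/√n with the n−1 denominator;
flagged `NA` for a single animal). Group comparisons use one-way ANOVA
followed by Fisher's LSD — unadjusted pairwise t tests on the pooled MSE
with N−k degrees of freedom, reported with the conventional
\*/\*\*/\*\*\* stars; LSD pairs are always reported with the omnibus p
carried alongside, leaving gating to the reader. Correlation magnitudes
are compared with the one-tailed Fisher Z test for independent
correlations, $Z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2) /
\sqrt{1/(n_1-3) + 1/(n_2-3)}$. Behavioral metrics cover time-in-centre
(frames inside the zone × frame interval) and the novel-object
discrimination index in both its fraction ($t_n/(t_n+t_f)$, chance 0.5)
and signed ($(t_n-t_f)/(t_n+t_f)$, chance 0) conventions — published
"preference indices" use either, so both are returned and neither is
presumed. Longitudinal REML mixed-effects modelling is out of scope by
design; the per-session tidy tables this package emits are exactly what
such a fit (e.g. `lme4::lmer`) consumes.

## The synthetic generator

`generateScene()` draws a calibrated field with:

* **Plaque archetypes.** *Diffuse* plaques are thresholded isotropic
  Gaussian blobs (gentle density 0.28–0.70 OD); *dense* plaques have a
  steep radial profile (up to 0.95 OD); *dense-core* plaques are a compact
  high-density disc (1.1 OD, radius 0.3× the plaque radius, at least
  3.5 µm so cores stay measurable) inside a fainter corona. Outlines get
  smooth low-order angular wobble so masks are not circles. Every in-mask
  density exceeds 0.28 OD, comfortably above the 0.15 segmentation
  threshold, so ground-truth masks and segmented masks coincide on
  noiseless renders — which is what makes exact recovery testable.
* **Vessels** are random-walk centrelines (step 1.25 px, small angular
  jitter) dilated to the vessel radius — enough structure to exercise the
  distance logic, with no claim to vascular realism.
* **Placement** is sequential rejection sampling, largest plaque first,
  with a separation margin that keeps masks disjoint even after closing.
  An optional planted contact fraction seeds that share of plaques
  directly on a vessel (falling back to natural placement when a short
  vessel cannot host another separated plaque), which lets cohort
  simulations plant group differences in vessel association.
* **Fluorescence construction.** The Aβ42 channel covers every plaque.
  For target overlap $\rho$ and area ratio $r$, the Aβ40 channel takes the
  innermost $\rho\sqrt{r}$ fraction of each plaque's pixels (ranked by
  distance from the centroid — Aβ40 concentrates in compact centres)
  plus the nearest free pixels outside any plaque up to a total area of
  $r$ × the plaque area. With equal channel intensities the pixelwise
  Manders coefficient of the noiseless pair is then exactly
  $\rho\sqrt{r}\,n_B / \sqrt{r\,n_B \cdot n_B} = \rho$, so recovery tests
  have an analytic target. Feasibility requires
  $\rho \le \min(\sqrt r, 1/\sqrt r)$, enforced at spec validation.
* **ThS layer.** A configurable fraction of dense and dense-core plaques
  carries a bright fibrillar core (the dense-core disc, or half the radius
  for dense plaques), giving ground truth for ThS counts.
* **Noise** is additive Gaussian on transmitted intensity (default sd 2 in
  8-bit units) — the simplest model that stresses thresholds.
* **Ground truth** is computed from the realised raster masks with the
  same pixel-centre semantics as the measurement modules (areas from
  pixel counts, diameters from hull distances, vessel distances from the
  exact distance transform), so generator and measurement agree by
  construction at raster precision and every discrepancy in a test is a
  genuine defect.

Default study conditions: 512×512 px at 1 µm/px, 25 plaques of 10–40 µm
maximum diameter (cortical mean diameters in such models are ≈20–24 µm;
no full size distribution is published, so the range brackets the means
without claiming calibration), type mix 40/35/25%
diffuse/dense/dense-core, 5 vessels of 4 µm radius, fibrillar core
fraction 0.5, Aβ40/Aβ42 area ratio 0.5 and overlap 0.6 (reported group
values span ≈0.18–0.48 for the ratio and 0.43–0.62 for the overlap).

What the generator does **not** emulate: tissue autofluorescence, scanner
illumination gradients and compression artifacts, section folds, 3-D
plaque structure, vascular branching morphology, and plaque-type specific
spatial clustering. Passing recovery tests therefore demonstrates that
the measurement chain is correct on images whose generative model is
known — not that segmentation parameters transfer to any particular
scanner; on real material the thresholds in `SegmentationParams` are the
knobs a study must fix once on control sections.

## Cohort simulation and the pipeline

`simulateCohortMetrics()` plants group effects the way a treatment would
express them: each virtual animal draws a lognormal burden effect
(default sd 0.25, i.e. interanimal CV ≈ 25%, typical of such cohorts) and
a Poisson plaque count with mean `base_plaque_mean` × the group's burden
multiplier; contact fractions, overlap and area-ratio levels are set per
group. The demo configuration uses burden multipliers 1.0 / 0.4 / 1.4 and
cortical contact fractions 0.28 / 0.18 / 0.26 for a control / clearance-
facilitator / clearance-inhibitor design, matching the direction and
magnitude of reported AQP4-modulation effects. `runPipeline()` chains
simulation, rendering, unmixing, segmentation, morphometry, vascular,
colocalization and ThS stages, aggregates per group, runs ANOVA + LSD per
region × metric, and writes CSV tables plus a `summary.json` that is
byte-identical across runs with one seed (the run log, not the summary,
carries timestamps and the resolved-config MD5).

### Problem sizes used in validation

The test suite and acceptance script validate at sizes chosen to make the
statistics crisp on a single workstation: ten 512×512 scenes of 25
plaques for segmentation recovery; 200 random mask pairs (≤64×64) against
the brute-force distance oracle; 1000 random stain triplets for the
unmixing roundtrip; n = 2000 pooled records for correlation recovery; and
200 cohort replicates of 3 × 15 virtual animals on reduced 144×144 px
fields with Poisson(10) plaques for planted-contrast detection. That last
design was sized by a power calculation: at ~10 plaques per animal the
burden CV is ≈0.45, putting the 0.4:1 facilitator contrast at an effect
size of d ≈ 1.4 and the detection power well above the 0.8 the recovery
check demands; fields small enough to drop counts to ~5 would leave
Poisson noise alone consuming the effect.

## Numerical choices and edge cases

* Optical densities use $-\log_{10}(\max(I, 0.5)/W)$; the clamp only
  guards $I = 0$ and leaves the render–unmix roundtrip exact.
* 8-connectivity for components; diagonal-touching deposits are one ROI.
* Closing radius 1 px by default; radius 0 disables merging.
* Contact threshold is $\sqrt 2$ px with a $10^{-9}$ tolerance so exact
  diagonal adjacency is contact on every platform.
* Degenerate inputs take defined paths: empty masks raise errors for
  per-ROI measures, empty vessel masks yield an `NA` sentinel with a
  warning and downstream exclusion, an all-identical ANOVA input returns
  F = 0 with p = 1, LSD refuses a zero pooled MSE, Fisher Z refuses
  |r| = 1, and a zero-plaque cohort flows through the pipeline with
  zeroed burden metrics and clean degenerate statistics.
* All randomness is seeded; scenes, renders and whole pipeline runs are
  bit-reproducible given the spec/config seed.

## Limitations

Plaque subtype *classification* (diffuse vs dense vs dense-core) is
intentionally absent — there is no published quantitative rule, so the
generator knows its archetypes but the measurement chain never guesses
them. FD magnitudes are implementation-specific across packages. The
colocalization thresholds, not the coefficient, dominate its behaviour on
noisy data. The synthetic vasculature is geometric, so vessel-distance
distributions on real tissue will differ in shape even when the contact
logic is identical.
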