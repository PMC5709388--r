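---
title: "Per-organoid live/dead image analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-organoid live/dead image analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrganoidScreen)
```

## The problem

Heterotypic 3D tumor cultures — tumor cells grown with stromal fibroblasts —
form a heterogeneous mix of lobed, non-spheroidal organoids. Volumetric
treatment-response readouts that assume spherical geometry are inaccurate for
such cultures, and single-metric colorimetric assays collapse mechanistically
distinct treatment effects into one number. This package implements an
image-based alternative: every organoid in a well is segmented from the
brightfield image, indexed, and characterized by several readouts at once
(total area, an intensity-ratio viability, and thresholded live/dead areas),
with the index preserved so the readouts can be correlated per organoid.

The experimental substrate is a standard in-situ live/dead stain: calcein AM
marks live cells (esterase cleavage retains fluorescent calcein in the
cytoplasm), propidium iodide (PI) marks necrotic cells (it cannot cross
intact membranes). Each well contributes a registered triplet of single-plane
grayscale rasters: brightfield, live channel, dead channel. Every experiment
must include a no-treatment control group and a total-killing control group
(fixed and permeabilized wells); these anchor the dynamic range of both the
acquisition and the analysis.

## The workflow

`run_analyze()` executes the stages in a fixed order:

1. **Brightfield masking.** Organoids appear as dark silhouettes on a bright,
   non-uniformly illuminated background, so a global threshold fails. The
   image is min-max rescaled, complemented (dark-object polarity), and each
   pixel is compared with `2 * sensitivity` times the mean intensity of its
   `neighborhood_size` square window (defaults 0.55 and 65 px). At
   sensitivity 0.5 this is plain local-mean thresholding; 0.55 demands a 10%
   deviation above the local mean.
2. **Size filter.** Connected components (8-connectivity by default, so
   touching lobes count as one nodule) smaller than `min_object_area`
   (default 1950 µm², about five 400 µm² cells) are discarded as debris or
   single migrating cells. Retention is inclusive at exactly the threshold.
3. **Out-of-focus filter.** The live and dead channels are summed, rescaled
   to [0, 1], and binarized with Otsu's method over all pixels. Because live
   and dead fluorescence are complementary over viable-to-dead tissue, any
   in-focus organoid is bright in the sum regardless of its health, while
   out-of-focus organoids (visible in brightfield, dim in fluorescence) fall
   with the background. The brightfield mask is intersected with this
   binarization, the size filter re-applied, and survivors re-indexed; this
   label map is definitive for all downstream readouts.
4. **Background estimation and subtraction.** On no-treatment images only,
   the final mask is dilated by a 2 px discrete disk and inverted; per image
   and channel the median intensity of the inverse mask is taken, and the
   medians are averaged across control images. The median is essential:
   bright loci from detached cells and debris litter the inter-organoid
   space and bias a mean upward. The estimate is subtracted from every image
   of the experiment, clipping at zero.
5. **Per-object quantification.** For each indexed organoid: pixel count and
   physical area (`area_px * pixel_area`); mean background-corrected live
   and dead intensities; `viability = live / (live + dead)` (1 fully live, 0
   fully dead, `NA` flagged when both are zero); and thresholded live area —
   the count of object pixels strictly exceeding a fixed experiment-wide
   threshold, converted to µm², plus its fraction of total area. The live
   threshold is Otsu's method over the pooled within-mask live pixels of the
   no-treatment group times a factor (default 0.4) that widens the dynamic
   range so untreated organoids approach fractional live area 1 and
   total-killing organoids reach 0. The dead-area threshold is calibrated
   symmetrically on total-killing controls.
6. **Analytics.** Group summaries report the mean (with SD and SEM) of the
   per-image medians, so crowded images do not dominate. Dose series are fit
   by least squares with an exponential decay
   `R(d) = plateau + (R0 - plateau) exp(-k d)` (all parameters
   non-negative), pairwise per-organoid relationships by ordinary least
   squares, and each well can be rendered as a viability heatmap and a
   binary live-area map.

### Ordering subtlety

The background estimate needs control masks, but the definitive mask's focus
filter should see background-corrected fluorescence. The pipeline therefore
segments the no-treatment controls once on raw fluorescence solely to
estimate the background, then re-segments every image after subtraction. The
focus filter's Otsu cut is driven by the contrast between fluorescent
objects and empty background, which a constant offset barely moves, so the
first-pass masks are reliable for background sampling.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `sensitivity` | 0.55 | — | deviation above local mean demanded for foreground |
| `neighborhood_size` | 65 | px | local-mean window; should exceed typical organoid diameter |
| `min_object_area` | 1950 | µm² | debris/single-cell rejection |
| `connectivity` | 8 | — | touching lobes merge into one nodule |
| `background_radius` | 2 | px | mask dilation before inversion |
| `live_threshold_factor` | 0.4 | — | multiplier on the raw Otsu live threshold |
| `pixel_area` | (required) | µm²/px | physical scale; deliberately no default |

`pixel_area` has no default because published descriptions of this assay are
internally inconsistent about scale (a 50 px ≈ 1931 µm² equivalence implies
≈38.6 µm²/px, while four 512×512 px tiles covering ≈6.4 mm² imply
≈6.1 µm²/px); the manifest must state the true calibration of the
acquisition. A second printed size threshold (1931 µm²) circulates alongside
1950 µm²; the package defaults to 1950 and exposes the value. The 0.4
threshold factor is likewise exposed, as it may need retuning per imaging
configuration.

## The synthetic-scene generator

No public image set exists for this assay, so the package ships a generator
(`generate_scene()`, `render_scene()`, `simulate_plate()`) that emulates the
features the pipeline must survive, with per-pixel ground truth:

- **Geometry.** Organoid areas are log-normal (default median 20 000 µm²,
  `sdlog` 0.45); shapes are unions of 1–3 overlapping rotated ellipses,
  mimicking the lobed phenotype of heterotypic cocultures. Masks are
  pairwise disjoint with a 2 px guard gap.
- **Viability.** Per-pixel viability is
  `base * (1 - depth * d)` where `d` is the distance from the organoid
  boundary normalized to [0, 1]. The minimum is at the **center**, emulating
  hypoxic-core formation in untreated cultures; the default depth 0.2 is a
  mild rim-to-core drop giving untreated organoids a mean viability near
  0.92, the healthy-control regime this assay is calibrated on.
- **Optics.** Brightfield is a bright background under a multiplicative
  linear illumination gradient (default ×0.7–×1.3) with organoids darkened
  by a silhouette factor; live fluorescence is `background + gain * v`, dead
  is its complement over the mask; noise is Gaussian with SD
  `noise_sd + coef * signal`; channels are quantized to 16-bit integers.
- **Confounders.** Dark debris specks below half the size threshold (faintly
  fluorescent), detached bright single cells in inter-organoid space, and a
  fraction of organoids rendered out-of-focus: fluorescence attenuated 15×
  and Gaussian-blurred, brightfield silhouette unchanged — exactly the
  failure mode the focus filter targets.
- **Treatments.** `uniform_kill` scales all viability fields by
  `exp(-alpha * dose)`; `size_dependent_kill` by
  `exp(-alpha * dose * (a_ref/area)^gamma)`, hitting small organoids harder.
  The two models reproduce the opposing viability-vs-size regression slopes
  that distinguish homogeneously acting drugs from therapies that spare
  large organoids.

Fluorescence is rendered proportional to viability occupancy rather than
through a point-spread-function model: the pipeline under test is
intensity-ratio based, so optical realism beyond gradients, noise and
attenuation would add complexity without test power. Consequences: the
generator does not emulate chromatic cross-talk, detector saturation,
z-dependent partial volumes, or spatially varying background, so passing
tests certify the algorithmic chain, not robustness to every real-world
artifact.

Two named presets pin the regimes used by the validation suite:
`"segmentation_snr"` (strong gradient, debris, 15% out-of-focus; seed 101)
and `"quantification_snr"` (milder optics, per-organoid baseline viability
drawn from [0.15, 1] to create rank structure; seed 202). The test suite
runs single 512×512 wells and small plates at 256×256 or 1024×1024; those
sizes are ample for 50+ organoids per field at the default scale.

## Numerical choices

- **Otsu implementation.** Equal-width histogram over the sample range
  (default 256 bins); the returned threshold is the interior bin edge
  maximizing between-class variance computed from bin midpoints, ties broken
  toward the lowest edge. The suite verifies exact agreement with an
  exhaustive within-class-variance minimizer.
- **Local mean borders** use replicate padding; zero padding would darken
  borders of the complemented image and create spurious edge foreground.
- **Degenerate inputs.** A constant brightfield image yields an empty mask
  with a warning (min-max rescale undefined); a constant summed-fluorescence
  image removes all objects with a warning; a constant Otsu sample is an
  error. 0/0 viability is a flagged `NA`, never an exception, so area
  statistics stay complete.
- **Exponential-decay fitting** exploits the model's conditional linearity:
  for fixed rate `k` the remaining two parameters are a linear least-squares
  solve, so the fitter scans a fixed logarithmic grid of rates, polishes the
  best bracket by golden-section search, and projects onto the non-negative
  constraint boundary when needed. Deterministic by construction; RSS ties
  resolve to the smallest rate.
- **Determinism.** Labeling order is raster-scan; all generator randomness
  derives from one seed through a string-hash that keeps derived seeds in
  32-bit range; re-running any analysis on identical inputs reproduces
  identical CSV bytes.

## Design choices where the procedure was open

- **Adaptive-threshold semantics.** Reference descriptions give a
  "sensitivity" without defining its scale. Here foreground requires the
  working pixel to exceed `2 * sensitivity * local_mean`, chosen so 0.5
  degenerates to plain local-mean thresholding; the parameter is exposed and
  the synthetic suite is the calibration surface.
- **Pixelwise vs whole-object focus filtering.** Multiplying masks suggests
  pixelwise; "excluding organoids" suggests whole-object. Default is
  pixelwise followed by a size re-filter (the intersection can shrink
  objects below threshold — re-applying keeps the size invariant honest);
  `focus_mode = "whole_object"` drops objects with under half their pixels
  fluorescence-positive, keeping survivors intact.
- **Size filter applied twice** (before and after the fluorescence
  intersection) — a deliberate strengthening so every reported object
  honors the area floor.
- **Otsu sample for the focus filter** is all pixels of the summed image,
  not object-restricted pixels, matching binarization "of the image".
- **Live-threshold Otsu sample** is the pooled within-mask live pixels of
  no-treatment images; pooling the whole frame would let empty background
  dominate the histogram.
- **Clipping at zero after background subtraction**: negative intensities
  are non-physical and would corrupt the viability ratio's [0, 1] range.
- **No hole filling** by default; interior brightfield holes are resolved by
  the fluorescence intersection. A `fill_holes` flag exists for unusual
  optics.

## Limitations

Single-plane analysis has no axial resolution: organoid overlap in z is
invisible, and the out-of-focus filter discards (rather than recovers)
organoids outside the focal plane. Merged organoids touching in-plane are
counted as one nodule by design (no watershed splitting). The viability
ratio is an intensity ratio: it is robust to global gain but not to
channel-specific nonlinearities, and it disregards which cell types within a
heterotypic organoid live or die. Statistical hypothesis testing across
groups is intentionally out of scope; the per-object CSV is the hand-off
surface for external statistics tools.
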