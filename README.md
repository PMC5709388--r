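# OrganoidScreen

Per-organoid live/dead image analysis for architecturally complex 3D tumor
cultures.

## The problem

Heterotypic organoid cultures (tumor cells grown with stromal fibroblasts)
form lobed, non-spheroidal nodules of wildly heterogeneous size. Volumetric
viability assays that assume spherical geometry, and single-number
colorimetric assays, both misreport treatment response for such cultures.
OrganoidScreen instead quantifies response **nodule by nodule** from
standard confocal image triplets — brightfield, calcein-AM (live) and
propidium-iodide (dead) fluorescence — for anyone running treatment
screens on 3D cultures: drug developers, radiobiology and photomedicine
labs, and groups building patient-derived culture platforms.

## The method

Each well's brightfield image is binarized with an **adaptive local-mean
threshold** (foreground where the complemented, rescaled image exceeds
2·*s* times its 65×65 px local mean, *s* = 0.55), which survives the
non-uniform illumination that defeats global thresholds. Components below
1950 µm² are discarded as debris; an **out-of-focus filter** binarizes the
summed fluorescence by Otsu's method and intersects it with the mask. Each
surviving organoid gets a persistent index *i* and:

- total area `A_i = (pixel count) × (µm²/px)`,
- viability (intensity ratio, background-corrected means over the object)

  `V_i = I_calcein / (I_calcein + I_PI)  ∈ [0, 1]`,

- live area: pixels with calcein intensity above a fixed threshold
  (Otsu over the pooled within-mask live pixels of the no-treatment
  group × 0.4), in µm², and the fractional live area

  `frac live area_i = (live area)_i / A_i`,

  with the dead-area analog calibrated on total-killing controls.

Fluorescence background is the **mean across no-treatment images of the
per-image median** intensity outside the 2 px-dilated object mask — the
median resists the bright detached-cell loci that bias a mean. Group
summaries report the mean of per-image medians (±SD/SEM); dose series are
fit by least squares with `R(d) = plateau + (R0 − plateau)·e^(−kd)`;
per-organoid regressions (e.g. viability vs. area) separate size-dependent
therapies from homogeneously acting drugs.

A seeded **synthetic-scene generator** renders ground-truthed plates
(lobed organoids, hypoxic-core viability gradients, illumination gradients,
debris, detached cells, out-of-focus organoids) so every stage is testable
without microscope data.

## Worked example

Simulate a small plate (two control wells per group plus a four-dose
series of a size-dependent treatment) and analyze it:

```r
library(OrganoidScreen)
cfg <- scene_config(image_shape = c(256L, 256L), n_organoids = 12L, seed = 7L)
sim <- simulate_plate(cfg, "plate", doses = c(5, 10, 25, 50),
                      n_control_wells = 2L, n_wells_per_dose = 1L)
res <- run_analyze(read_manifest(sim$manifest), run_config(), out_dir = "out")
res$background
#> <background_estimate> live=1503.500 dead=1201.500 (n=2 images)
res$live_threshold
#> <area_threshold> live: 7281.8844 (raw Otsu 18204.7109 x factor 0.40)
res$summaries[["no_treatment"]]
#> <group_summary> no_treatment: 2 image(s)
#>   total_area       mean of medians 2.122e+04 (sd 4.72e+03, sem 3.34e+03)
#>   frac_live_area   mean of medians 1 (sd 0, sem 0)
#>   viability        mean of medians 0.9168 (sd 0.00248, sem 0.00175)
res$summaries[["treatment@25"]]
#> <group_summary> treatment dose=25: 1 image(s)
#>   total_area       mean of medians 2.599e+04 (sd 0, sem 0)
#>   frac_live_area   mean of medians 0 (sd 0, sem 0)
#>   viability        mean of medians 0.2928 (sd 0, sem 0)
res$dose_response
#> <dose_response_fit> R(d) = 0 + (0.9207 - 0) exp(-0.04704 d), rss=0.0002238
```

The estimated background (true values 1500/1200 a.u.) and the untreated
median viability ≈0.92 (healthy organoids with a mild hypoxic core) anchor
the dynamic range; at dose 25 the median viability drops to 0.29 and the
fractional live area to 0, and the fitted decay rate 0.047 per dose unit
recovers the generating kill rate (0.05). Per-object records:

```r
head(res$records[, c("well_id","group","object_id","total_area","viability","frac_live_area")])
#>   well_id        group object_id total_area viability frac_live_area
#> 1    NT01 no_treatment         1   47155.02 0.9186002              1
#> 2    NT01 no_treatment         2   34178.70 0.9184928              1
#> 3    NT01 no_treatment         3   24562.32 0.9212150              1
#> ...
```

`out/` receives `per_object.csv`, `group_summary.csv`, `run_report.json`
(all parameters, background, thresholds — every run is reconstructible),
`dose_response.json`, and per-well viability-heatmap / live-area PNGs.

A command-line wrapper is included:

```sh
Rscript inst/cli/organoidscreen.R simulate --config reference_plate --out plate
Rscript inst/cli/organoidscreen.R analyze --manifest plate/manifest.csv --out results_dir
```

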