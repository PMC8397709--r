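# isletwave

Classification and connectivity analysis of intravital islet Ca²⁺
recordings, for labs imaging pancreatic islets (e.g. engrafted in the
anterior chamber of the eye) with genetically encoded indicators such as
GCaMP6f and asking how coordinated beta-cell activity changes over weeks —
after bariatric surgery, drug treatment, or disease progression.

## What it computes

Given per-cell fluorescence traces (extracted from a TIFF stack or
supplied as CSV), the package:

* **classifies each recording** on the five-level activity scale used for
  islet Ca²⁺ dynamics — 0 no activity, 1 oscillations, 2 partial wave,
  3 full wave, 4 superwave (recurrent full wave) — by detecting per-cell
  onsets (half-maximum crossings above a robust noise threshold),
  partitioning the islet into three ordered regions, and testing each
  event for the hallmarks of a propagating front (recruitment, temporal
  compactness, spatially ordered onsets);
* **estimates wavefront velocity** as v = d/Δt in µm/s, the distance
  between first- and last-recruited reference points divided by their
  onset lag;
* **quantifies functional connectivity** from pairwise Pearson
  correlations of the smoothed traces over a 100-frame (~30 s) window:
  R excluding the autocorrelation, significance by a circular-shift
  permutation test (or a fixed R threshold), the percentage of
  significantly connected cell pairs, the mean positive R, colour-binned
  Cartesian connectivity maps (blue 0.1–0.25 → red 0.76–1.0, hub cells as
  red dots) and heatmaps;
* **aggregates cohorts** (e.g. sham vs. VSG over weeks 0–10) with week-0
  baseline correction and two-sided unpaired Student's t-tests, writing
  time-course tables and a machine-readable report.

A ground-truthed synthetic generator (islet geometries, per-level
recordings, rendered image stacks, whole longitudinal cohorts) emulates
the study conditions — 18–40 cell-scale ROIs, 400 frames at 3 frames/s —
so the whole pipeline is testable without animal data.

## Worked example

```r
library(isletwave)

# one synthetic islet: 24 cells, full wave at 45 um/s
geom <- make_islet_geometry(24, islet_radius = 60, min_spacing = 12, seed = 11)
sim  <- simulate_recording(geom, sim_params(level = 3, wave_velocity = 45, seed = 11))
fit  <- analyze_islet(sim$recording, seed = 11)
fit
#> <islet_analysis> 24 cells x 400 frames @ 3 fps
#>   activity: level 3 (wave)
#>   wavefront velocity: 46.8 um/s (median of 1 event(s))
#>   connectivity (permutation): 100.0% pairs connected, mean positive R = 0.971
```

The classifier recovered the simulated level (3, a single full wave); the
d/Δt estimate (46.8 µm/s) sits within 4% of the generator's 45 µm/s; and,
because every cell rides the same wave, all pairs are significantly
connected with a mean positive R near 1. `plot(fit, "traces")`,
`plot(fit, "map")` and `plot(fit, "heatmap")` draw the region-coloured
traces, the Cartesian connectivity map and the pairwise-R heatmap;
`summary(fit)` returns the per-islet metrics row used by
`analyze_cohort()` / `summarize_levels()` / `report()`.

For real data, the same pipeline starts from files:

```r
stack <- read_stack("islet.tif")
rois  <- read_rois("rois.csv")            # id, x_um, y_um, diameter_um
rec   <- extract_roi_traces(stack, rois, fps = 3, pixel_size = 2)
fit   <- analyze_islet(rec, geometry = read_geometry_json("geometry.json"))
```

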