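Package: isletwave
Title: Classification and Connectivity Analysis of Intravital Islet Calcium Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vivo calcium imaging of pancreatic
    islets engrafted in the anterior eye chamber. Classifies each GCaMP6f
    recording into a five-level activity scale (inactive, oscillations,
    partial wave, full wave, recurrent superwave), estimates wavefront
    velocity as distance over onset lag, and quantifies beta-cell
    functional connectivity from pairwise Pearson correlations with
    circular-shift permutation significance. Includes a ground-truthed
    synthetic recording and cohort generator emulating longitudinal
    sham-versus-surgery imaging studies, TIFF stack and ROI trace I/O,
    rolling-average smoothing, connectivity maps and heatmaps, and
    cohort-level summary reports with week-0 baseline correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
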