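Package: wavegraft
Title: Calcium-Wave Optical Mapping of Graft-Host Electrophysiological Integration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for calcium-imaging movies of cardiomyocyte
    monolayers with grafted single cells: TIFF stack input/output with
    acquisition metadata, background subtraction to dF/F0, Kalman stack
    filtering, Gaussian blurring and histogram-band signal-to-noise
    quantification, adaptive per-pixel-threshold activation maps, kymograph
    (reslice) construction with wavefront-slope conduction-velocity fits,
    stimulus-locked synchronization statistics with an exact-binomial and
    Monte-Carlo coincidence null, a cell-chain model of per-contact
    transmission time yielding the graft/monolayer contact-efficiency ratio,
    and temporal decoding of confocal raster-scan frames (firing period and
    calcium-transient duration from band geometry). Includes a seeded
    synthetic calcium-wave movie and raster-frame generator with ground-truth
    manifests for validation.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
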