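Package: oximap
Title: Tissue Oxygenation and Perfusion Mapping from Snapshot Mosaic
    Multispectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing pipeline for intraoperative snapshot-mosaic
    multispectral imaging of the exposed heart. Converts raw mosaic sensor
    frames into calibrated, L1-normalized reflectance cubes (dark
    subtraction, Lanczos demosaicing, bilateral denoising, spectral
    correction, white-reference balancing), derives per-pixel tissue
    oxygenation, relative hemoglobin content and superficial/deep
    perfusion indices by Beer-Lambert linear spectral unmixing, and
    compares pre- versus post-bypass regions of interest with
    random-intercept linear mixed models. Includes a phantom simulator
    that renders ground-truth scenes into raw sensor frames so the whole
    chain is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
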