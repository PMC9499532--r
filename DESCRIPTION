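Package: rhizotrack
Title: Time-Lapse Luminescence Root Phenotyping in Rhizotrons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-lapse luminescence imaging of plant
    root systems grown in soil-filled rhizotrons. Turns day-by-day grayscale
    images into registered, denoised, cumulative binary root images;
    decomposes them into oriented root segments; rebuilds the root system in
    silico as directed vectors; removes non-root particles by iterative
    single-linkage distance clustering; computes nine dynamic root system
    architecture traits (width, depth, center of mass, convex hull area,
    depth-to-width ratio, total length, average angle, plus per-day new
    growth length and angle); and summarizes replicated trait time courses
    with a random-intercept random-slope mixed model, broad-sense
    heritability, and trajectory clustering. A synthetic rhizotron simulator
    provides ground-truth root systems and rendered image series so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    lme4,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
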