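Package: canopylight
Title: Illumination Compensation for Canopy Images in Tall-Short Strip
    Intercropping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects the systematic left-to-right brightness gradient that a
    tall crop strip (e.g. maize) casts onto an adjacent short crop strip (e.g.
    soybean) in nadir canopy images. Fits a quadratic regression of canopy
    light intensity on crop height difference, solar elevation angle and
    position within the shaded strip; applies a column-wise clamped-ratio
    brightness compensation ("ICNet") driven by that model; provides
    histogram-equalization, multi-scale Retinex and gamma-correction baseline
    enhancers; and evaluates enhancement with MSE/PSNR, RGB and HLS centerline
    profiles and trimmed per-channel standard deviations. Ships a seeded
    synthetic canopy-scene generator with model-driven shading and uniformly
    lit ground truth for end-to-end scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
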