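Package: sarcnet
Title: Quantifying Sarcomere Network Maturation in Contractile Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Standardised, image-based quantification of sarcomere network
    maturation in striated cells (iPSC-derived and primary cardiomyocytes,
    skeletal muscle cells) from super-resolution images of the alpha-actinin
    channel. Implements Steger-style curvilinear ridge detection of z-discs
    with sub-pixel centerlines, local tangents and widths; structure-tensor
    orientation analysis relative to the cell's long axis with axial circular
    statistics (Watson-Williams test); per-cell sarcomere density, sarcomere
    length from intensity-peak spacing, z-disc thickness, and cell shape
    descriptors; calcium transient kinetics (CD50, T50on, T50off, tau); and a
    fully seeded synthetic striated-cell generator with recorded ground truth
    for estimator validation. Tidy interfaces: tibbles in and out, ggplot2
    autoplot methods, broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    tiff,
    png,
    withr,
    generics,
    EBImage,
    minpack.lm,
    multcomp,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
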