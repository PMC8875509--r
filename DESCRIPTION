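Package: nanocoloc
Title: Nanoscale Colocalization Analysis for Single-Molecule Localization
    Microscopy by Image Cross-Correlation Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify dual-color colocalization at the nanoscale
    from single-molecule localization microscopy (SMLM/dSTORM) data.
    Localization tables are rendered as superpositions of Gaussian point
    spread functions, stage drift is estimated and corrected from
    persistent fiducial markers (e.g. fluorescent nanodiamonds), and
    colocalization is quantified by image cross-correlation spectroscopy
    (ICCS): the colocalized fraction f_ICCS from the amplitudes of the
    spatial auto- and cross-correlation functions, and the correlation
    distance d from the broadening of the cross-correlation. Includes
    local (sliding-window) colocalization maps, landmark-based
    registration of confocal images for mask-restricted analysis, and a
    fully seeded dual-color simulator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
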