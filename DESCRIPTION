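Package: rfscreen
Title: Reproductive-Fitness Scoring and Hit Selection for Worm RNAi Modifier Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for genome-scale RNAi modifier screens in
    Caenorhabditis elegans run in 96-well liquid format with GFP-marked
    pharynxes. Provides semi-automated counting of parent and progeny worms in
    well fluorescence images (object detection by area/mass/perimeter rules and
    size-based adult/larva classification), reproductive-fitness statistics
    (progeny per parent, replicate averaging with an OUT sentinel,
    mutant-over-control RF ratios), control-calibrated hit thresholds
    (mean + 2 SD of positive-control ratios), lethality exclusion, two-stage
    enhancer selection and suppressor flagging, plate-level quality control
    (replicate correlation, control separation), readers and writers for the
    screen-record CSV schema, and a synthetic-data generator that produces
    images and full two-strain screens with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    igraph,
    tiff,
    yaml,
    withr,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
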