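Package: myoquant
Title: Quantification of HRas Localization, FRET Activity, and Myoblast
    Differentiation from Fluorescence Micrographs and Bench Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for senescence and myoblast-differentiation
    studies: marker-guided quantification of the Golgi-to-plasma-membrane
    distribution of HRas (the R_mean statistic), sensitized-emission FRET
    with single-label bleed-through calibration and acceptor normalization,
    myotube fusion index and nuclear-area readouts from DAPI/MHC channels,
    and bench-side quantifications (delta-delta-Ct relative expression,
    growth-curve doubling time, MRM standard-curve lipid quantitation with
    per-cell normalization, MTT viability, Student and Dunnett tests).
    Includes seeded synthetic-data generators with ground-truth sidecars
    for every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
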