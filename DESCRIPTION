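Package: picls
Title: Propidium-Iodide Chronological Lifespan Quantification for Plate Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies yeast chronological lifespan (CLS) from 96-well
    plate-reader data using propidium iodide (PI) fluorescence normalized by
    OD600. Provides readers for grid and long-table plate exports,
    fluorescence-OD calibration with linear-range detection, the PI survival
    statistic and its outgrowth comparator, Z-factor assay quality control,
    dose-response screening with bootstrap hit calling, and a synthetic
    plate-screen generator with Weibull mortality kinetics and a saturating
    optical measurement model, so every analysis stage is testable without
    wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
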