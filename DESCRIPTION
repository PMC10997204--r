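Package: seasprayr
Title: Enrichment and Global Flux of Perfluoroalkyl Acids on Sea Spray Aerosol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates enrichment factors (EFs) of perfluoroalkyl acids
    (PFAAs) in nascent sea spray aerosol (SSA) from chamber-experiment data,
    with left-censoring substitution, a detection-frequency gate, and a
    through-origin total least squares regression. Projects size-fraction EFs
    onto a three-mode log-normal SSA source function and scales gridded
    sea-salt emission and deposition fields by province-level seawater
    concentrations to estimate global secondary PFAA emission and deposition
    under mean, low and high scenarios. Includes a synthetic-data generator
    that emulates the chamber experiments and a toy gridded ocean world so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    nortest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
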