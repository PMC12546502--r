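Package: dpnpv
Title: Net Present Value Modelling of Digital Pathology Adoption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seven-year discounted cash-flow model for the business case of
    adopting digital pathology in a hospital pathology department. Builds
    per-year investment schedules (scanners with capacity-threshold fleet
    sizing, workstations, software, IT and storage, scanning personnel) and
    benefit schedules (productivity-captured exam volumes, secondary
    consultations, workforce efficiency, microscope equipment savings),
    discounts them, and reports net present value, break-even and payback
    years, and per-case economics. Includes deterministic anchor-based
    calibration of under-specified parameters against published table totals,
    base/best/worst scenario runs, one-way (tornado) sensitivity analysis,
    Monte Carlo probabilistic sensitivity analysis, and a synthetic
    multi-laboratory parameter panel generator.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
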