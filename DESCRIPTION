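Package: bpprisk
Title: Probabilistic Dietary Risk Assessment for Benzophenone-Type
    Photoinitiators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cumulative dietary risk assessment of benzophenone-type
    photoinitiators (BP, 2-OHBP, 4-OHBP, 4-MBP, M2BB, PBZ) that migrate
    from ultraviolet-cured printing inks on food packaging into food.
    Implements probabilistic average-daily-dose estimation by Monte Carlo
    simulation from occurrence and consumption data, lower-bound/upper-bound
    substitution for left-censored concentrations, margin-of-exposure (MOE)
    and cumulative MOE_T risk characterization, threshold-of-toxicological-
    concern (TTC) screening by Cramer class, RISK21-style exposure/toxicity
    classification, and contribution-to-variance sensitivity analysis.
    Ships a synthetic market-survey generator so the full pipeline is
    testable without access to the underlying survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fitdistrplus,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
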