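Package: latereturn
Title: Weekly Return Hazards and a Clinical-Management Loss-to-Follow-Up
    Cut-Off for ART Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a clinical-management lost-to-follow-up (LTFU) cut-off
    from visit-level antiretroviral therapy (ART) program data. Computes
    per-visit lateness from the dispensed drug supply, applies cohort
    inclusion filters, estimates the discrete weekly hazard of return among
    late patients together with the cumulative distribution function of
    return and Greenwood-variance confidence intervals, and formalizes the
    selection of the weeks-late cut-off at which patient tracing should
    begin. Includes a synthetic cohort generator emulating refill-cycle
    visit schedules so the full analysis runs end to end with no external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
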