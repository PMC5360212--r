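Package: fsmplan
Title: Costing and Willingness-to-Pay Analysis for Rural Fecal Sludge
    Management Services
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for planning subdistrict-scale fecal sludge emptying and
    transport services for single-pit latrines. Converts latrine-stock
    parameters into annual emptying demand, sizes emptying and transport
    fleets for direct-haul and transfer-station options, aggregates
    annualised capital, labour and per-kilometre operating costs into
    per-event and per-household tariffs, and estimates household
    willingness to pay from double-bounded dichotomous-choice contingent
    valuation surveys by interval-censored normal maximum likelihood, with
    single-bound probit checks, bootstrap confidence intervals, design-based
    sample-size calculations, and a seeded synthetic survey generator. A
    financing-gap report joins the cost and willingness-to-pay results.
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
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
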