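Package: txcost
Title: First-Year Treatment Cost and Budget-Impact Modelling for Renal
    Transplantation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic cost engine, Monte Carlo cohort simulator and
    hemodialysis comparator for estimating first-year treatment costs of
    renal transplantation therapy from a health-insurance (payer)
    perspective.  Costs are built from a global hospitalization tariff,
    maintenance immunosuppressive regimen lines, probability-weighted
    adverse-event treatment bundles and miscellaneous medication lines,
    all computed in exact whole-Rial arithmetic with a documented rounding
    policy and converted to US dollars at a configurable exchange rate.
    Includes a synthetic strategy generator for property-based testing,
    YAML/JSON configuration input and output, table rendering, and a
    bundled input set describing the 2011-2012 Iranian transplant cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
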