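Package: pencost
Title: Ingredient-Based Incremental Costing for Primary-Care NCD Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bottom-up, ingredient-based incremental costing pipeline for
    primary-care non-communicable-disease (NCD) prevention programs of the
    WHO-PEN family, modelled on Iran's IraPEN pilot. Reads item-level cost
    ledgers, direct-observation task-time logs, staffing rosters, and
    population denominators; annualizes capital expenditure by the capital
    recovery factor; allocates fixed/variable and specific/non-specific costs
    across service protocols; and reports annual and per-capita incremental
    costs per protocol. Includes a two-stage stratified cluster-sampling
    survey simulator with a design-based coverage estimator, and a synthetic
    scenario generator with closed-form ground truth for end-to-end
    verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
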