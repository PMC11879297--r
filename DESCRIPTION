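Package: vwcost
Title: Cost-Comparison Modelling for Virtual Ward (Hospital at Home) Services
Version: 1.0.0
Authors@R:
    person("VW Costing", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A configurable health-economic cost-comparison pipeline for
    virtual ward (hospital at home) services. Costs a virtual-ward cohort and
    a propensity-matched standard-care counterfactual from patient-level
    resource use, decomposes costs into set-up, fixed and variable as well as
    direct and indirect components, reports incremental results, and provides
    deterministic one-way sensitivity (tornado) and break-even threshold
    analyses. Includes staff microcosting from annual employment cost and
    working hours, 1:1 propensity-score matching, and a calibrated synthetic
    cohort generator so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
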