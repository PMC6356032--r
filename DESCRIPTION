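Package: owbscreen
Title: Screening-Level Operator, Worker and Bystander Exposure Model for
    Co-Formulants in Plant Protection Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tier-1 (screening level) dermal and inhalation exposure
    predictions for co-formulants used in plant protection products,
    following the operator-worker-bystander (OWB) approach: BBA unit-exposure
    algebra for mixing/loading and spray application, a constant-rate-release
    indoor air model for greenhouse vapour, dislodgeable-foliar-residue
    re-entry and spray-drift bystander models, PHED surrogate values for
    granule and treated-seed handling, and consumer adaptations. Computes
    risk characterization ratios (RCR) against DNELs, combines correlated
    tasks, and solves for the maximum substance application rate meeting a
    target RCR.
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
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
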