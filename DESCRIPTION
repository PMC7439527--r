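Package: ohdsurv
Title: Ontology-Based Dental EHR Representation and Restoration Longevity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing dental electronic health record (EHR) data as
    an OWL instance graph over a miniature Oral Health and Disease (OHD)
    ontology, and for analysing the longevity of dental restorations from such
    graphs. Includes a statistically controlled synthetic dental-practice
    generator with known Weibull proportional-hazards ground truth, a
    relational-row to RDF instance translator with deterministic IRI minting,
    an in-memory semantic store with the entailments clinical queries need
    (subclass-closure typing, transitive parthood, per-patient encounter
    chaining), cohort extraction under shared-surface restoration-failure
    rules with right censoring, and a survival stage producing Kaplan-Meier
    curves, Cox proportional-hazards effect estimates rendered as percent
    hazard change, and kernel-smoothed hazard-rate curves.
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
    readr,
    rlang,
    stats,
    stringr,
    survival,
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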