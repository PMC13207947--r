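Package: dictox
Title: Target-Engagement Screening for Drug-Induced Cardiotoxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A translational framework for early cardiac-safety assessment of
    drug candidates. Reads DICTrank-style concern-labelled drug tables and
    per-drug pharmacology annotations, consolidates trade-name and salt-form
    duplicates to unique generic drugs, harmonizes affinity and exposure
    units to nanomolar, computes fractional target engagement under an Emax
    concentration-response model at the unbound maximum plasma concentration,
    assigns drugs to cardiovascular risk-target panels (with a-priori
    hERG/QT prioritisation), produces tiered concern-versus-risk-target
    contingency summaries with a fraction-unbound imputation sensitivity
    analysis, benchmarks new candidates against reference drugs sharing a
    target class, and generates synthetic labelled datasets with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    yaml
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
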