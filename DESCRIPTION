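Package: psychaudit
Title: Prescribing-Quality Audit of Psychotropics in Nursing-Home Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes prescribing-quality indicators for psychotropic
    medication in older nursing-home populations: psychotropic polypharmacy
    (three or more concurrent substances), potentially inappropriate
    psychotropic combinations (PICP) and substances (PIPS), and potential
    drug-drug interactions matched against an editable knowledge base with
    lexicographic first-ranked selection (recommended action > documentation
    > severity). Includes two-cohort comparison statistics (chi-square or
    Fisher's exact test, Mann-Whitney U-test, a three-step logistic
    regression procedure with multicollinearity diagnostics) and a seeded
    synthetic-cohort generator so the full audit pipeline runs without
    patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
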