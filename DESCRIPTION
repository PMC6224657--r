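Package: clonesel
Title: Clonal Selection Dynamics of Mutant Hematopoietic Clones Under
    Cytotoxic Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models and estimates the selective expansion of
    apoptosis-resistant hematopoietic clones (such as PPM1D-truncated
    clones) under repeated doses of cytotoxic chemotherapy. Provides a
    per-dose survival-ratio fitness model with naive and odds-normalized
    compounding, a stochastic two-clone competition simulator with
    binomial survival and flow-cytometry-style sampling, maximum
    likelihood fitness estimation with profile-likelihood confidence
    intervals, cohort-level contingency statistics (Woolf odds-ratio
    intervals, Fisher exact tests, Benjamini-Hochberg false discovery
    rates, pairwise co-occurrence matrices, exposure-association scans),
    variant-level clonality utilities (VAF filtering, clonal
    classification, cancer cell fraction, protein-change consequence
    parsing), and a seeded synthetic-data generator with planted ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
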