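Package: switchscreen
Title: Cross-Species Screening of Switch-Like Tissue-Specific Alternative
    Splicing from RT-PCR Percent-Spliced-In Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies percent-spliced-in (PSI) for alternative splicing
    events from RT-PCR capillary-electrophoresis peak tables (mass-to-molarity
    conversion, expected-size peak matching, a purity quality gate), detects
    switch-like brain-specific splice events from multi-tissue PSI panels,
    calls their conservation across species through an ortholog map, tests
    event-type enrichment with an exact contingency-table test, and
    characterises splicing dynamics (net shift, pivot interval, onset time)
    over differentiation and embryogenesis time courses.  Ships a seeded
    synthetic-data generator that plants ground-truth switch events, lane
    contamination and sigmoidal time courses so the whole pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    pheatmap
Config/testthat/edition: 3
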