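Package: signalkit
Title: Disproportionality Signal Detection and Network Toxicology for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of spontaneous adverse-event
    reporting data in the FAERS quarterly ASCII format: reading and writing the
    '$'-delimited DEMO/DRUG/REAC/INDI/THER/OUTC/RPSR tables, case
    deduplication, restriction to primary-suspect drugs with a chosen
    indication inside each drug's approval window, demographic and
    time-to-onset descriptive summaries, and drug-event signal detection with
    three disproportionality algorithms (reporting odds ratio, the MHRA
    proportional reporting ratio with Pearson chi-squared, and the BCPNN
    information component with its lower credibility bound). A companion
    network-toxicology stage intersects drug-target and organ-class gene sets,
    ranks protein-protein interaction hubs by degree, and performs
    hypergeometric over-representation analysis with Benjamini-Hochberg
    correction. A seeded synthetic-report generator with planted drug-event
    relative risks makes every stage testable without access to the live
    database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
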