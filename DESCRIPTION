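Package: pvscreen
Title: Disproportionality Signal Screening for Drug-Drug Modulation of
    Adverse Events
Version: 0.1.0
Authors@R:
    person("pv", "screen", email = "pvscreen@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance disproportionality analysis on
    spontaneous adverse-event report databases in the FAERS ASCII dialect:
    report ingestion and case-level deduplication, reporting odds ratio
    (ROR) signal statistics with Wald confidence intervals and Fisher exact
    p-values, sex- and age-stratified analyses, and a concomitant-drug
    screen that detects comedications modulating a base drug's adverse
    event reporting odds. Includes downstream clinical chart-review
    endpoint statistics (RECIST response rates, CTCAE hypertension event
    flagging, blood-pressure change summaries), two-group gene-expression
    comparison on pathway gene subsets, delta-delta-Cq qPCR quantification
    with Dunnett many-to-one testing, and seeded synthetic-data generators
    with planted effects for validating every stage without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
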