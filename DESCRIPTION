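Package: sendhc
Title: Historical Control Analysis for CDISC SEND Toxicology Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and maintains an SQLite database from CDISC SEND
    (Standard for Exchange of Nonclinical Data) toxicology studies stored as
    SAS XPT v5 transport files, extracts matched historical control data
    through a composable chain of study- and subject-level filters (study
    design, start date, control type, sex, species/strain, route, animal age,
    study phase), aggregates background incidence rates for microscopic
    findings and reference ranges for quantitative domains, and harmonizes
    SEND terminology via a tab-delimited controlled-terminology to JSON
    vocabulary pipeline that rewrites cleaned XPT files. Includes a
    deterministic synthetic SEND study generator with planted ground truth
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    haven,
    DBI,
    RSQLite,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
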