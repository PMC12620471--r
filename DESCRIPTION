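Package: roughdelphi
Title: Fuzzy Delphi Screening and Rough-Set Rule Mining for Configurational Satisfaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage configurational analysis of ordinal satisfaction
    surveys. Stage one screens candidate evaluation criteria with the Fuzzy
    Delphi Method: expert conservative/optimistic score intervals are
    aggregated into double triangular fuzzy numbers, convergence is tested via
    the gray zone, and criteria are retained against a consensus threshold.
    Stage two mines a Likert decision table with classical rough-set theory:
    indiscernibility partitions, lower and upper approximations, quality of
    classification, reducts and core, LEM2-style minimal-covering induction of
    certain decision rules with support and coverage statistics, coverage
    filtering, stratified cross-validation, and decision flow-graph export.
    A seeded synthetic-data module generates expert panels and survey tables
    with planted conjunction rules at designed coverages so that every
    pipeline stage is testable end to end.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
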