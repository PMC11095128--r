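Package: hpbbench
Title: Benchmarking Quality Indicators in Hepato-Pancreato-Biliary Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for auditing hospital performance in liver and pancreatic
    surgery. Computes the four standard quality indicators (postoperative
    mortality, major morbidity, failure to rescue, and the composite
    textbook/ideal outcome) from patient-level registry records, estimates
    national benchmarks, and answers the design question behind them: how
    large must a hospital's caseload be before a clinically relevant
    deviation from the benchmark becomes statistically detectable?  Sample
    sizes follow the variance-stabilised (arcsine) one-sample proportion
    test; their inversion yields the smallest detectable difference at any
    volume, minimum annual volume requirements under pooling of registry
    years, and exact-binomial funnel-plot limits with outlier
    classification.  A seeded synthetic-registry generator emulating the
    Dutch hepatobiliary and pancreatic audits makes every stage testable
    without access to confidential audit data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
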