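Package: aumimic
Title: Facial Mimicry Quantification from Action Unit Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies facial mimicry of artificial agents from facial
    Action Unit (AU) intensity time series. Detects spontaneous mimicry in
    rapid (0-1000 ms) and controlled (1000-5000 ms) post-onset windows from
    FACS AU activation patterns, quantifies instructed-mimicry accuracy via
    cross-recurrence quantification analysis (cross-recurrence rate, mean
    and maximal diagonal line length, determinism), applies study-level
    snippet validity rules, and runs the mixed-design ANOVA and regression
    stage on the resulting participant-by-embodiment tables. Includes a
    seeded synthetic-cohort generator with known ground truth so the whole
    pipeline is testable end to end without raw video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
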