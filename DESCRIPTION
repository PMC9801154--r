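Package: cpvar
Title: Cognitive Performance Variability Analysis for Viral Challenge Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the cognitive performance variability (CPV) score, a
    max-pooled change statistic for repeated cognitive-test sessions, and the
    downstream analyses that relate pre-exposure CPV to post-exposure outcomes
    in a human viral challenge study: viral-shedding and symptom outcome
    scoring, correlation/R2/AUC association measures, a coefficient-of-variation
    comparator, leave-one-session-out and combinatorial session-timing
    sensitivity studies, an FDR-controlled gene-expression correlation screen
    with Fisher-exact pathway enrichment, and a synthetic study generator with
    recorded ground truth so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
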