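Package: cagtools
Title: Co-Abundant Gene Groups and Reproducible Disease Association in
    Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Groups microbial genes from whole-genome shotgun metagenomes
    into Co-Abundant Gene groups (CAGs) by cosine co-abundance, using an
    approximate-nearest-neighbor accelerated, iterative average-linkage
    clustering with an exact all-pairs oracle for verification. Tests CAGs
    for reproducible association with host disease via centered-log-ratio
    linear and mixed models, Storey q-value discovery and sign-matched
    validation across cohorts, a conservative binomial sign-agreement bound
    on the global null, Fisher/Holm-Sidak annotation enrichment, and a
    permutation test for CAG gene co-occurrence in single microbial cells.
    Includes a synthetic-data generator with planted CAG structure so every
    stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RcppHNSW,
    rhdf5,
    lme4,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
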