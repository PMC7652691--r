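Package: corisknet
Title: Comorbidity Co-Occurrence Risk Networks for Hospital Readmission
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated supervised and unsupervised analysis of comorbidity
    risk for 30-day hospital readmission in case-control cohorts. Implements
    pairwise combinatorial odds-ratio tests with directionality and
    cross-dataset replication, patient-comorbidity bipartite biclustering by
    Barber modularity maximization (BRIM) with permutation significance,
    Rand-index replication of cluster structure, and construction of the
    integrated co-occurrence risk (CoRisk) network with an exploded layout.
    Includes a seeded synthetic cohort generator with planted pairwise odds
    ratios and planted bicluster structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
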