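Package: pathcollab
Title: Collaborative Driver-Pathway Identification from Somatic Mutation Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies sets of collaborative driver pathways from somatic
    mutation calls. Genes are ranked by a score combining a Mutation Factor
    (the weighted contrast between non-synonymous and synonymous mutation
    impacts) with a topology-aware Interaction Factor built from pathway
    shortest-path distances, pairwise sample coverage and mutual exclusivity.
    Pathway enrichment is assessed by a weighted Kolmogorov-Smirnov statistic
    with a permutation null and rank-based FDR. A greedy search then assembles
    a collaborative pathway set maximizing the fraction of samples in which
    every member pathway is mutated, subject to a single-gene-dominance filter
    and a mutation-redistribution permutation test. Includes a synthetic
    somatic-mutation cohort generator with planted co-mutated pathway groups
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
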