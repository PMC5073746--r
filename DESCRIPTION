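Package: droughtnet
Title: Staged Differential Expression and Co-Expression Network
    Cartography for Water-Stress Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of multi-genotype, multi-timepoint water-stress
    expression experiments: permutation-based multiclass SAM screening,
    one-way ANOVA with Bonferroni correction, per-contrast fold-change and
    Welch t-test selection with Venn set accounting, short time-series
    model-profile clustering with permutation significance and
    cross-genotype profile matching, Pearson co-expression networks with
    heat cartography (within-module degree z-score, participation
    coefficient, average neighbour correlation, seven node roles) and
    switch-gene mining, and hypergeometric GO-slim overrepresentation.
    Includes a synthetic-data generator emulating a 2-genotype x
    2-treatment x 3-timepoint x 3-replicate microarray design with planted
    effects, modules and switch nodes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
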