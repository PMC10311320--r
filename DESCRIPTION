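Package: metaminer
Title: Significant Meta-Marker Mining over Gene-Interaction Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers genomic meta-markers, i.e. OR-aggregations of genetic
    interval variants across sets of interacting genes, that are statistically
    associated with a binary phenotype while conditioning on a categorical
    covariate via the Cochran-Mantel-Haenszel test. The search enumerates
    per-gene genomic intervals with per-gene dominant or recessive encodings
    over gene interactions derived from biological networks (connected
    subgraphs, protein complexes), and controls the family-wise error rate
    either with Tarone's testability correction or with Westfall-Young
    permutations, using minimum attainable p-values and a descendant envelope
    bound for branch-and-bound pruning. Includes a synthetic-data generator
    with a planted meta-marker for power and error-control studies, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    generics,
    ggplot2,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
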