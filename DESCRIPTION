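Package: matbin
Title: Composition-Based Binning and Community Analysis of Metagenome Assemblies
Version: 0.1.0
Authors@R:
    person("matbin", "developers", email = "matbin@example.org", role = c("aut", "cre"))
Description: Tools for composition-based analysis of metagenome assemblies
    from microbial mat communities. Computes oligonucleotide (3-6-mer) word
    frequencies and G+C statistics per scaffold, bins scaffolds into putative
    populations by Monte-Carlo consensus k-means clustering with a
    co-clustering support network, and summarizes bins. Also provides
    ordination (PCA/PCoA), Gower dissimilarity of mixed environmental
    variables with permutation-based vector fitting, non-parametric
    alpha-diversity estimators (Chao1, ACE, Fisher's alpha, Shannon, inverse
    Simpson) with analytic rarefaction, functional-category abundance
    profiling with two-way hierarchical clustering, and a synthetic community
    generator with planted structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    igraph,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
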