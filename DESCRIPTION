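Package: paranome
Title: Paralog Age Distributions for Detecting Ancient Whole-Genome Duplications
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects signatures of ancient whole-genome duplication (WGD) in
    transcriptome data from synonymous-distance (Ks) age distributions of
    paralogs. Implements the complete pipeline: all-against-all protein
    similarity search by exact affine-gap local alignment with Karlin-Altschul
    statistics, Markov clustering of the similarity graph into gene families,
    protein-guided progressive codon alignment, Nei-Gojobori (1986) and
    maximum-likelihood synonymous distance estimation, phylogeny-based
    redundancy correction that weights each duplication node's m Ks estimates
    by 1/m so every duplication event contributes unit mass, weighted kernel
    density estimation with peak calling, and reciprocal-best-hit ortholog
    divergence distributions for two-species comparisons. A codon-level
    forward simulator generates transcriptomes with planted duplication
    histories for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    igraph,
    ggplot2,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
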