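Package: asmscope
Title: Community Assembly, Co-Occurrence Networks, and Diversity Statistics
    for Microbiome Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify the ecological processes structuring microbial
    communities from an OTU count table, a rooted phylogeny, and a sample
    grouping. Implements alpha diversity (observed richness, Faith's
    phylogenetic diversity), Jaccard and Bray-Curtis dissimilarities, and
    first-principles permutation statistics (PERMANOVA, ANOSIM, PERMDISP
    dispersion distances); Dufrene-Legendre indicator value (IndVal) screening
    with permutation tests and false-discovery-rate control; per-group
    co-occurrence networks at a fixed correlation cutoff with a topological
    panel and Zi-Pi keystone classification; and phylogenetic null models for
    community assembly: nearest taxon index (NTI), beta nearest taxon index
    (betaNTI), Bray-Curtis-based Raup-Crick (RCbray), the five-way process
    classification (variable selection, homogeneous selection, dispersal
    limitation, homogenizing dispersal, drift), and a null-model beta
    deviation test of group dispersion. A synthetic community generator
    produces count tables, phylogenies, and metadata under controlled
    selection, dispersal, and drift regimes so every stage is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
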