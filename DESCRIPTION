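Package: elevassembly
Title: Community Assembly of Soil Bacteria Along Elevational Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Diversity, beta-diversity and community-assembly analysis for
    amplicon OTU tables sampled along elevational gradients. Implements the
    phylogenetic and taxonomic null models that partition assembly into
    variable selection, homogeneous selection, dispersal limitation,
    homogenizing dispersal and ecological drift (beta-NTI and Raup-Crick on
    Bray-Curtis), Sorensen beta-diversity partitioning into turnover and
    nestedness, unweighted UniFrac, ANOSIM and the Mantel family of matrix
    tests, indicator-species analysis per elevation zone, and
    phylogenetic-signal statistics for elevational habitat preference
    (preferred elevation, bootstrap patristic-distance nulls, clade
    divergence, root-to-tip contrasts). A synthetic-community generator
    simulates phylogenies, Brownian-motion elevation optima and multinomial
    sampling under tunable selection, dispersal and drift regimes so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    picante,
    phangorn,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
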