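Package: phyllocore
Title: Core Community, Abundance-Distribution and Diversity Analysis for
    Leaf-Microbiome OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for phyllosphere (crop-leaf) bacterial
    community profiles stored as OTU count tables. Implements
    occupancy-abundance core-microbiome selection with the three-criterion
    rule (mean relative abundance, occupancy, per-sample rank abundance),
    fitting and comparison of five species-abundance-distribution models
    (zero-truncated Poisson-lognormal, lognormal, Fisher log-series, Zipf,
    broken-stick) scored by variation explained on log10 rank abundance,
    alpha-diversity indices (Shannon, Simpson, Chao1, ACE) with rarefaction
    and species-accumulation curves, UniFrac/Bray-Curtis beta-diversity with
    PCoA, UPGMA and multi-response permutation procedure (MRPP) group tests,
    redundancy analysis against environmental covariates with marginal
    permutation tests, and LEfSe-style differential-abundance detection
    (Kruskal-Wallis screen plus bootstrapped linear-discriminant effect
    sizes). Includes a synthetic-data generator that emulates the assumed
    data structure (Poisson-lognormal abundances, planted core taxa,
    group-structured composition, environmental gradients, random
    phylogenies) so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    permute,
    pracma,
    stats,
    utils,
    vegan
Suggests:
    biomformat,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
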