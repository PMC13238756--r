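Package: cudelim
Title: Conservation-Unit Delineation from Landscape Genomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for delineating conservation units in
    anadromous fishes from population allele-frequency data: Hudson FST and
    allele-frequency-difference matrices, individual p-distances and BIONJ
    trees, PCA and linkage-based SNP pruning, admixture-replicate mode
    clustering and Evanno's delta-K, Mantel and partial Mantel decomposition
    of isolation by distance, environment and colonization with a
    residual-substitution procedure, pcadapt-style robust Mahalanobis genome
    scans, redundancy analysis (RDA/pRDA) with VIF pruning, backward
    selection and permutation axis tests, three-way variance partitioning,
    gene-windowed Z aggregation (WZA) of per-SNP statistics, multi-method
    consensus, region/QTL/term enrichment, and a synthetic two-lineage
    coastal landscape generator with ground-truth tables for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    igraph,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
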