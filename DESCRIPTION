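Package: ariNet
Title: Integrated GWAS, Coexpression Network, and cis-eSNP Analysis for
    Case-Control Traits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrated genomic analysis pipeline for binary traits
    such as allergic rhinitis: case/control genome-wide association scans
    with principal-component control for population stratification,
    sample-size-weighted meta-analysis across ancestry groups with genomic
    control diagnostics, weighted gene coexpression network construction
    (soft-thresholded adjacency, topological overlap, dendrogram-based
    module detection), cis expression-SNP (eSNP) mapping at a
    false-discovery-rate threshold, and the integration statistics that
    connect them: GWAS-locus module tagging within a fixed window,
    binomial enrichment of loci tagging a module, Fisher's exact
    enrichment of modules for disease-associated eSNPs, and generic
    gene-set (GMT) enrichment. A synthetic-data generator with planted
    population structure, linkage disequilibrium, coexpression modules,
    cis-eSNP effects and causal risk SNPs provides a recoverable ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    limma,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR,
    withr,
    rtracklayer
biocViews: GenomeWideAssociation, NetworkInference, GeneExpression,
    SNP, GraphAndNetwork, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
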