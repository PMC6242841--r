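Package: volatilomeGWAS
Title: Mixed-Model GWAS and Effect-Network Analysis of the Cheese Volatilome
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of the genomic architecture of volatile
    organic compound (VOC) profiles measured by PTR-ToF-MS on individual-cow
    model cheeses. Implements spectrometric peak preprocessing (intensity
    filtering, compositional log transform, isotope-satellite removal),
    genotype quality control, identity-by-state genomic relationship matrices,
    REML estimation of genomic heritability, the three-step GRAMMAR-GC
    mixed-model association scan with genomic control, cross-trait similarity
    networks built from SNP allele-substitution effect vectors with
    cohesiveness-based dense-cluster detection, and windowed SNP-to-gene
    mapping with Fisher exact gene-set enrichment under FDR control. A
    synthetic-data generator with planted QTLs, pleiotropy blocks and isotope
    satellites makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    fgsea,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr
biocViews: GenomeWideAssociation, SNP, Metabolomics, Network, GeneSetEnrichment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
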