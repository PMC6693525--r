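Package: spetkit
Title: Single Primer Enrichment Technology Panel Design, Simulation and
    Germplasm Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for single primer enrichment technology (SPET)
    genotyping of crop germplasm collections. Designs spacing-constrained
    SNP probe panels from candidate variants and a reference genome,
    simulates SPET reads for multi-species germplasm sets with
    divergence-dependent probe dropout, calls genotypes from the simulated
    readouts with depth and allele-balance filters, and summarises
    germplasm diversity and relationships (polymorphic information
    content, heterozygosity, duplicate and mislabel detection,
    neighbor-joining trees with bootstrap supports, Robinson-Foulds tree
    comparison, and principal component analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    data.table,
    igraph,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'diversity.R'
    'fixture.R'
    'formats-io.R'
    'genotyper.R'
    'panel-design.R'
    'relationships.R'
    'simulator.R'
    'spet-config.R'
    'spetkit-package.R'
    'utils.R'
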