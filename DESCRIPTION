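Package: YTraffic
Title: Gene Traffic to the Y Chromosome from Sexed Read Sets
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to characterize a repeat-rich Y chromosome from a genome
    assembly and male/female short-read sets: k-mer based identification of
    Y-linked scaffolds (the YGS procedure), detection of autosome-to-Y
    segmental duplications from the male/female binned read-depth ratio with
    intra-Y copy-number estimation and male-specific SNP counting,
    classification of duplicated gene copies as functional or pseudogene from
    CDS integrity and expression share, duplication-mechanism inference from
    segmental-duplication membership and intron-position conservation, and
    Dollo-style parsimony mapping of gene gains and losses on a species tree
    with a Poisson gain-loss rate-ratio estimator (likelihood-ratio test and
    profile confidence interval). Includes simulators for genomes, sexed read
    sets, implanted segmental duplications, pseudogenized gene copies and
    gain/loss histories that emit ground-truth labels, so the whole pipeline
    is testable without external data.
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
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Sequencing, Coverage, Genetics, CopyNumberVariation, Phylogenetics
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'covdup.R'
    'simdata.R'
    'simdata-events.R'
    'gainloss.R'
    'genefate.R'
    'kmer.R'
    'report.R'
    'ygs.R'
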