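Package: parentalASE
Title: Parental Haplotype-Resolved Allele-Specific Expression in Single Cells
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trio-based parental haplotype construction and downstream
    allele-specific expression analysis for single-cell RNA-seq of human
    fetal germ cells. Selects informative SNPs (fetal-heterozygous,
    maternal-homozygous), builds parental reference sequences, assigns
    reads to a parental allele by edit distance, and tabulates per-cell
    per-gene maternal and paternal read counts in a SummarizedExperiment
    container. On top of the counts it stages germ cells from a marker
    panel, quantifies imprinting erasure per imprinted gene-cluster under
    a dropout-aware fair-coin significance model, classifies per-cell X
    chromosome reactivation against a binned autosomal empirical null
    (plus geometric-mean and median-bias variants), runs a negative
    binomial two-group differential expression test with
    Benjamini-Hochberg correction, and summarizes CpG methylation over
    imprinting control regions. A synthetic-data module generates trio
    genotypes, allele-tagged counts and methylation reads with known
    ground truth.
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
    Biostrings,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    optparse,
    knitr
biocViews: SingleCell, Transcriptomics, AlleleSpecificExpression,
    Epigenetics, DifferentialExpression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
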