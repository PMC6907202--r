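Package: somaclone
Title: Somatic Variant Diversification Analysis for Clonally Propagated Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize how vegetatively propagated (clonal)
    lineages diversify at the genome level. Provides hard filtering and
    sanitation of multi-sample variant calls, a four-way genomic feature
    classification (exon, intron, intergenic repeat, non-repetitive
    intergenic), the clone-sharing spectrum of heterozygous variants,
    feature-stratified length-normalized mutation rates, transition /
    transversion and cytosine-context (CpG, CHG, CHH) mutation signatures, a
    minimal variant-effect classifier with a putatively-deleterious impact
    tier, KING-robust kinship with PCA and dendrogram summaries of
    relatedness, transposable-element insertion sharing and gene proximity,
    and structural variant summaries. A forward simulator of a small
    annotated diploid genome with a star pedigree of clones generates
    ground-truthed FASTA/GFF3/BED/VCF/TSV fixtures so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    VariantAnnotation,
    rtracklayer,
    ape,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
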