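#' VariantTable: multi-sample diploid variant calls
#'
#' The central exchange object of the package. A `VariantTable` extends
#' [SummarizedExperiment::RangedSummarizedExperiment]: rows are variant
#' records (a `GRanges` whose width is the length of the reference allele),
#' columns are samples, and the single `"GT"` assay holds diploid genotype
#' strings (`"0/0"`, `"0/1"`, `"1/1"`, `"./."`, ...). Row metadata carries the
#' reference allele (`REF`), the alternate alleles (`ALT`, a `CharacterList`
#' so multi-allelic records are lossless), the site quality (`QUAL`), the
#' annotation-style filter status (`FILTER`: `"."` before filtering, `"PASS"`
#' or a semicolon-joined list of failed rule names after
#' [applyHardFilters()]), and the six caller metrics `DP`, `QD`, `FS`, `MQ`,
#' `MQRankSum`, `ReadPosRankSum` (NA when absent from the source VCF).
#'
#' @slot (inherited) see `RangedSummarizedExperiment`.
#' @seealso [readVariantTable()], [makeVariantTable()], [applyHardFilters()]
#' @exportClass VariantTable
setClass("VariantTable", contains = "RangedSummarizedExperiment")

setValidity("VariantTable", function(object) {
  need <- c("REF", "ALT", "QUAL", "FILTER", VARIANT_METRICS)
  miss <- base::setdiff(need, colnames(mcols(rowRanges(object))))
  if (length(miss) > 0)
    return(paste("missing row metadata column(s):", paste(miss, collapse = ", ")))
  if (!"GT" %in% names(assays(object)))
    return("missing 'GT' assay")
  if (nrow(object) > 0 && any(nchar(mcols(rowRanges(object))$REF) == 0))
    return("empty REF allele")
  if (anyDuplicated(colnames(object)))
    return("duplicated sample names")
  TRUE
})

#' FeatureIndex: a four-way tiling of the genome
#'
#' Every base of every contig is assigned to exactly one of the classes
#' `exon`, `intron`, `intergenic-repeat`, `intergenic-nonrepetitive`.
#' Built by [buildFeatureIndex()]; queried with [classifyPosition()].
#'
#' @slot tiles `GRanges` with a `featureClass` metadata column; disjoint and
#'   covering each contig end to end.
#' @slot classLengths named numeric, total bp per class (all four classes
#'   always present, zero allowed).
#' @slot contigLengths named numeric of contig lengths.
#' @exportClass FeatureIndex
setClass("FeatureIndex",
  representation(tiles = "GRanges", classLengths = "numeric",
                 contigLengths = "numeric"))

setValidity("FeatureIndex", function(object) {
  if (!all(FEATURE_CLASSES %in% names(object@classLengths)))
    return("classLengths must name all four feature classes")
  if (abs(sum(object@classLengths) - sum(object@contigLengths)) > 0.5)
    return("classLengths must sum to the total genome length")
  tl <- object@tiles
  bad <- !as.character(mcols(tl)$featureClass) %in% FEATURE_CLASSES
  if (any(bad)) return("unknown feature class in tiles")
  # per-contig coverage check: disjoint tiles summing to contig length
  bp <- tapply(width(tl), as.character(seqnames(tl)), sum)
  for (ctg in names(object@contigLengths)) {
    got <- if (ctg %in% names(bp)) bp[[ctg]] else 0
    if (got != object@contigLengths[[ctg]])
      return(sprintf("tiles do not cover contig %s exactly", ctg))
  }
  if (!GenomicRanges::isDisjoint(tl)) return("tiles overlap")
  TRUE
})

#' CloneGenome: a simulated annotated reference
#'
#' Output of [simulateReference()]: the reference sequence, gene models,
#' intergenic repeat intervals, the derived [FeatureIndex-class], and the
#' generating [cloneSimConfig()].
#'
#' @slot sequence `DNAStringSet`, one entry per contig.
#' @slot genes `GRanges` in GFF3 layout (`type` in gene/mRNA/exon/CDS with
#'   `ID`/`Parent` metadata).
#' @slot repeats `GRanges` of intergenic repeat intervals.
#' @slot index `FeatureIndex`.
#' @slot config the simulation configuration list.
#' @exportClass CloneGenome
setClass("CloneGenome",
  representation(sequence = "DNAStringSet", genes = "GRanges",
                 repeats = "GRanges", index = "FeatureIndex",
                 config = "list"))

#' CloneSimulation: simulated variants plus ground truth
#'
#' Output of [simulateCloneVariants()].
#'
#' @slot genome the [CloneGenome-class] the variants were placed on.
#' @slot variants a [VariantTable-class] over the clone samples.
#' @slot truth `data.frame` of truth records (one per emitted variant,
#'   including TE insertions and SVs).
#' @slot te `data.frame` of TE insertions (contig, position, class, order,
#'   superfamily, carriers).
#' @slot sv `data.frame` of structural variants (contig, start, end, type,
#'   length, carriers).
#' @exportClass CloneSimulation
setClass("CloneSimulation",
  representation(genome = "CloneGenome", variants = "VariantTable",
                 truth = "data.frame", te = "data.frame", sv = "data.frame"))

setMethod("show", "VariantTable", function(object) {
  cat("VariantTable:", nrow(object), "records x", ncol(object), "samples\n")
  f <- filterStatus(object)
  if (nrow(object) > 0 && !all(f == "."))
    cat("  PASS:", sum(f == "PASS"), "/", nrow(object), "\n")
  callNextMethod()
})

setMethod("show", "FeatureIndex", function(object) {
  cat("FeatureIndex over", length(object@contigLengths), "contig(s),",
      sum(object@contigLengths), "bp\n")
  cl <- object@classLengths[FEATURE_CLASSES]
  for (k in names(cl))
    cat(sprintf("  %-26s %10d bp\n", k, as.integer(cl[[k]])))
})

setMethod("show", "CloneGenome", function(object) {
  cat("CloneGenome:", length(object@sequence), "contig(s),",
      sum(GenomeInfoDb::seqlengths(object@index@tiles)), "bp;",
      sum(mcols(object@genes)$type == "gene"), "genes,",
      length(object@repeats), "repeat intervals\n")
})

setMethod("show", "CloneSimulation", function(object) {
  cat("CloneSimulation:", nrow(object@variants), "small variants,",
      nrow(object@te), "TE insertions,", nrow(object@sv), "SVs over",
      ncol(object@variants), "samples\n")
})
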