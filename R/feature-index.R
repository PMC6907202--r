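## Four-way genomic feature classification and length-normalized rates.

#' Build a FeatureIndex from gene models and repeat intervals
#'
#' Tiles every contig into `exon`, `intron`, `intergenic-repeat` and
#' `intergenic-nonrepetitive` with the precedence exon > intron > repeat >
#' remaining intergenic. Exons of overlapping transcripts are merged; bases
#' inside a gene but outside any exon are intron (UTR-less gene models are
#' fine); repeat intervals overlapping genic bases are truncated to their
#' intergenic portion, so `intergenic-repeat` means exactly that.
#'
#' @param genes `GRanges` in GFF3 layout (needs `type` metadata with at
#'   least `gene` and `exon` rows), or a path to a GFF3 file.
#' @param repeats `GRanges` of repeat intervals, a path to a BED file, or
#'   `NULL` for none.
#' @param contigLengths named integer vector of contig lengths.
#' @return a [FeatureIndex-class].
#' @export
buildFeatureIndex <- function(genes, repeats, contigLengths) {
  if (is.character(genes)) genes <- rtracklayer::import(genes)
  if (is.character(repeats)) repeats <- rtracklayer::import(repeats)
  if (is.null(repeats)) repeats <- GRanges()
  stopifnot(!is.null(names(contigLengths)))
  contigLengths <- vapply(contigLengths, as.numeric, numeric(1))

  checkContigs <- function(gr, what) {
    ctg <- as.character(seqnames(gr))
    unknown <- base::setdiff(unique(ctg), names(contigLengths))
    if (length(unknown) > 0)
      stop("unknown contig in ", what, ": ", paste(unknown, collapse = ", "))
    over <- end(gr) > contigLengths[ctg] | start(gr) < 1
    if (any(over))
      stop(what, " interval beyond contig bounds: ",
           paste0(ctg[over][1], ":", start(gr)[over][1], "-",
                  end(gr)[over][1]))
  }
  checkContigs(genes, "gene annotation")
  if (length(repeats) > 0) checkContigs(repeats, "repeat annotation")

  si <- GenomeInfoDb::Seqinfo(names(contigLengths),
                              as.integer(contigLengths))
  asSI <- function(gr) {
    gr <- granges(gr)
    GenomeInfoDb::seqlevels(gr) <- names(contigLengths)
    GenomeInfoDb::seqinfo(gr) <- si
    gr
  }
  whole <- GRanges(names(contigLengths),
                   IRanges(1, as.integer(contigLengths)), seqinfo = si)
  typ <- as.character(mcols(genes)$type)
  exons <- reduce(asSI(genes[typ == "exon"]), ignore.strand = TRUE)
  genic <- reduce(asSI(genes[typ == "gene"]), ignore.strand = TRUE)
  if (length(genic) == 0)  # fall back to exon envelope if no gene rows
    genic <- exons
  genic <- reduce(c(genic, exons), ignore.strand = TRUE)
  introns <- GenomicRanges::setdiff(genic, exons, ignore.strand = TRUE)
  intergenic <- GenomicRanges::setdiff(whole, genic, ignore.strand = TRUE)
  reps <- reduce(asSI(repeats), ignore.strand = TRUE)
  repInter <- GenomicRanges::intersect(reps, intergenic, ignore.strand = TRUE)
  interNon <- GenomicRanges::setdiff(intergenic, repInter,
                                     ignore.strand = TRUE)

  pieces <- list(exon = exons, intron = introns,
                 `intergenic-repeat` = repInter,
                 `intergenic-nonrepetitive` = interNon)
  tiles <- do.call(c, unname(lapply(names(pieces), function(k) {
    g <- pieces[[k]]
    mcols(g)$featureClass <- rep(k, length(g))
    g
  })))
  tiles <- GenomicRanges::sort(tiles, ignore.strand = TRUE)
  cl <- vapply(pieces, function(g) sum(as.numeric(width(g))), numeric(1))
  new("FeatureIndex", tiles = tiles, classLengths = cl,
      contigLengths = contigLengths)
}

#' @describeIn buildFeatureIndex total bp per feature class
#' @param index a `FeatureIndex`
#' @export
featureClassLengths <- function(index) index@classLengths[FEATURE_CLASSES]

#' @describeIn buildFeatureIndex the tiling as a `GRanges`
#' @export
featureTiles <- function(index) index@tiles

#' Classify genomic positions
#'
#' Returns the feature class of each 1-based position. INDELs and SVs should
#' be classified by their leftmost reference-affected base (see
#' [affectedPosition()]).
#'
#' @param index a [FeatureIndex-class].
#' @param contig,position parallel vectors of contig names and 1-based
#'   positions.
#' @return character vector of feature classes.
#' @export
classifyPosition <- function(index, contig, position) {
  n <- max(length(contig), length(position))
  contig <- rep_len(as.character(contig), n)
  position <- rep_len(as.integer(position), n)
  bad <- !contig %in% names(index@contigLengths) |
    position < 1 | position > index@contigLengths[contig]
  if (any(bad))
    stop("position out of range: ", contig[bad][1], ":", position[bad][1])
  q <- GRanges(contig, IRanges(position, width = 1))
  hit <- findOverlaps(q, index@tiles, select = "first")
  as.character(mcols(index@tiles)$featureClass[hit])
}

#' Leftmost reference-affected base of a variant
#'
#' For SNVs this is the record position; for VCF-anchored deletions the first
#' deleted base (`position + 1`); for insertions the anchor base itself.
#'
#' @param position record positions (1-based).
#' @param ref,alt allele strings.
#' @return integer positions.
#' @export
affectedPosition <- function(position, ref, alt) {
  isDel <- !grepl("^<.*>$", alt) & nchar(ref) > nchar(alt)
  as.integer(position) + ifelse(isDel, 1L, 0L)
}

#' Length-normalized variant rates per feature class
#'
#' `rate = count / class_bp * 1000` (variants per kb of feature), computed
#' for each row of a count table keyed by feature class and any additional
#' grouping columns (variant type, zygosity, sample, group, ...).
#'
#' @param counts `data.frame` with columns `feature` and `count` (plus any
#'   grouping columns, carried through).
#' @param index a [FeatureIndex-class].
#' @return `counts` with added `classBp` and `ratePerKb` columns.
#' @export
normalizedRates <- function(counts, index) {
  stopifnot(all(c("feature", "count") %in% names(counts)))
  cl <- featureClassLengths(index)
  unknown <- base::setdiff(unique(counts$feature), names(cl))
  if (length(unknown) > 0)
    stop("unknown feature class: ", paste(unknown, collapse = ", "))
  bp <- cl[counts$feature]
  if (any(bp == 0 & counts$count > 0))
    stop("nonzero count in zero-length feature class")
  counts$classBp <- as.numeric(bp)
  counts$ratePerKb <- ifelse(bp > 0, counts$count / bp * 1000, 0)
  counts
}

#' Per-sample variant counts by feature class, type and zygosity
#'
#' The count table behind the normalized-rate comparison of clone panels:
#' for every sample, variants where that sample is heterozygous (`het`) or
#' homozygous-alternate (`hom`) are tallied by feature class and variant type
#' (first alt).
#'
#' @param x a [VariantTable-class] (sanitized: complete calls expected).
#' @param index a [FeatureIndex-class].
#' @param samples samples to tally (default all columns).
#' @param group optional named vector mapping sample -> group label.
#' @return `data.frame` with columns sample, group, feature, vartype,
#'   zygosity, count.
#' @export
countByFeature <- function(x, index, samples = colnames(x), group = NULL) {
  vt <- variantType(x)
  keep <- vt %in% c("SNV", "INDEL")
  x2 <- x[keep, ]; vt <- vt[keep]
  alts <- vapply(as.list(altAlleles(x2)), `[[`, character(1), 1)
  pos <- affectedPosition(start(rowRanges(x2)), refAllele(x2), alts)
  feat <- classifyPosition(index, as.character(seqnames(rowRanges(x2))), pos)
  gt <- genotypes(x2)
  grid <- expand.grid(sample = samples, feature = FEATURE_CLASSES,
                      vartype = c("SNV", "INDEL"), zygosity = c("het", "hom"),
                      stringsAsFactors = FALSE)
  grid$count <- 0L
  for (s in samples) {
    het <- gtIsHet(gt[, s]); hom <- gtIsHomAlt(gt[, s])
    for (zg in c("het", "hom")) {
      sel <- if (zg == "het") het else hom
      if (!any(sel)) next
      tb <- table(feature = feat[sel], vartype = vt[sel])
      for (f in rownames(tb)) for (v in colnames(tb)) {
        i <- grid$sample == s & grid$feature == f & grid$vartype == v &
          grid$zygosity == zg
        grid$count[i] <- as.integer(tb[f, v])
      }
    }
  }
  if (!is.null(group)) grid$group <- unname(group[grid$sample])
  grid
}
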