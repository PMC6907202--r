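## Transposable-element insertion proximity/sharing and SV summarization.

#' Read a TE-insertion table
#'
#' Tab-separated with columns `contig`, `position`, `te_class`, `te_order`,
#' `te_superfamily`, `carriers` (comma-separated clone labels).
#'
#' @param path TSV file.
#' @return `data.frame`.
#' @export
readTeTable <- function(path) {
  te <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("contig", "position", "carriers")
  stopifnot(all(need %in% names(te)))
  te
}

#' Distances from TE insertions to the nearest gene
#'
#' For each insertion: `0` on both sides (and `genic = TRUE`) when the
#' position falls inside a gene; otherwise the bp gap to the nearest gene
#' boundary on each side (`NA` when no gene lies on that side of the contig).
#' The summary reports the median and 25th percentile of the upstream,
#' downstream, and nearest-side distances over intergenic insertions.
#'
#' @param te `data.frame` with `contig` and `position` columns, or a
#'   `GRanges`.
#' @param genes `GRanges` of gene spans (rows with `type == "gene"` are used
#'   when a `type` column is present).
#' @return list with `distances` (per-insertion `data.frame`) and `summary`.
#' @export
nearestGeneDistances <- function(te, genes) {
  if (is(te, "GRanges"))
    te <- data.frame(contig = as.character(seqnames(te)),
                     position = start(te))
  if (!is.null(mcols(genes)$type))
    genes <- genes[as.character(mcols(genes)$type) == "gene"]
  genes <- reduce(granges(genes), ignore.strand = TRUE)
  n <- nrow(te)
  up <- down <- rep(NA_real_, n)
  genic <- rep(FALSE, n)
  gctg <- as.character(seqnames(genes))
  for (i in seq_len(n)) {
    g <- genes[gctg == te$contig[i]]
    if (length(g) == 0) next
    p <- te$position[i]
    if (any(start(g) <= p & end(g) >= p)) {
      genic[i] <- TRUE; up[i] <- 0; down[i] <- 0
      next
    }
    left <- end(g)[end(g) < p]
    right <- start(g)[start(g) > p]
    up[i] <- if (length(left)) p - max(left) else NA_real_
    down[i] <- if (length(right)) min(right) - p else NA_real_
  }
  d <- data.frame(contig = te$contig, position = te$position,
                  genic = genic, upstream = up, downstream = down)
  d$nearest <- pmin(d$upstream, d$downstream, na.rm = TRUE)
  d$nearest[genic] <- 0
  d$nearest[is.na(d$upstream) & is.na(d$downstream)] <- NA
  ig <- d[!d$genic & !is.na(d$nearest), ]
  q <- function(v) if (nrow(ig) == 0) c(NA, NA) else
    unname(quantile(v, c(0.5, 0.25), na.rm = TRUE))
  s <- data.frame(side = c("upstream", "downstream", "nearest"),
                  median = c(q(ig$upstream)[1], q(ig$downstream)[1],
                             q(ig$nearest)[1]),
                  q25 = c(q(ig$upstream)[2], q(ig$downstream)[2],
                          q(ig$nearest)[2]))
  list(distances = d, summary = s, nGenic = sum(genic),
       nIntergenic = sum(!genic))
}

SV_TYPES <- c("deletion", "duplication", "insertion", "inversion",
              "duplicated insertion", "inverted duplication")

#' Read the simulator's (or any VCF-like) SV records
#'
#' Accepts a VCF with symbolic alternate alleles (`<DEL>`, `<DUP>`, `<INS>`,
#' `<INV>`, `<DUP:INS>`, `<INV:DUP>`) and INFO keys `SVTYPE`, `SVLEN`, `END`,
#' and per-sample GT; returns a flat table with one row per record.
#'
#' @param path VCF file.
#' @return `data.frame` with columns contig, start, end, type, length,
#'   carriers (comma-joined samples with a non-reference genotype).
#' @export
readSvTable <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  inf <- info(vcf)
  rr <- rowRanges(vcf)
  gt <- geno(vcf)$GT
  typeMap <- c(DEL = "deletion", DUP = "duplication", INS = "insertion",
               INV = "inversion", `DUP:INS` = "duplicated insertion",
               `INV:DUP` = "inverted duplication")
  svtype <- as.character(inf$SVTYPE)
  carriers <- apply(gt, 1, function(g)
    paste(colnames(gt)[gtHasNonRef(g)], collapse = ","))
  data.frame(contig = as.character(seqnames(rr)),
             start = start(rr),
             end = as.integer(inf$END),
             type = unname(typeMap[svtype]),
             length = abs(as.integer(inf$SVLEN)),
             carriers = unname(carriers),
             stringsAsFactors = FALSE)
}

#' Merge equivalent SV records across samples
#'
#' Records of the same type on the same contig whose intervals reciprocally
#' overlap by at least `minOverlap` are treated as one event; carrier sets
#' are unioned. Insertions (width ~1) are merged when their positions differ
#' by at most `insWindow` bp.
#'
#' @param sv `data.frame` as from [readSvTable()].
#' @param minOverlap reciprocal-overlap fraction (default 0.8).
#' @param insWindow positional tolerance for insertion merging (bp).
#' @return merged `data.frame`.
#' @export
mergeSvRecords <- function(sv, minOverlap = 0.8, insWindow = 10) {
  if (nrow(sv) == 0) return(sv)
  sv$..grp <- seq_len(nrow(sv))
  for (i in seq_len(nrow(sv))) for (j in seq_len(i - 1L)) {
    if (sv$type[i] != sv$type[j] || sv$contig[i] != sv$contig[j]) next
    same <- if (sv$type[i] == "insertion" ||
                grepl("insertion", sv$type[i])) {
      abs(sv$start[i] - sv$start[j]) <= insWindow
    } else {
      ov <- min(sv$end[i], sv$end[j]) - max(sv$start[i], sv$start[j]) + 1
      wi <- sv$end[i] - sv$start[i] + 1
      wj <- sv$end[j] - sv$start[j] + 1
      ov > 0 && ov / wi >= minOverlap && ov / wj >= minOverlap
    }
    if (same) sv$..grp[sv$..grp == sv$..grp[i]] <- sv$..grp[j]
  }
  out <- do.call(rbind, lapply(split(sv, sv$..grp), function(d) {
    r <- d[1, , drop = FALSE]
    r$carriers <- paste(sort(unique(unlist(strsplit(d$carriers, ",")))),
                        collapse = ",")
    r
  }))
  out$..grp <- NULL
  rownames(out) <- NULL
  out[order(out$contig, out$start), ]
}

#' Per-type structural variant summary
#'
#' For each SV type: count, median length, total length, percent of the
#' assembly length, and the number of distinct genes intersected. Also
#' returns the per-type length-distribution statistics (quartiles and the
#' mean of log10 length) backing box-plot style summaries.
#'
#' @param sv `data.frame` with columns contig, start, end, type, length.
#' @param genes `GRanges` of gene spans (`type == "gene"` rows used if
#'   present).
#' @param assemblyLength denominator for the percent-of-assembly column; use
#'   the intended primary-assembly length even on partial input.
#' @param dropRepeatOverlap optional `GRanges` of repeats: SVs intersecting
#'   any are excluded before summarization (mirrors short-read SV-caller
#'   hygiene); `NULL` disables.
#' @return list with `summary`, `lengthStats` and `nSkipped`.
#' @export
summarizeSVs <- function(sv, genes, assemblyLength,
                         dropRepeatOverlap = NULL) {
  bad <- is.na(sv$length) & (is.na(sv$start) | is.na(sv$end))
  nSkipped <- sum(bad)
  sv <- sv[!bad, , drop = FALSE]
  sv$length[is.na(sv$length)] <- sv$end[is.na(sv$length)] -
    sv$start[is.na(sv$length)] + 1
  if (!is.null(dropRepeatOverlap) && nrow(sv) > 0) {
    gr <- GRanges(sv$contig, IRanges(sv$start, pmax(sv$start, sv$end)))
    hit <- unique(S4Vectors::queryHits(
      findOverlaps(gr, granges(dropRepeatOverlap), ignore.strand = TRUE)))
    if (length(hit)) sv <- sv[-hit, , drop = FALSE]
  }
  if (!is.null(mcols(genes)$type))
    genes <- genes[as.character(mcols(genes)$type) == "gene"]
  gg <- granges(genes)
  perType <- lapply(split(sv, factor(sv$type, levels = SV_TYPES)),
                    function(d) {
    if (nrow(d) == 0)
      return(data.frame(count = 0L, medianSize = NA_real_, totalBp = 0,
                        pctAssembly = 0, genes = 0L))
    gr <- GRanges(d$contig, IRanges(d$start, pmax(d$start, d$end)))
    hits <- findOverlaps(gr, gg, ignore.strand = TRUE)
    data.frame(count = nrow(d),
               medianSize = median(d$length),
               totalBp = sum(d$length),
               pctAssembly = 100 * sum(d$length) / assemblyLength,
               genes = length(unique(S4Vectors::subjectHits(hits))))
  })
  summ <- do.call(rbind, perType)
  summ <- cbind(type = rownames(summ), summ)
  rownames(summ) <- NULL
  lenStats <- do.call(rbind, lapply(
    split(sv, factor(sv$type, levels = SV_TYPES)), function(d) {
      if (nrow(d) == 0)
        return(data.frame(q25 = NA_real_, median = NA_real_, q75 = NA_real_,
                          meanLog10 = NA_real_))
      q <- unname(quantile(d$length, c(0.25, 0.5, 0.75)))
      data.frame(q25 = q[1], median = q[2], q75 = q[3],
                 meanLog10 = mean(log10(d$length)))
    }))
  lenStats <- cbind(type = rownames(lenStats), lenStats)
  rownames(lenStats) <- NULL
  list(summary = summ, lengthStats = lenStats, nSkipped = nSkipped)
}
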