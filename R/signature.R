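## Transition/transversion accounting and cytosine-context signatures.
##
## Plant DNA methylation occurs at CpG, CHG and CHH cytosine contexts
## (H = A, C or T); methylated cytosines spontaneously deaminate to thymine,
## so methylation-dense (repeat-rich) sequence is expected to show an excess
## of C->T transitions. These functions measure that signature.

#' Transition test for a base substitution
#'
#' TRUE iff the unordered pair \{ref, alt\} is \{A, G\} or \{C, T\}.
#' Symmetric in its arguments; bases must be in A/C/G/T.
#'
#' @param ref,alt single-base vectors (recycled).
#' @return logical vector.
#' @export
isTransition <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- toupper(rep_len(ref, n)); alt <- toupper(rep_len(alt, n))
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok))
    stop("non-ACGT base in transition test: ",
         paste(unique(c(ref[!ok], alt[!ok])), collapse = ", "))
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Ti/Tv ratios by group
#'
#' Transitions / transversions per group; `NA` (reported absent) when a
#' group has zero transversions.
#'
#' @param snv `data.frame` with columns `ref`, `alt` and any grouping
#'   columns named in `by`.
#' @param by character vector of grouping column names (default
#'   `"feature"`).
#' @return `data.frame` with the grouping columns plus nTransition,
#'   nTransversion, titv.
#' @export
titvRatio <- function(snv, by = "feature") {
  stopifnot(all(c("ref", "alt", by) %in% names(snv)))
  tr <- isTransition(snv$ref, snv$alt)
  key <- interaction(snv[by], drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(levels(key), function(k) {
    sel <- key == k
    g <- snv[which(sel)[1], by, drop = FALSE]
    nTi <- sum(tr[sel]); nTv <- sum(!tr[sel])
    cbind(g, data.frame(nTransition = nTi, nTransversion = nTv,
                        titv = if (nTv > 0) nTi / nTv else NA_real_))
  }))
  rownames(out) <- NULL
  out
}

#' Cytosine context of reference positions
#'
#' For a plus-strand C at position i: `CpG` if base i+1 is G; else `CHG` if
#' base i+2 is G; else `CHH`. A reference G is a minus-strand cytosine and is
#' evaluated on the reverse complement symmetrically. Non-C/G bases, and
#' positions whose decision requires bases beyond the contig end, return
#' `"none"`.
#'
#' @param reference `DNAStringSet` (names = contigs) or path to a FASTA.
#' @param contig,position parallel vectors (1-based positions).
#' @return character vector in c("CpG", "CHG", "CHH", "none").
#' @export
cytosineContext <- function(reference, contig, position) {
  if (is.character(reference)) reference <- readDNAStringSet(reference)
  names(reference) <- sub("\\s.*", "", names(reference))
  n <- max(length(contig), length(position))
  contig <- rep_len(as.character(contig), n)
  position <- rep_len(as.integer(position), n)
  out <- character(n)
  for (ctg in unique(contig)) {
    if (!ctg %in% names(reference)) stop("unknown contig: ", ctg)
    s <- as.character(reference[[ctg]])
    len <- nchar(s)
    sel <- which(contig == ctg)
    p <- position[sel]
    if (any(p < 1 | p > len))
      stop("position out of range on ", ctg)
    base <- substring(s, p, p)
    p1 <- ifelse(p + 1 <= len, substring(s, p + 1, p + 1), "")
    p2 <- ifelse(p + 2 <= len, substring(s, p + 2, p + 2), "")
    m1 <- ifelse(p - 1 >= 1, substring(s, p - 1, p - 1), "")
    m2 <- ifelse(p - 2 >= 1, substring(s, p - 2, p - 2), "")
    ctx <- rep("none", length(p))
    isC <- base == "C"
    ctx[isC & p1 == "G"] <- "CpG"
    ctx[isC & p1 %in% c("A", "C", "T") & p2 == "G"] <- "CHG"
    ctx[isC & p1 %in% c("A", "C", "T") & p2 %in% c("A", "C", "T")] <- "CHH"
    ## G = cytosine on the minus strand; complemented neighbours read 5'->3'
    ## on that strand are comp(base at i-1), comp(base at i-2).
    isG <- base == "G"
    ctx[isG & m1 == "C"] <- "CpG"
    ctx[isG & m1 %in% c("A", "G", "T") & m2 == "C"] <- "CHG"
    ctx[isG & m1 %in% c("A", "G", "T") & m2 %in% c("A", "G", "T")] <- "CHH"
    out[sel] <- ctx
  }
  out
}

#' Census of cytosine-context sites per feature class
#'
#' Counts reference cytosine sites (both strands: every C and every G) in
#' CpG, CHG and CHH context within each feature class. A CpG dinucleotide
#' therefore contributes two sites, one per strand — the denominators of
#' [contextTransitionPercentages()] count cytosines, not dinucleotides.
#'
#' @param reference `DNAStringSet` or FASTA path.
#' @param index a [FeatureIndex-class].
#' @return `data.frame` with columns feature, context, nSites.
#' @export
contextCensus <- function(reference, index) {
  if (is.character(reference)) reference <- readDNAStringSet(reference)
  names(reference) <- sub("\\s.*", "", names(reference))
  rows <- list()
  for (ctg in names(index@contigLengths)) {
    s <- as.character(reference[[ctg]])
    ch <- strsplit(s, "")[[1]]
    pos <- which(ch %in% c("C", "G"))
    if (length(pos) == 0) next
    ctx <- cytosineContext(reference, ctg, pos)
    feat <- classifyPosition(index, ctg, pos)
    keep <- ctx != "none"
    if (!any(keep)) next
    rows[[ctg]] <- data.frame(feature = feat[keep], context = ctx[keep])
  }
  d <- do.call(rbind, rows)
  grid <- expand.grid(feature = FEATURE_CLASSES,
                      context = c("CpG", "CHG", "CHH"),
                      stringsAsFactors = FALSE)
  tb <- table(factor(d$feature, FEATURE_CLASSES),
              factor(d$context, c("CpG", "CHG", "CHH")))
  grid$nSites <- mapply(function(f, c) as.integer(tb[f, c]),
                        grid$feature, grid$context)
  grid[order(grid$feature, grid$context), ]
}

#' Percentage of context sites carrying a unique C->T transition, per clone
#'
#' For each clone, feature class and cytosine context:
#' `100 * (context sites whose reference C carries a clone-unique
#' heterozygous C->T transition) / (context sites in the class)`. On the
#' minus strand the deamination signature reads G->A against the reference.
#' Only C->T (and mirrored G->A) changes count — the mechanism (deamination
#' of methylated cytosine) is directional. The summary reports the mean and
#' standard error across clones; clones with no unique SNVs contribute 0.
#'
#' @param snv `data.frame` of clone-unique (N = 1) heterozygous SNVs with
#'   columns `clone`, `contig`, `position`, `ref`, `alt`.
#' @param reference `DNAStringSet` or FASTA path.
#' @param index a [FeatureIndex-class].
#' @param clones clone labels (ensures zero rows for mutation-free clones).
#' @param census optional precomputed [contextCensus()] (it only depends on
#'   reference + index).
#' @return list with `perClone` (clone x feature x context percentages) and
#'   `summary` (feature x context mean, se, nClones).
#' @export
contextTransitionPercentages <- function(snv, reference, index, clones,
                                         census = NULL) {
  if (is.null(census)) census <- contextCensus(reference, index)
  mut <- snv[(snv$ref == "C" & snv$alt == "T") |
             (snv$ref == "G" & snv$alt == "A"), , drop = FALSE]
  if (nrow(mut) > 0) {
    mut$context <- cytosineContext(reference, mut$contig, mut$position)
    mut$feature <- classifyPosition(index, mut$contig, mut$position)
    mut <- mut[mut$context != "none", , drop = FALSE]
  }
  grid <- expand.grid(clone = clones, feature = FEATURE_CLASSES,
                      context = c("CpG", "CHG", "CHH"),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$clone, d$feature, d$context)
  cnt <- if (nrow(mut) > 0) table(key(mut)) else table(character())
  grid$nMutated <- as.integer(cnt[key(grid)])
  grid$nMutated[is.na(grid$nMutated)] <- 0L
  ck <- paste(census$feature, census$context)
  grid$nSites <- census$nSites[match(paste(grid$feature, grid$context), ck)]
  grid$percent <- ifelse(grid$nSites > 0,
                         100 * grid$nMutated / grid$nSites, NA_real_)
  summ <- do.call(rbind, lapply(
    split(grid, paste(grid$feature, grid$context)), function(d) {
      data.frame(feature = d$feature[1], context = d$context[1],
                 mean = mean(d$percent), se = sd(d$percent) /
                   sqrt(sum(!is.na(d$percent))),
                 nClones = length(clones))
    }))
  rownames(summ) <- NULL
  summ <- summ[order(summ$feature, summ$context), ]
  list(perClone = grid, summary = summ)
}
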