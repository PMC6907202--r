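## Independent brute-force oracles used to validate the implementation.

## --- translate-and-diff effect oracle -------------------------------------
## Applies the edit to the raw contig string, shifts CDS intervals by plain
## interval arithmetic, re-extracts and translates the full CDS, and
## classifies by whole-protein comparison. Valid for variants fully inside
## one CDS exon with >= 1 codon margin from the CDS start and stop.

oracleCdsCoord <- function(starts, ends, strandChar, pos) {
  cum <- 0L
  for (i in seq_along(starts)) {
    if (pos >= starts[i] && pos <= ends[i]) {
      cc <- cum + (pos - starts[i] + 1L)
      total <- sum(ends - starts + 1L)
      return(if (strandChar == "-") total - cc + 1L else cc)
    }
    cum <- cum + (ends[i] - starts[i] + 1L)
  }
  NA_integer_
}

oracleRevComp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

oracleTranslate <- function(s) {
  as.character(Biostrings::translate(Biostrings::DNAString(s)))
}

oracleEffect <- function(starts, ends, strandChar, contigSeq, pos, ref,
                         alt) {
  extract <- function(seqStr, s, e) {
    parts <- vapply(seq_along(s), function(i)
      substr(seqStr, s[i], e[i]), character(1))
    cds <- paste(parts, collapse = "")
    if (strandChar == "-") cds <- oracleRevComp(cds)
    cds
  }
  refCds <- extract(contigSeq, starts, ends)
  delta <- nchar(alt) - nchar(ref)
  editEnd <- pos + nchar(ref) - 1L
  mutSeq <- paste0(substr(contigSeq, 1, pos - 1), alt,
                   substr(contigSeq, editEnd + 1, nchar(contigSeq)))
  s2 <- ifelse(starts > editEnd, starts + delta, starts)
  e2 <- ifelse(ends > editEnd, ends + delta, ends)
  mutCds <- extract(mutSeq, s2, e2)
  if (nchar(mutCds) %% 3 != 0) return("frameshift")
  pRef <- oracleTranslate(refCds)
  pMut <- oracleTranslate(mutCds)
  if (substr(pMut, 1, 1) != "M") return("start_lost")
  firstStop <- regexpr("*", pMut, fixed = TRUE)
  if (firstStop == -1) return("stop_lost")
  if (firstStop < nchar(pMut)) return("stop_gained")
  if (pMut == pRef) return("synonymous")
  if (delta == 0) return("missense")
  "inframe_indel"
}

## random CDS variant generators with clean margins inside one CDS exon

randomCdsSnv <- function(model, seqStr) {
  starts <- GenomicRanges::start(model$cds)
  ends <- GenomicRanges::end(model$cds)
  total <- sum(ends - starts + 1L)
  repeat {
    ex <- sample(length(starts), 1)
    if (ends[ex] - starts[ex] < 8) next
    pos <- sample(seq(starts[ex] + 1, ends[ex] - 1), 1)
    cc <- oracleCdsCoord(starts, ends, model$strand, pos)
    if (cc >= 4 && cc <= total - 3) break
  }
  ref <- substr(seqStr, pos, pos)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  list(pos = pos, ref = ref, alt = alt)
}

randomCdsIndel <- function(model, seqStr) {
  starts <- GenomicRanges::start(model$cds)
  ends <- GenomicRanges::end(model$cds)
  total <- sum(ends - starts + 1L)
  repeat {
    ex <- sample(length(starts), 1)
    if (ends[ex] - starts[ex] < 20) next
    del <- runif(1) < 0.5
    L <- sample(1:6, 1)
    if (del) {
      p1 <- sample(seq(starts[ex] + 2, ends[ex] - L - 1), 1)
      cc1 <- oracleCdsCoord(starts, ends, model$strand, p1)
      cc2 <- oracleCdsCoord(starts, ends, model$strand, p1 + L - 1)
      if (min(cc1, cc2) >= 5 && max(cc1, cc2) <= total - 4) {
        pos <- p1 - 1L
        ref <- substr(seqStr, pos, pos + L)
        return(list(pos = pos, ref = ref, alt = substr(seqStr, pos, pos)))
      }
    } else {
      pos <- sample(seq(starts[ex] + 1, ends[ex] - 2), 1)
      cc <- oracleCdsCoord(starts, ends, model$strand, pos)
      if (cc >= 4 && cc <= total - 4) {
        ref <- substr(seqStr, pos, pos)
        ins <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                     collapse = "")
        return(list(pos = pos, ref = ref, alt = paste0(ref, ins)))
      }
    }
  }
}

## --- cytosine context by 3-mer scan ---------------------------------------

oracleContext <- function(seqStr, pos) {
  ch <- strsplit(seqStr, "")[[1]]
  vapply(pos, function(i) {
    b <- ch[i]
    triplet <- function(v) {
      v[is.na(v)] <- "$"  # off-contig
      v
    }
    classify <- function(n1, n2) {
      if (identical(n1, "G")) return("CpG")
      if (!n1 %in% c("A", "C", "T")) return("none")
      if (identical(n2, "G")) return("CHG")
      if (n2 %in% c("A", "C", "T")) return("CHH")
      "none"
    }
    if (identical(b, "C")) {
      n <- triplet(ch[c(i + 1, i + 2)])
      classify(n[1], n[2])
    } else if (identical(b, "G")) {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      up <- triplet(ch[c(i - 1, i - 2)])
      n <- ifelse(up %in% names(comp), comp[up], "$")
      classify(unname(n[1]), unname(n[2]))
    } else "none"
  }, character(1))
}

## --- Venn partition by per-site membership loop ---------------------------

oracleVenn <- function(sets) {
  un <- unique(unlist(sets))
  pats <- vapply(un, function(s)
    paste(as.integer(vapply(sets, function(x) s %in% x, logical(1))),
          collapse = ""), character(1))
  as.list(table(pats))
}

## --- naive average-linkage agglomeration ----------------------------------

oracleAverageLinkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL; bestd <- Inf
    for (i in seq_len(length(clusters) - 1))
      for (j in seq(i + 1, length(clusters))) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
      }
    merges[[length(merges) + 1]] <- sort(c(clusters[[best[1]]],
                                           clusters[[best[2]]]))
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  list(merges = merges, heights = heights)
}

## merged leaf sets of an hclust, in merge order
hclustMergeSets <- function(hc) {
  n <- length(hc$order) + 1 - 1
  sets <- list()
  members <- list()
  for (k in seq_len(nrow(hc$merge))) {
    grab <- function(v) if (v < 0) -v else members[[v]]
    members[[k]] <- sort(c(grab(hc$merge[k, 1]), grab(hc$merge[k, 2])))
    sets[[k]] <- members[[k]]
  }
  sets
}

## --- brute-force nearest gene scan ----------------------------------------

oracleGeneDistances <- function(contig, position, geneDf) {
  g <- geneDf[geneDf$contig == contig, ]
  if (nrow(g) == 0) return(c(NA, NA))
  if (any(g$start <= position & g$end >= position)) return(c(0, 0))
  lefts <- g$end[g$end < position]
  rights <- g$start[g$start > position]
  c(if (length(lefts)) position - max(lefts) else NA,
    if (length(rights)) min(rights) - position else NA)
}
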