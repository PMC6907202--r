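## The "shared by only N clones" spectrum of heterozygous variants.

#' Sharing level of each record
#'
#' The number of clone samples heterozygous for the considered alternate
#' allele. Homozygous-reference and (by default) homozygous-alternate
#' genotypes are non-carriers; the latter are regarded as likely technical
#' artifacts in a clonal panel, where true somatic mutations are expected
#' heterozygous.
#'
#' @param x a [VariantTable-class] with no missing genotypes among
#'   `cloneSamples` (run [completeCallSites()] first; missing genotypes are
#'   an error).
#' @param cloneSamples the clone sample columns (default all).
#' @param altIndex which alternate allele defines carriage.
#' @return integer vector of N, one per record.
#' @export
sharingLevel <- function(x, cloneSamples = colnames(x), altIndex = 1) {
  stopifnot(is(x, "VariantTable"))
  gt <- genotypes(x)[, cloneSamples, drop = FALSE]
  if (nrow(gt) > 0 && any(apply(gt, 1, function(g) any(gtIsMissing(g)))))
    stop("missing genotypes present; restrict to complete-call sites first")
  as.integer(apply(gt, 1, function(g)
    sum(gtCarriesAltHet(g, altIndex))))
}

#' Build the clone-sharing spectrum
#'
#' Counts heterozygous variants by sharing level N, per variant type (SNV,
#' INDEL, and optionally SV and TEI), overall (`feature = "all"`) and, when a
#' [FeatureIndex-class] is supplied, stratified by feature class for SNVs and
#' INDELs. Sites carried by no clone (N = 0) are excluded. TEI sharing uses
#' presence/absence from the carrier column; SV sharing uses genotype
#' presence after [mergeSvRecords()].
#'
#' @param x a sanitized [VariantTable-class] (PASS + complete calls); records
#'   not passing filters are dropped here by default.
#' @param cloneSamples clone sample columns.
#' @param index optional [FeatureIndex-class] for the feature stratification.
#' @param te optional TE-insertion `data.frame` (see [readTeTable()]).
#' @param sv optional SV `data.frame` (see [readSvTable()]); merged before
#'   counting.
#' @param excludeUniformHet when TRUE, sites at which every clone has the
#'   identical heterozygous genotype are excluded (such loci read as
#'   ancestral background rather than "variant sites" under some
#'   conventions); default FALSE keeps them, so the N = n-clones bin reflects
#'   full ancestral sharing.
#' @param usePass drop non-PASS records first (default TRUE; unannotated
#'   `"."` counts as pass).
#' @param svMinOverlap reciprocal-overlap threshold for SV merging.
#' @return `data.frame` with columns vartype, feature, N, count, proportion
#'   (proportion within each vartype x feature stratum).
#' @export
buildSpectrum <- function(x, cloneSamples = colnames(x), index = NULL,
                          te = NULL, sv = NULL, excludeUniformHet = FALSE,
                          usePass = TRUE, svMinOverlap = 0.8) {
  stopifnot(is(x, "VariantTable"))
  if (usePass) x <- passingRecords(x)
  if (nrow(x) == 0 && is.null(te) && is.null(sv)) {
    warning("empty input; empty spectrum returned")
    return(data.frame(vartype = character(), feature = character(),
                      N = integer(), count = integer(),
                      proportion = numeric()))
  }
  nClones <- length(cloneSamples)
  N <- sharingLevel(x, cloneSamples)
  if (excludeUniformHet && nrow(x) > 0) {
    gt <- genotypes(x)[, cloneSamples, drop = FALSE]
    uniform <- apply(gt, 1, function(g)
      all(gtIsHet(g)) && length(unique(g)) == 1)
    keep <- !uniform
    x <- x[keep, ]; N <- N[keep]
  }
  vt <- variantType(x)
  keep <- N > 0 & vt %in% c("SNV", "INDEL")
  x <- x[keep, ]; N <- N[keep]; vt <- vt[keep]

  rows <- list()
  addStratum <- function(vartype, feature, Ns) {
    if (length(Ns) == 0) return()
    tb <- table(factor(Ns, levels = seq_len(nClones)))
    nz <- tb[tb > 0]
    rows[[length(rows) + 1]] <<- data.frame(
      vartype = vartype, feature = feature,
      N = as.integer(names(nz)), count = as.integer(nz),
      proportion = as.integer(nz) / sum(tb))
  }
  for (v in c("SNV", "INDEL")) addStratum(v, "all", N[vt == v])
  if (!is.null(index) && nrow(x) > 0) {
    alts <- vapply(as.list(altAlleles(x)), `[[`, character(1), 1)
    pos <- affectedPosition(start(rowRanges(x)), refAllele(x), alts)
    feat <- classifyPosition(index, as.character(seqnames(rowRanges(x))),
                             pos)
    for (v in c("SNV", "INDEL")) for (f in FEATURE_CLASSES)
      addStratum(v, f, N[vt == v & feat == f])
  }
  if (!is.null(te) && nrow(te) > 0) {
    teN <- vapply(strsplit(te$carriers, ","), function(cc)
      length(base::intersect(cc, cloneSamples)), integer(1))
    addStratum("TEI", "all", teN[teN > 0])
  }
  if (!is.null(sv) && nrow(sv) > 0) {
    svm <- mergeSvRecords(sv, minOverlap = svMinOverlap)
    svN <- vapply(strsplit(svm$carriers, ","), function(cc)
      length(base::intersect(cc, cloneSamples)), integer(1))
    addStratum("SV", "all", svN[svN > 0])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(vartype = character(), feature = character(), N = integer(),
               count = integer(), proportion = numeric())
  rownames(out) <- NULL
  attr(out, "nClones") <- nClones
  out
}

#' Headline fractions of a sharing spectrum
#'
#' The fraction of each variant type shared by all clones (ancestral
#' heterozygosity) and the fraction occurring in at most `maxFew` clones
#' (recent somatic mutation), read from the `feature == "all"` strata.
#'
#' @param spectrum output of [buildSpectrum()].
#' @param nClones panel size (defaults to the attribute set by
#'   [buildSpectrum()]).
#' @param maxFew threshold for "few clones" (default 2).
#' @return `data.frame` with vartype, total, sharedByAll, fractionSharedByAll,
#'   fractionAtMostFew.
#' @export
spectrumHeadlines <- function(spectrum, nClones = attr(spectrum, "nClones"),
                              maxFew = 2) {
  s <- spectrum[spectrum$feature == "all", ]
  out <- do.call(rbind, lapply(split(s, s$vartype), function(d) {
    tot <- sum(d$count)
    data.frame(vartype = d$vartype[1], total = tot,
               sharedByAll = sum(d$count[d$N == nClones]),
               fractionSharedByAll = sum(d$count[d$N == nClones]) / tot,
               fractionAtMostFew = sum(d$count[d$N <= maxFew]) / tot)
  }))
  rownames(out) <- NULL
  out
}

#' Per-TE-classification sharing spectrum
#'
#' The TEI spectrum keyed by the Wicker-style class/order/superfamily strings
#' present in the input.
#'
#' @param te TE-insertion `data.frame` with `te_class`, `te_order`,
#'   `te_superfamily` and `carriers` columns.
#' @param cloneSamples clone labels.
#' @return `data.frame` with columns classification, N, count.
#' @export
teClassificationSpectrum <- function(te, cloneSamples) {
  lab <- apply(te[, c("te_class", "te_order", "te_superfamily")], 1,
               function(r) paste(r[!is.na(r) & r != ""], collapse = "/"))
  N <- vapply(strsplit(te$carriers, ","), function(cc)
    length(base::intersect(cc, cloneSamples)), integer(1))
  d <- data.frame(classification = lab, N = N)
  d <- d[d$N > 0, ]
  out <- as.data.frame(table(classification = d$classification, N = d$N),
                       stringsAsFactors = FALSE)
  out <- out[out$Freq > 0, ]
  names(out)[3] <- "count"
  out$N <- as.integer(out$N)
  rownames(out) <- NULL
  out[order(out$classification, out$N), ]
}
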