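## Hard filtering and call sanitation for multi-sample variant tables.

#' Hard-filter configuration
#'
#' One removal rule per caller metric, with the conventional GATK-style
#' defaults: a record *fails* a rule when its metric satisfies the printed
#' condition. The default set is `DP > 20`, `DP < 5`, `QUAL < 20`,
#' `QD < 2.0`, `FS > 60.0`, `MQ < 40.0`, `MQRankSum < -12.5`,
#' `ReadPosRankSum < -8.0`. Note that `DP > 20` together with `DP < 5`
#' retains only records with DP in \[5, 20\]; at ~30x coverage this pair of
#' conditions is surprising and is likely intended as a much higher
#' high-depth cap, but the defaults apply the rules exactly as written —
#' disable or re-threshold either rule individually if that is not what your
#' data need.
#'
#' @param rules optional `data.frame` with columns `name`, `metric`
#'   (`"QUAL"` or one of the INFO metrics), `op` (`">"` or `"<"`),
#'   `threshold`, `enabled`; defaults to the set above.
#' @param disable character vector of rule names to disable.
#' @return a `data.frame` of rules (class `"somaclone_filter_config"`).
#' @examples
#' filterConfig(disable = "DP>20")
#' @export
filterConfig <- function(rules = NULL, disable = character()) {
  if (is.null(rules)) {
    rules <- data.frame(
      metric = c("DP", "DP", "QUAL", "QD", "FS", "MQ", "MQRankSum",
                 "ReadPosRankSum"),
      op = c(">", "<", "<", "<", ">", "<", "<", "<"),
      threshold = c(20, 5, 20, 2.0, 60.0, 40.0, -12.5, -8.0),
      stringsAsFactors = FALSE)
    rules$name <- paste0(rules$metric, rules$op, rules$threshold)
    rules$enabled <- TRUE
  }
  stopifnot(all(c("name", "metric", "op", "threshold", "enabled") %in%
                  names(rules)),
            all(rules$op %in% c(">", "<")),
            all(is.finite(rules$threshold)))
  rules$enabled <- rules$enabled & !(rules$name %in% disable)
  class(rules) <- c("somaclone_filter_config", "data.frame")
  rules
}

#' Annotate records with hard-filter status
#'
#' Evaluates every enabled rule of `cfg` against each record's metrics (and
#' QUAL) and rewrites the `FILTER` column: `"PASS"` when no rule fires, else
#' the semicolon-joined names of every failed rule. Records are annotated,
#' never removed. A rule whose metric is absent (NA) for a record is not
#' evaluated there; each such rule is reported once via `message()`.
#'
#' @param x a [VariantTable-class].
#' @param cfg a [filterConfig()].
#' @return `x` with updated filter status.
#' @export
applyHardFilters <- function(x, cfg = filterConfig()) {
  stopifnot(is(x, "VariantTable"))
  cfg <- cfg[cfg$enabled, , drop = FALSE]
  if (nrow(cfg) == 0) stop("no enabled filter rules")
  n <- nrow(x)
  failed <- vector("list", n)
  met <- as.data.frame(variantMetrics(x))
  met$QUAL <- variantQual(x)
  for (i in seq_len(nrow(cfg))) {
    v <- met[[cfg$metric[i]]]
    if (is.null(v)) v <- rep(NA_real_, n)
    if (anyNA(v))
      message("rule ", cfg$name[i], " skipped for ", sum(is.na(v)),
              " record(s) with absent ", cfg$metric[i])
    hit <- !is.na(v) & (if (cfg$op[i] == ">") v > cfg$threshold[i]
                        else v < cfg$threshold[i])
    for (j in which(hit)) failed[[j]] <- c(failed[[j]], cfg$name[i])
  }
  status <- vapply(failed, function(f)
    if (is.null(f)) "PASS" else paste(f, collapse = ";"), character(1))
  if (any(status == "PASS" & apply(is.na(met), 1, all)))
    warning("record(s) with all metrics absent were vacuously PASSed")
  mcols(rowRanges(x))$FILTER <- status
  x
}

#' Keep only PASS (or unannotated) records
#'
#' @param x a [VariantTable-class].
#' @return the subset of `x` whose filter status is `"PASS"` or `"."`.
#' @export
passingRecords <- function(x) {
  x[filterStatus(x) %in% c("PASS", "."), ]
}

#' Remove records with non-reference calls in the reference sample
#'
#' When the panel's reference genome was assembled from one of the sequenced
#' samples, any non-reference genotype called for that sample against its own
#' assembly is an error; records containing one are removed wholesale. The
#' fraction removed is attached as attribute `"removedFraction"` and logged.
#'
#' @param x a [VariantTable-class].
#' @param refSample the reference sample's column name.
#' @return the cleaned table (reference sample column retained).
#' @export
dropReferenceNonref <- function(x, refSample) {
  stopifnot(is(x, "VariantTable"))
  if (!refSample %in% colnames(x))
    stop("unknown sample label: ", refSample)
  bad <- gtHasNonRef(genotypes(x)[, refSample])
  out <- x[!bad, ]
  frac <- if (nrow(x) > 0) mean(bad) else 0
  message(sprintf("dropReferenceNonref: removed %d/%d records (%.1f%%)",
                  sum(bad), nrow(x), 100 * frac))
  attr(out, "removedFraction") <- frac
  out
}

#' Restrict to sites called in every sample
#'
#' @param x a [VariantTable-class].
#' @return the subset of records with no missing genotype in any sample.
#' @export
completeCallSites <- function(x) {
  stopifnot(is(x, "VariantTable"))
  if (nrow(x) == 0) return(x)
  miss <- apply(genotypes(x), 1, function(g) any(gtIsMissing(g)))
  x[!miss, ]
}

#' Concordance partition of multiple call sets
#'
#' Given two or more named sets of variant-site keys (e.g.
#' `"contig:pos:ref:alt"` strings), counts every membership pattern of the
#' Venn partition and summarizes, per set, the sites unique to it.
#'
#' @param callSets named list (length >= 2) of character vectors.
#' @return list with `partition` (`data.frame`: one row per observed
#'   membership pattern, logical column per set, `count`), `nUnion`, and
#'   `perSet` (`data.frame`: set, size, unique count, fraction of the set's
#'   own sites unsupported by any other set, fraction of the union unique to
#'   the set).
#' @export
callSetConcordance <- function(callSets) {
  if (length(callSets) < 2) stop("need at least two call sets")
  if (is.null(names(callSets)) || any(names(callSets) == ""))
    stop("call sets must be named")
  callSets <- lapply(callSets, unique)
  un <- unique(unlist(callSets, use.names = FALSE))
  memb <- vapply(callSets, function(s) un %in% s, logical(length(un)))
  if (length(un) == 1) memb <- matrix(memb, nrow = 1,
                                      dimnames = list(NULL, names(callSets)))
  pat <- apply(memb, 1, function(r) paste(as.integer(r), collapse = ""))
  tab <- table(pat)
  pm <- do.call(rbind, lapply(names(tab), function(p)
    as.logical(as.integer(strsplit(p, "")[[1]]))))
  part <- as.data.frame(pm)
  names(part) <- names(callSets)
  part$count <- as.integer(tab)
  rownames(part) <- NULL
  onlyOne <- rowSums(memb) == 1
  per <- data.frame(
    set = names(callSets),
    size = vapply(callSets, length, integer(1)),
    unique = vapply(seq_along(callSets), function(j)
      sum(memb[, j] & onlyOne), integer(1)),
    row.names = NULL)
  per$fractionOfSetUnique <- ifelse(per$size > 0, per$unique / per$size, NA)
  per$fractionOfUnionUnique <- per$unique / length(un)
  list(partition = part, nUnion = length(un), perSet = per)
}

#' Site keys for concordance comparison
#'
#' `contig:position:ref:alt` strings, one per (record, alt) pair, suitable
#' for [callSetConcordance()].
#'
#' @param x a [VariantTable-class].
#' @param altIndex alt allele index, or `NULL` for all alts.
#' @return character vector.
#' @export
variantKeys <- function(x, altIndex = 1) {
  alts <- as.list(altAlleles(x))
  ctg <- as.character(seqnames(rowRanges(x)))
  pos <- start(rowRanges(x))
  rf <- refAllele(x)
  if (!is.null(altIndex)) {
    a <- vapply(alts, function(z)
      if (length(z) >= altIndex) z[[altIndex]] else NA_character_,
      character(1))
    return(paste(ctg, pos, rf, a, sep = ":"))
  }
  unlist(lapply(seq_along(alts), function(i)
    paste(ctg[i], pos[i], rf[i], alts[[i]], sep = ":")))
}
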