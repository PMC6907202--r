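## KING-robust kinship, genotype PCA and hierarchical clustering.

#' Dosage genotype matrix from a variant table
#'
#' Non-reference allele counts (0/1/2, NA = missing) at biallelic SNV sites,
#' the substrate for kinship and PCA. By default only PASS (or unannotated)
#' records are used and multi-allelic sites are excluded (dosage is
#' ill-defined there); the number excluded is reported via `message()`.
#'
#' @param x a [VariantTable-class].
#' @param samples columns to keep (default all).
#' @param snvOnly keep only single-base ref/alt records (default TRUE).
#' @param usePass drop non-PASS records first (default TRUE).
#' @return integer matrix, sites x samples.
#' @export
genotypeMatrix <- function(x, samples = colnames(x), snvOnly = TRUE,
                           usePass = TRUE) {
  stopifnot(is(x, "VariantTable"))
  if (usePass) x <- passingRecords(x)
  nAlt <- lengths(altAlleles(x))
  multi <- nAlt > 1
  if (any(multi))
    message(sum(multi), " multi-allelic site(s) excluded from the genotype ",
            "matrix")
  x <- x[!multi, ]
  if (snvOnly) x <- x[variantType(x) == "SNV", ]
  gt <- genotypes(x)[, samples, drop = FALSE]
  d <- apply(gt, 2, gtDosage)
  if (nrow(gt) == 1) d <- matrix(d, nrow = 1, dimnames = list(NULL, samples))
  rownames(d) <- variantKeys(x)
  d
}

#' KING-robust kinship coefficient of a sample pair
#'
#' The within-family robust estimator
#' \deqn{\phi = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa}(i) + N_{Aa}(j)}}
#' where, over pairwise-complete sites, \eqn{N_{Aa,Aa}} counts sites with
#' both samples heterozygous, \eqn{N_{AA,aa}} sites with opposite
#' homozygotes, and \eqn{N_{Aa}(\cdot)} each sample's heterozygous sites.
#' The estimator ranges from ~0 (unrelated) through 0.25 (parent-offspring)
#' to exactly 0.5 for self-comparison.
#'
#' @param gi,gj integer dosage vectors (0/1/2/NA) over the same sites.
#' @return the kinship coefficient phi.
#' @export
kingPhi <- function(gi, gj) {
  stopifnot(length(gi) == length(gj))
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  if (length(gi) == 0) stop("no pairwise-complete sites")
  n11 <- sum(gi == 1 & gj == 1)
  nOpp <- sum((gi == 0 & gj == 2) | (gi == 2 & gj == 0))
  nHet <- sum(gi == 1) + sum(gj == 1)
  if (nHet == 0)
    stop("kinship undefined: no heterozygous sites in either sample ",
         "over pairwise-complete sites")
  (n11 - 2 * nOpp) / nHet
}

#' All-pairs kinship matrix
#'
#' Symmetric matrix of [kingPhi()] over the columns of a dosage matrix.
#' The diagonal is computed (not assigned) and equals 0.5 for any sample
#' with at least one heterozygous site. Pairs whose denominator is zero are
#' set to NA with a warning.
#'
#' @param gm sites x samples dosage matrix (see [genotypeMatrix()]).
#' @return samples x samples numeric matrix.
#' @export
kinshipMatrix <- function(gm) {
  ns <- ncol(gm)
  if (ns < 2) stop("need at least two samples")
  phi <- matrix(NA_real_, ns, ns, dimnames = list(colnames(gm),
                                                  colnames(gm)))
  undef <- character()
  for (i in seq_len(ns)) for (j in i:ns) {
    v <- tryCatch(kingPhi(gm[, i], gm[, j]), error = function(e) NA_real_)
    if (is.na(v) && i != j)
      undef <- c(undef, paste(colnames(gm)[i], colnames(gm)[j], sep = "-"))
    phi[i, j] <- phi[j, i] <- v
  }
  if (length(undef) > 0)
    warning("kinship undefined for pair(s): ", paste(undef, collapse = ", "))
  phi
}

#' Principal component analysis of genotype dosages
#'
#' Mean-centered (unscaled) dosages decomposed with [stats::prcomp()].
#' The sample the reference assembly was built from is conventionally
#' excluded (its calls against its own assembly are not comparable);
#' pass its label via `exclude`.
#'
#' @param gm sites x samples dosage matrix.
#' @param exclude sample labels to drop before the decomposition.
#' @param nComponents how many components to return.
#' @return list with `scores` (samples x components), `varianceExplained`
#'   (fractions), `nSites`.
#' @export
genotypePCA <- function(gm, exclude = NULL, nComponents = 10) {
  if (!is.null(exclude)) gm <- gm[, !colnames(gm) %in% exclude, drop = FALSE]
  if (ncol(gm) < 2 || nrow(gm) < 2)
    stop("need at least two samples and two sites")
  gm <- gm[complete.cases(gm), , drop = FALSE]
  m <- t(gm)  # samples x sites
  keep <- apply(m, 2, function(v) stats::var(v) > 0)
  if (!any(keep)) stop("degenerate decomposition: all sites constant")
  m <- m[, keep, drop = FALSE]
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(p$x))
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       varianceExplained = ve[seq_len(k)], nSites = ncol(m))
}

#' Average-linkage dendrogram from a kinship matrix
#'
#' Hierarchical clustering of samples on the dissimilarity
#' `d(i, j) = 0.5 - phi(i, j)` (self-kinship maps to distance 0) with
#' average linkage. Sampling noise can push phi above 0.5; the resulting
#' negative distances are clipped to 0 with a warning. Ties in merge
#' heights are broken by `stats::hclust`'s deterministic (label-order)
#' behaviour.
#'
#' @param phi symmetric kinship matrix with sample dimnames (complete: no
#'   NA off-diagonal).
#' @return list with `hclust` (the tree) and `newick` (serialized string).
#' @export
kinshipDendrogram <- function(phi) {
  stopifnot(is.matrix(phi), nrow(phi) == ncol(phi))
  d <- 0.5 - phi
  diag(d) <- 0
  if (any(is.na(d))) stop("kinship matrix has undefined entries")
  if (any(d < 0)) {
    warning("negative distance(s) clipped to 0 (phi > 0.5)")
    d[d < 0] <- 0
  }
  hc <- hclust(as.dist(d), method = "average")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, newick = nwk)
}

#' Simulate unrelated diploid genotypes under Hardy-Weinberg equilibrium
#'
#' Independent individuals: per site an allele frequency is drawn uniformly
#' from `freqRange` and each individual's dosage is Binomial(2, p). Used to
#' calibrate the unrelated end of the kinship scale.
#'
#' @param nSites,nSamples dimensions.
#' @param freqRange allele-frequency range (default 0.05-0.95).
#' @param seed integer seed.
#' @return sites x samples integer dosage matrix.
#' @export
simulateHardyWeinberg <- function(nSites, nSamples, freqRange = c(0.05, 0.95),
                                  seed = 1) {
  set.seed(seed)
  p <- runif(nSites, freqRange[1], freqRange[2])
  m <- vapply(seq_len(nSamples), function(j) rbinom(nSites, 2, p),
              integer(nSites))
  colnames(m) <- sprintf("hw%02d", seq_len(nSamples))
  m
}

#' Simulate a parent-offspring dosage pair
#'
#' The offspring inherits one allele drawn from the parent's genotype and
#' one from the population (Binomial(1, p)); the expected KING-robust
#' kinship of the pair is 0.25.
#'
#' @inheritParams simulateHardyWeinberg
#' @return sites x 2 integer matrix (parent, offspring).
#' @export
simulateParentOffspring <- function(nSites, freqRange = c(0.05, 0.95),
                                    seed = 1) {
  set.seed(seed)
  p <- runif(nSites, freqRange[1], freqRange[2])
  parent <- rbinom(nSites, 2, p)
  fromParent <- rbinom(nSites, 1, parent / 2)
  fromPop <- rbinom(nSites, 1, p)
  cbind(parent = parent, offspring = fromParent + fromPop)
}
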