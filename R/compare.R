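## Thin delegations to standard group-comparison routines.

#' Compare value distributions between groups
#'
#' Delegates to the standard implementations: one-way ANOVA with Tukey's HSD
#' (all pairwise contrasts, with compact significance letters), the
#' two-sample Kolmogorov-Smirnov test, or the Mann-Whitney (Wilcoxon
#' rank-sum) test. The pairwise tests require exactly two groups.
#'
#' @param values numeric vector.
#' @param groups group labels, parallel to `values`.
#' @param test one of `"tukey"`, `"ks"`, `"mannwhitney"`.
#' @param alpha significance level for the Tukey letter grouping.
#' @return for `"tukey"`: list with `anova` p-value, `pairs` (the HSD
#'   table) and `letters` (groups sharing a letter are not significantly
#'   different); for the pairwise tests: list with `statistic` and
#'   `p.value`.
#' @export
compareGroups <- function(values, groups, test = c("tukey", "ks",
                                                   "mannwhitney"),
                          alpha = 0.05) {
  test <- match.arg(test)
  groups <- as.factor(as.character(groups))
  stopifnot(length(values) == length(groups))
  sizes <- table(groups)
  if (test == "tukey") {
    if (length(sizes) < 2 || any(sizes < 2))
      stop("Tukey HSD needs >= 2 groups with >= 2 values each")
    fit <- aov(values ~ groups)
    hsd <- TukeyHSD(fit)$groups
    pr <- summary(fit)[[1]]$`Pr(>F)`[1]
    p <- hsd[, "p adj"]
    pairNames <- strsplit(rownames(hsd), "-", fixed = TRUE)
    lt <- significanceLetters(levels(groups), pairNames, p, alpha)
    return(list(test = "tukey", anova.p = pr,
                pairs = data.frame(pair = rownames(hsd), hsd,
                                   row.names = NULL, check.names = FALSE),
                letters = lt))
  }
  if (length(sizes) != 2)
    stop("pairwise test needs exactly 2 groups")
  a <- values[groups == levels(groups)[1]]
  b <- values[groups == levels(groups)[2]]
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  ht <- if (test == "ks") suppressWarnings(ks.test(a, b))
        else suppressWarnings(wilcox.test(a, b))
  list(test = test, statistic = unname(ht$statistic),
       p.value = ht$p.value)
}

## compact letter display by insert-and-absorb over the non-significant
## pairs (groups sharing a letter are not significantly different)
significanceLetters <- function(groupNames, pairNames, p, alpha) {
  k <- length(groupNames)
  same <- diag(TRUE, k)
  dimnames(same) <- list(groupNames, groupNames)
  for (i in seq_along(p)) {
    g <- pairNames[[i]]
    if (p[i] > alpha) same[g[1], g[2]] <- same[g[2], g[1]] <- TRUE
  }
  sets <- list()
  for (g in groupNames) {
    friends <- groupNames[same[g, ]]
    placed <- FALSE
    for (j in seq_along(sets)) {
      if (all(sets[[j]] %in% friends) &&
          all(same[g, sets[[j]]])) {
        sets[[j]] <- c(sets[[j]], g); placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  ## absorb duplicated subsets
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets))
    if (i != j && keep[i] && keep[j] &&
        all(sets[[i]] %in% sets[[j]])) keep[i] <- FALSE
  sets <- sets[keep]
  out <- setNames(rep("", k), groupNames)
  for (j in seq_along(sets))
    for (g in sets[[j]]) out[g] <- paste0(out[g], letters[j])
  out
}
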