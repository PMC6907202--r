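test_that("constructed codon changes hit the canonical categories", {
  fx <- defaultSim()
  models <- readGeneModels(fx$genome@genes)
  ref <- fx$genome@sequence
  ## build a stop via TAC->TAA style third-position change: search for a
  ## codon whose single-base change introduces a stop on a plus-strand gene
  plus <- Filter(function(m) m$strand == "+", models)
  m <- plus[[1]]
  seqStr <- as.character(ref[[m$contig]])
  cds <- somaclone:::modelCdsSeq(m, ref)
  found <- NULL
  for (ci in seq(2, nchar(cds) / 3 - 1)) {
    codon <- substr(cds, ci * 3 - 2, ci * 3)
    for (off in 1:3) for (b in c("A", "G", "T")) {
      mut <- codon
      substr(mut, off, off) <- b
      if (mut != codon && mut %in% c("TAA", "TAG", "TGA") &&
          !codon %in% c("TAA", "TAG", "TGA")) {
        found <- list(ci = ci, off = off, b = b, codon = codon)
        break
      }
    }
    if (!is.null(found)) break
  }
  ## genomic position of that CDS base (plus strand: direct mapping)
  cdsPos <- (found$ci - 1) * 3 + found$off
  starts <- GenomicRanges::start(m$cds); ends <- GenomicRanges::end(m$cds)
  cum <- cumsum(c(0, ends - starts + 1))
  exI <- which(cdsPos > cum[-length(cum)] & cdsPos <= cum[-1])[1]
  gPos <- starts[exI] + (cdsPos - cum[exI]) - 1
  v <- data.frame(contig = m$contig, position = gPos,
                  ref = substr(seqStr, gPos, gPos), alt = found$b)
  eff <- classifyEffect(v, models, ref)
  expect_equal(eff$category, "stop_gained")
  expect_equal(eff$impact, "HIGH")

  ## 1 bp mid-CDS deletion = frameshift; 3 bp = inframe
  p <- starts[1] + 10
  fs <- data.frame(contig = m$contig, position = p,
                   ref = substr(seqStr, p, p + 1),
                   alt = substr(seqStr, p, p))
  expect_equal(classifyEffect(fs, models, ref)$category, "frameshift")
  inf <- data.frame(contig = m$contig, position = p,
                    ref = substr(seqStr, p, p + 3),
                    alt = substr(seqStr, p, p))
  got <- classifyEffect(inf, models, ref)$category
  expect_true(got %in% c("inframe_indel", "stop_gained"))

  ## SNV in the start codon
  sc <- if (m$strand == "+") starts[1] else ends[length(ends)]
  v2 <- data.frame(contig = m$contig, position = starts[1] + 1,
                   ref = substr(seqStr, starts[1] + 1, starts[1] + 1),
                   alt = "C") # ATG -> ACG
  expect_equal(classifyEffect(v2, models, ref)$category, "start_lost")
})

test_that("splice-site and exon-loss variants classify per definition on both strands", {
  fx <- defaultSim()
  models <- readGeneModels(fx$genome@genes)
  ref <- fx$genome@sequence
  for (m in models[1:4]) {
    seqStr <- as.character(ref[[m$contig]])
    ex <- m$exons
    intrS <- GenomicRanges::end(ex)[1] + 1
    intrE <- GenomicRanges::start(ex)[2] - 1
    donorPos <- if (m$strand == "+") intrS else intrE
    accPos <- if (m$strand == "+") intrE else intrS
    vd <- data.frame(contig = m$contig, position = donorPos,
                     ref = substr(seqStr, donorPos, donorPos), alt = "A")
    if (vd$ref == "A") vd$alt <- "C"
    expect_equal(classifyEffect(vd, models, ref)$category, "splice_donor")
    va <- data.frame(contig = m$contig, position = accPos,
                     ref = substr(seqStr, accPos, accPos), alt = "A")
    if (va$ref == "A") va$alt <- "C"
    expect_equal(classifyEffect(va, models, ref)$category,
                 "splice_acceptor")
    ## deletion covering the whole second exon
    dPos <- GenomicRanges::start(ex)[2] - 3
    dEnd <- GenomicRanges::end(ex)[2] + 2
    vx <- data.frame(contig = m$contig, position = dPos,
                     ref = substr(seqStr, dPos, dEnd),
                     alt = substr(seqStr, dPos, dPos))
    effx <- classifyEffect(vx, models, ref)
    expect_equal(effx$category, "exon_loss")
    expect_equal(effx$impact, "HIGH")
  }
})

test_that("a deletion across the CDS of two genes is a gene fusion", {
  fx <- defaultSim()
  models <- readGeneModels(fx$genome@genes)
  ref <- fx$genome@sequence
  ## two adjacent genes on ctg1
  onCtg <- Filter(function(m) m$contig == "ctg1", models)
  ord <- order(vapply(onCtg, function(m)
    min(GenomicRanges::start(m$cds)), numeric(1)))
  m1 <- onCtg[[ord[1]]]; m2 <- onCtg[[ord[2]]]
  seqStr <- as.character(ref[["ctg1"]])
  dPos <- max(GenomicRanges::end(m1$cds)) - 5
  dEnd <- min(GenomicRanges::start(m2$cds)) + 5
  v <- data.frame(contig = "ctg1", position = dPos,
                  ref = substr(seqStr, dPos, dEnd),
                  alt = substr(seqStr, dPos, dPos))
  eff <- classifyEffect(v, models, ref)
  expect_equal(eff$category, "gene_fusion")
  expect_equal(eff$impact, "HIGH")
})

test_that("classifier agrees with the translate-and-diff oracle on random CDS variants", {
  fx <- defaultSim()
  models <- readGeneModels(fx$genome@genes)
  ref <- fx$genome@sequence
  set.seed(41)
  nAgree <- 0L; nTot <- 0L
  for (rep in seq_len(260)) {
    m <- models[[sample(length(models), 1)]]
    seqStr <- as.character(ref[[m$contig]])
    v <- if (rep %% 2 == 0) randomCdsSnv(m, seqStr) else
      randomCdsIndel(m, seqStr)
    got <- classifyEffect(
      data.frame(contig = m$contig, position = v$pos, ref = v$ref,
                 alt = v$alt), models, ref)$category
    want <- oracleEffect(GenomicRanges::start(m$cds),
                         GenomicRanges::end(m$cds), m$strand, seqStr,
                         v$pos, v$ref, v$alt)
    nTot <- nTot + 1L
    if (identical(got, want)) nAgree <- nAgree + 1L else
      fail(sprintf("disagreement at %s:%d %s>%s (%s): got %s want %s",
                   m$contig, v$pos, v$ref, v$alt, m$strand, got, want))
  }
  expect_equal(nAgree, nTot)
  expect_gte(nTot, 250)
})

test_that("severity choice is deterministic under transcript reordering", {
  fx <- defaultSim()
  models <- readGeneModels(fx$genome@genes)
  ref <- fx$genome@sequence
  m <- models[[1]]
  seqStr <- as.character(ref[[m$contig]])
  p <- GenomicRanges::start(m$cds)[1] + 4
  v <- data.frame(contig = m$contig, position = p,
                  ref = substr(seqStr, p, p),
                  alt = setdiff(c("A", "C"), substr(seqStr, p, p))[1])
  e1 <- classifyEffect(v, models, ref)
  e2 <- classifyEffect(v, rev(models), ref)
  expect_equal(e1$category, e2$category)
  expect_equal(e1$gene_id, e2$gene_id)
})

test_that("reference mismatches are integrity errors; intergenic is MODIFIER", {
  fx <- defaultSim()
  models <- readGeneModels(fx$genome@genes)
  ref <- fx$genome@sequence
  seqStr <- as.character(ref[["ctg1"]])
  wrong <- setdiff(c("A", "C", "G", "T"), substr(seqStr, 500, 500))[1]
  expect_error(classifyEffect(
    data.frame(contig = "ctg1", position = 500, ref = wrong, alt = "A"),
    models, ref), "reference mismatch")
  ## position 1..3 of ctg1 should be intergenic in the default layout
  ig <- classifyEffect(
    data.frame(contig = "ctg1", position = 2,
               ref = substr(seqStr, 2, 2),
               alt = setdiff(c("A", "C"), substr(seqStr, 2, 2))[1]),
    models, ref)
  expect_equal(ig$category, "intergenic")
  expect_equal(ig$impact, "MODIFIER")
})

test_that("deleterious fractions by sharing follow the effect labels", {
  eff <- data.frame(
    impact = c("HIGH", "HIGH", "LOW", "MODERATE", "HIGH", "LOW"),
    N = c(1, 1, 1, 5, 5, 15))
  d <- deleteriousFractionBySharing(eff, nClones = 15)
  expect_equal(d$fraction[d$N == 1], 2 / 3)
  expect_equal(d$fraction[d$N == 5], 1 / 2)
  expect_equal(d$fraction[d$N == 15], 0)
  expect_false(2 %in% d$N) # zero-denominator bins reported absent
  ## all HIGH at N = 1 and probabilistic labels recover their rates
  set.seed(13)
  n <- 4000
  Ns <- sample(c(1, 15), n, replace = TRUE)
  pHigh <- ifelse(Ns == 1, 0.3, 0.05)
  sim <- data.frame(impact = ifelse(runif(n) < pHigh, "HIGH", "LOW"),
                    N = Ns)
  d2 <- deleteriousFractionBySharing(sim, nClones = 15)
  expect_lt(abs(d2$fraction[d2$N == 1] - 0.3),
            3 * sqrt(0.3 * 0.7 / sum(Ns == 1)))
  expect_lt(abs(d2$fraction[d2$N == 15] - 0.05),
            3 * sqrt(0.05 * 0.95 / sum(Ns == 15)))
})
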