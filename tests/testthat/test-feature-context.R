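makeToyAnnotation <- function() {
  ## contig of 1000 bp; gene 101-300 with exons 101-140 and 181-300;
  ## repeats 130-190 (overlaps the gene) and 401-500 (intergenic)
  contigLengths <- c(ctg = 1000L)
  genes <- GRanges("ctg", IRanges(c(101, 101, 101, 181),
                                  c(300, 300, 140, 300)))
  S4Vectors::mcols(genes)$type <- c("gene", "mRNA", "exon", "exon")
  S4Vectors::mcols(genes)$ID <- c("g1", "g1.t1", "e1", "e2")
  S4Vectors::mcols(genes)$Parent <- IRanges::CharacterList(
    list(character(0), "g1", "g1.t1", "g1.t1"))
  repeats <- GRanges("ctg", IRanges(c(130, 401), c(190, 500)))
  list(genes = genes, repeats = repeats, contigLengths = contigLengths)
}

test_that("feature index applies exon > intron > repeat precedence and hand-summed lengths", {
  toy <- makeToyAnnotation()
  idx <- buildFeatureIndex(toy$genes, toy$repeats, toy$contigLengths)
  cl <- featureClassLengths(idx)
  ## hand tiling: exon 40 + 120; intron 40; genic repeat portion subsumed;
  ## intergenic repeat only 401-500
  expect_equal(unname(cl[["exon"]]), 160)
  expect_equal(unname(cl[["intron"]]), 40)
  expect_equal(unname(cl[["intergenic-repeat"]]), 100)
  expect_equal(unname(cl[["intergenic-nonrepetitive"]]), 700)
  expect_equal(sum(cl), 1000)
  expect_equal(classifyPosition(idx, "ctg", 150), "intron")
  expect_equal(classifyPosition(idx, "ctg", 135), "exon")
  expect_equal(classifyPosition(idx, "ctg", 185), "exon")
  expect_equal(classifyPosition(idx, "ctg", 450), "intergenic-repeat")
  expect_equal(classifyPosition(idx, "ctg", 50),
               "intergenic-nonrepetitive")
  expect_error(classifyPosition(idx, "ctg", 1001), "out of range")
})

test_that("annotation beyond contig bounds is rejected by name", {
  toy <- makeToyAnnotation()
  bad <- c(toy$contigLengths, ctg = 1000L)[1]
  g2 <- c(toy$genes, GRanges("ctg", IRanges(990, 1100),
                             type = "gene", ID = "g2",
                             Parent = IRanges::CharacterList(list(
                               character(0)))))
  expect_error(buildFeatureIndex(g2, toy$repeats, toy$contigLengths),
               "beyond contig bounds")
  expect_error(buildFeatureIndex(toy$genes, toy$repeats, c(other = 500L)),
               "unknown contig")
})

test_that("random positions always get exactly one class, matching the truth table", {
  fx <- defaultSim()
  idx <- fx$genome@index
  tr <- fx$sim@truth[fx$sim@truth$vartype %in% c("SNV", "INDEL"), ]
  pos <- affectedPosition(tr$position, tr$ref_allele, tr$alt_allele)
  got <- classifyPosition(idx, tr$contig, pos)
  expect_equal(got, tr$feature_class)
  ## tiling: every sampled base classified, classes tile exactly
  set.seed(4)
  rnd <- sample.int(fx$cfg$contig_length, 500)
  cls <- classifyPosition(idx, "ctg1", rnd)
  expect_true(all(cls %in% c("exon", "intron", "intergenic-repeat",
                             "intergenic-nonrepetitive")))
})

test_that("normalized rates are count/bp*1000 and scale-equivariant", {
  toy <- makeToyAnnotation()
  idx <- buildFeatureIndex(toy$genes, toy$repeats, toy$contigLengths)
  counts <- data.frame(feature = c("exon", "intron", "intergenic-repeat"),
                       count = c(0L, 4L, 10L))
  r <- normalizedRates(counts, idx)
  expect_equal(r$ratePerKb, c(0, 4 / 40 * 1000, 10 / 100 * 1000))
  ## doubling counts and lengths leaves rates unchanged
  toy2 <- makeToyAnnotation()
  big <- c(ctg = 2000L)
  g2 <- toy2$genes
  ## same annotation twice: shift a copy by 1000
  shift <- GenomicRanges::shift(toy2$genes, 1000)
  rep2 <- c(toy2$repeats, GenomicRanges::shift(toy2$repeats, 1000))
  idx2 <- buildFeatureIndex(c(g2, shift), rep2, big)
  counts2 <- counts; counts2$count <- counts2$count * 2L
  r2 <- normalizedRates(counts2, idx2)
  expect_equal(r2$ratePerKb, r$ratePerKb)
  expect_error(normalizedRates(data.frame(feature = "exon", count = 1),
                               buildFeatureIndex(
                                 toy$genes[0], toy$repeats[0],
                                 toy$contigLengths)),
               "zero-length")
})

test_that("configured somatic rate ranking is recovered from the simulator", {
  fx <- defaultSim()
  vt <- fx$sim@variants
  idx <- fx$genome@index
  clones <- cloneLabels(fx$cfg)
  N <- sharingLevel(vt, clones)
  som <- vt[N > 0 & N < fx$cfg$n_clones, ]
  alts <- vapply(as.list(altAlleles(som)), `[[`, character(1), 1)
  feat <- classifyPosition(
    idx, as.character(seqnames(rowRanges(som))),
    affectedPosition(GenomicRanges::start(rowRanges(som)),
                     refAllele(som), alts))
  counts <- data.frame(feature = names(table(feat)),
                       count = as.integer(table(feat)))
  r <- normalizedRates(counts, idx)
  r$perCloneRate <- r$ratePerKb / fx$cfg$n_clones
  cfgRate <- fx$cfg$somatic_rate_by_feature * 1000
  expect_equal(order(cfgRate[r$feature]), order(r$perCloneRate))
})

test_that("TE gene distances agree with a brute-force scan over boundaries", {
  fx <- defaultSim()
  genes <- fx$genome@genes
  gdf <- data.frame(
    contig = as.character(seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    type = as.character(S4Vectors::mcols(genes)$type))
  gdf <- gdf[gdf$type == "gene", ]
  set.seed(7)
  te <- data.frame(contig = sample(c("ctg1", "ctg2"), 200, replace = TRUE),
                   position = sample.int(fx$cfg$contig_length, 200))
  nd <- nearestGeneDistances(te, genes)
  for (i in seq_len(nrow(te))) {
    expected <- oracleGeneDistances(te$contig[i], te$position[i], gdf)
    expect_equal(c(nd$distances$upstream[i], nd$distances$downstream[i]),
                 as.numeric(expected))
  }
  ## genic insertions are flagged with zero distance
  genic <- nd$distances$genic
  expect_true(all(nd$distances$nearest[genic] == 0))
  ## equidistant construction
  mid <- nearestGeneDistances(
    data.frame(contig = "c", position = 1500),
    GRanges("c", IRanges(c(500, 2000), c(1000, 2500))))
  expect_equal(mid$distances$upstream, 500)
  expect_equal(mid$distances$downstream, 500)
})

test_that("SV summaries report counts, medians, totals and gene overlaps per type", {
  genes <- GRanges("c", IRanges(c(1000, 5000), c(2000, 6000)),
                   type = c("gene", "gene"))
  sv <- data.frame(contig = "c",
                   start = c(500, 900, 5500, 100),
                   end = c(2500, 1100, 5600, 150),
                   type = c("deletion", "deletion", "duplication",
                            "insertion"),
                   length = c(2001L, 201L, 101L, 300L))
  s <- summarizeSVs(sv, genes, assemblyLength = 1e6)
  del <- s$summary[s$summary$type == "deletion", ]
  expect_equal(del$count, 2L)
  expect_equal(del$medianSize, (2001 + 201) / 2)
  expect_equal(del$totalBp, 2202)
  expect_equal(del$pctAssembly, 100 * 2202 / 1e6)
  expect_equal(del$genes, 1L)      # both deletions hit only gene 1
  dup <- s$summary[s$summary$type == "duplication", ]
  expect_equal(dup$genes, 1L)
  ins <- s$summary[s$summary$type == "insertion", ]
  expect_equal(ins$pctAssembly, 100 * 300 / 1e6)
  ## single 2 kb deletion on a 1 Mb assembly = 0.2%
  one <- summarizeSVs(data.frame(contig = "c", start = 100, end = 2099,
                                 type = "deletion", length = 2000L),
                      genes, assemblyLength = 1e6)
  expect_equal(one$summary$pctAssembly[one$summary$type == "deletion"],
               0.2)
  ## a deletion spanning both genes counts 2 distinct genes
  two <- summarizeSVs(data.frame(contig = "c", start = 900, end = 5500,
                                 type = "deletion", length = 4601L),
                      genes, assemblyLength = 1e6)
  expect_equal(two$summary$genes[two$summary$type == "deletion"], 2L)
  ## simulator truth cross-check
  fx <- defaultSim()
  s2 <- summarizeSVs(fx$sim@sv, fx$genome@genes,
                     assemblyLength = sum(featureClassLengths(
                       fx$genome@index)))
  for (ty in unique(fx$sim@sv$type)) {
    d <- fx$sim@sv[fx$sim@sv$type == ty, ]
    row <- s2$summary[s2$summary$type == ty, ]
    expect_equal(row$count, nrow(d))
    expect_equal(row$medianSize, median(d$length))
    expect_equal(row$totalBp, sum(d$length))
  }
})

test_that("repeat-intersecting SVs can be excluded before summarization", {
  reps <- GRanges("c", IRanges(1000, 1500))
  genes <- GRanges("c", IRanges(5000, 6000), type = "gene")
  sv <- data.frame(contig = "c", start = c(900, 3000),
                   end = c(1100, 3200),
                   type = "deletion", length = c(201L, 201L))
  kept <- summarizeSVs(sv, genes, 1e6, dropRepeatOverlap = reps)
  expect_equal(kept$summary$count[kept$summary$type == "deletion"], 1L)
})
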