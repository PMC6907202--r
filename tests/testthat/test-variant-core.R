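test_that("VCF round trip is lossless for genotypes, alleles and metrics", {
  fx <- defaultSim()
  d <- withr::local_tempdir()
  p <- writeFixture(fx$sim, d)
  vt <- readVariantTable(p[["variants"]])
  v0 <- fx$sim@variants
  expect_equal(nrow(vt), nrow(v0))
  expect_equal(colnames(vt), colnames(v0))
  expect_equal(unname(genotypes(vt)), unname(genotypes(v0)))
  expect_equal(refAllele(vt), refAllele(v0))
  expect_equal(as.list(altAlleles(vt)), as.list(altAlleles(v0)))
  expect_equal(GenomicRanges::start(rowRanges(vt)),
               GenomicRanges::start(rowRanges(v0)))
  expect_equal(as.data.frame(variantMetrics(vt)),
               as.data.frame(variantMetrics(v0)), tolerance = 1e-6)
})

test_that("genotype string predicates follow VCF GT semantics", {
  gts <- c("0/0", "0/1", "1/0", "1/1", "./.", "1|0", "1/2", "2/2", "0/2")
  expect_equal(gtIsMissing(gts),
               c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                 FALSE))
  expect_equal(gtIsHet(gts),
               c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(gtIsHomAlt(gts),
               c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE,
                 FALSE))
  expect_equal(gtCarriesAltHet(gts, 1),
               c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE,
                 FALSE))
  expect_equal(gtCarriesAltHet(gts, 2),
               c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                 TRUE))
  expect_equal(gtDosage(gts), c(0L, 1L, 1L, 2L, NA, 1L, 1L, 0L, 0L))
})

test_that("hand-constructed records fail exactly the hand-derived rules", {
  ## ten records engineered against the default thresholds
  met <- data.frame(
    DP = c(10, 25, 3, 10, 10, 10, 10, 10, 10, 30),
    QD = c(5, 5, 5, 5, 1.5, 5, 5, 5, 5, 1.0),
    FS = c(10, 10, 10, 10, 10, 75, 10, 10, 10, 10),
    MQ = c(60, 60, 60, 60, 60, 60, 30, 60, 60, 60),
    MQRankSum = c(0, 0, 0, 0, 0, 0, 0, -13, 0, 0),
    ReadPosRankSum = c(0, 0, 0, 0, 0, 0, 0, 0, -9, 0))
  qual <- c(50, 50, 50, 15, 50, 50, 50, 50, 50, 50)
  gt <- matrix("0/1", nrow = 10, ncol = 2,
               dimnames = list(NULL, c("s1", "s2")))
  vt <- applyHardFilters(handTable(gt, metrics = met, qual = qual))
  expect_equal(filterStatus(vt),
               c("PASS", "DP>20", "DP<5", "QUAL<20", "QD<2", "FS>60",
                 "MQ<40", "MQRankSum<-12.5", "ReadPosRankSum<-8",
                 "DP>20;QD<2"))
})

test_that("absent metrics leave rules unevaluated with a warning for vacuous PASS", {
  gt <- matrix("0/1", nrow = 2, ncol = 1, dimnames = list(NULL, "s1"))
  vt <- handTable(gt, qual = c(NA, NA))
  expect_warning(
    suppressMessages(out <- applyHardFilters(vt)),
    "vacuously")
  expect_equal(filterStatus(out), c("PASS", "PASS"))
})

test_that("tightening a threshold never increases the PASS count", {
  fx <- defaultSim()
  cfg <- cloneSimConfig(seed = 2, fail_metric_fraction = 0.3)
  sim <- simulateCloneVariants(cfg, fx$genome)
  base <- filterConfig()
  loose <- suppressMessages(applyHardFilters(sim@variants, base))
  for (thr in c(30, 22, 15, 10)) {
    tight <- base
    tight$threshold[tight$name == "QD<2"] <- thr
    tight$name[tight$name == "QD<2"] <- paste0("QD<", thr)
    out <- suppressMessages(applyHardFilters(sim@variants,
                                             filterConfig(tight)))
    expect_lte(sum(filterStatus(out) == "PASS"),
               sum(filterStatus(loose) == "PASS"))
  }
})

test_that("reference-sample sanitation removes exactly the spiked records", {
  cfg <- cloneSimConfig(seed = 21, n_clones = 5L, n_genes = 4L,
                        n_contigs = 1L, contig_length = 15000L,
                        ancestral_het_rate = 0.004,
                        artifact_homalt_rate = 0.08,
                        artifact_samples = "REF", reference_sample = "REF",
                        n_te_ancestral = 0L, n_te_private = 0L,
                        n_sv_ancestral = 0L, n_sv_private = 0L)
  sim <- simulateCloneVariants(cfg, simulateReference(cfg))
  spiked <- sim@truth$artifact_in != ""
  out <- suppressMessages(dropReferenceNonref(sim@variants, "REF"))
  expect_equal(nrow(out), sum(!spiked))
  expect_equal(attr(out, "removedFraction"), mean(spiked))
  ## no-op when the reference sample is clean everywhere
  clean <- sim@variants[!spiked, ]
  expect_equal(nrow(suppressMessages(dropReferenceNonref(clean, "REF"))),
               nrow(clean))
  expect_error(dropReferenceNonref(sim@variants, "nope"), "unknown sample")
})

test_that("complete-call restriction drops rows with any missing genotype", {
  gt <- rbind(c("0/1", "0/1", "0/0"),
              c("0/1", "./.", "0/0"),
              c("0/0", "0/1", "0/1"))
  colnames(gt) <- c("a", "b", "c")
  vt <- handTable(gt)
  out <- completeCallSites(vt)
  expect_equal(nrow(out), 2)
  expect_equal(GenomicRanges::start(rowRanges(out)), c(100, 300))
})

test_that("sanitation predicates commute", {
  cfg <- cloneSimConfig(seed = 33, n_clones = 4L, n_genes = 4L,
                        n_contigs = 1L, contig_length = 15000L,
                        ancestral_het_rate = 0.004,
                        artifact_homalt_rate = 0.05,
                        reference_sample = "REF",
                        n_te_ancestral = 0L, n_te_private = 0L,
                        n_sv_ancestral = 0L, n_sv_private = 0L)
  sim <- simulateCloneVariants(cfg, simulateReference(cfg))
  ## add some missingness deterministically
  vt <- sim@variants
  gt <- genotypes(vt)
  gt[seq(1, nrow(gt), by = 7), 2] <- "./."
  vt2 <- handTable(gt, ref = refAllele(vt),
                   alt = vapply(as.list(altAlleles(vt)), `[[`,
                                character(1), 1),
                   position = GenomicRanges::start(rowRanges(vt)))
  a <- suppressMessages(completeCallSites(dropReferenceNonref(vt2, "REF")))
  b <- suppressMessages(dropReferenceNonref(completeCallSites(vt2), "REF"))
  expect_equal(GenomicRanges::start(rowRanges(a)),
               GenomicRanges::start(rowRanges(b)))
  expect_equal(unname(genotypes(a)), unname(genotypes(b)))
})

test_that("variant types are classified per alternate allele", {
  expect_equal(classifyVariantType("C", "T"), "SNV")
  expect_equal(classifyVariantType("CA", "C"), "INDEL")
  expect_equal(classifyVariantType("C", c("T", "CAA")),
               c("SNV", "INDEL"))
  expect_equal(classifyVariantType("C", "<DEL>"), "SV")
})

test_that("concordance partition matches spec example and brute force", {
  sets <- list(A = c("s1", "s2", "s3"), B = c("s2", "s3", "s4"),
               C = c("s3", "s4", "s5"))
  cc <- callSetConcordance(sets)
  all3 <- cc$partition$count[cc$partition$A & cc$partition$B &
                               cc$partition$C]
  expect_equal(all3, 1L)
  expect_equal(cc$perSet$unique[cc$perSet$set == "A"], 1L)
  expect_equal(cc$nUnion, 5L)
  expect_equal(sum(cc$partition$count), cc$nUnion)
  ## identical sets collapse to a single all-shared cell
  ident <- callSetConcordance(list(A = sets$A, B = sets$A, C = sets$A))
  expect_equal(sum(ident$partition$count), length(sets$A))
  expect_true(all(ident$perSet$unique == 0))
  ## randomized fixture vs brute-force enumeration
  set.seed(99)
  rs <- lapply(1:3, function(i) sample(paste0("v", 1:1000), 600))
  names(rs) <- c("A", "B", "C")
  cc2 <- callSetConcordance(rs)
  ov <- oracleVenn(rs)
  got <- setNames(cc2$partition$count,
                  apply(cc2$partition[, 1:3], 1, function(r)
                    paste(as.integer(r), collapse = "")))
  expect_mapequal(as.list(got), lapply(ov, as.integer))
  expect_equal(sum(cc2$partition$count), length(unique(unlist(rs))))
})
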