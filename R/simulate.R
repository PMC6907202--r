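## Forward simulator: an annotated diploid genome and a star pedigree of
## clones accumulating somatic mutations.

#' Simulation configuration
#'
#' Parameters of the synthetic clone-genome study. The defaults describe the
#' study conditions the package's analyses assume: a ~50 kb two-contig
#' genome at 34.5% GC (grapevine-like), UTR-less multi-exon genes, repeats
#' confined to intergenic space and covering 40% of it, a panel of 15 clones
#' descending as a star pedigree from one heterozygous mother, ancestral
#' heterozygosity at 2 sites/kb, somatic per-clone rates ranked
#' intergenic-repeat (2/kb) > intron (1/kb) > non-repetitive intergenic
#' (0.5/kb) > exon (0.2/kb), and a transition probability of 2/3 in repeats
#' versus 1/3 elsewhere (methylation-driven deamination raises transitions
#' where repeats are methylated).
#'
#' @param seed integer; every simulation stream derives from it, and an
#'   identical configuration reproduces byte-identical outputs.
#' @param n_contigs,contig_length genome layout (all contigs equal length).
#' @param gc_content fraction of G+C in the random background sequence.
#' @param n_genes,exons_per_gene,exon_length_mean,intron_length_mean gene
#'   architecture; CDS = exons (no UTRs), forced to start with ATG, end with
#'   a stop codon and contain no internal stop.
#' @param intergenic_repeat_fraction fraction of each intergenic gap covered
#'   by a repeat interval.
#' @param n_clones panel size (>= 2).
#' @param ancestral_het_rate heterozygous sites per bp inherited by all
#'   clones.
#' @param somatic_rate_by_feature named per-bp per-clone rates for the four
#'   feature classes.
#' @param transition_prob_by_stratum per feature class, a length-2 vector
#'   `c(context = p, other = p)`: the probability a simulated SNV is a
#'   transition at cytosine-context sites vs all other sites.
#' @param indel_fraction fraction of small variants that are INDELs
#'   (geometric lengths 1-10 bp, insertion/deletion equiprobable).
#' @param artifact_homalt_rate per-record per-sample probability of spiking
#'   an erroneous homozygous-alt genotype (labeled in truth).
#' @param artifact_samples samples eligible for artifact spikes (`NULL` =
#'   all samples, including the reference sample when present).
#' @param reference_sample optional label of an extra sample representing
#'   the assembly resequenced against itself: homozygous-reference
#'   everywhere except artifact spikes.
#' @param n_te_ancestral,n_te_private TE insertions shared by all clones /
#'   private to single clones.
#' @param n_sv_ancestral,n_sv_private structural variants likewise.
#' @param subclade_spec optional list of subclades, each
#'   `list(clones = c(...), n_events = k)`: somatic events shared by
#'   descent within the subclade.
#' @param fail_metric_fraction fraction of variant records given a failing
#'   caller metric (to exercise hard filters); labeled in truth.
#' @return validated configuration list (class `"cloneSimConfig"`).
#' @export
cloneSimConfig <- function(seed,
    n_contigs = 2L, contig_length = 25000L, gc_content = 0.345,
    n_genes = 12L, exons_per_gene = 4L, exon_length_mean = 250,
    intron_length_mean = 300, intergenic_repeat_fraction = 0.4,
    n_clones = 15L, ancestral_het_rate = 0.002,
    somatic_rate_by_feature = c(exon = 0.0002, intron = 0.001,
                                `intergenic-repeat` = 0.002,
                                `intergenic-nonrepetitive` = 0.0005),
    transition_prob_by_stratum = list(
      exon = c(context = 1/3, other = 1/3),
      intron = c(context = 1/3, other = 1/3),
      `intergenic-repeat` = c(context = 2/3, other = 2/3),
      `intergenic-nonrepetitive` = c(context = 1/3, other = 1/3)),
    indel_fraction = 0.15, artifact_homalt_rate = 0,
    artifact_samples = NULL, reference_sample = NULL,
    n_te_ancestral = 40L, n_te_private = 10L,
    n_sv_ancestral = 12L, n_sv_private = 4L,
    subclade_spec = NULL, fail_metric_fraction = 0) {
  stopifnot(length(seed) == 1, is.finite(seed),
            n_clones >= 2, n_contigs >= 1, contig_length >= 1000,
            gc_content >= 0, gc_content <= 1,
            intergenic_repeat_fraction >= 0,
            intergenic_repeat_fraction <= 1,
            ancestral_het_rate >= 0,
            all(somatic_rate_by_feature >= 0),
            all(FEATURE_CLASSES %in% names(somatic_rate_by_feature)),
            all(FEATURE_CLASSES %in% names(transition_prob_by_stratum)),
            indel_fraction >= 0, indel_fraction <= 1,
            artifact_homalt_rate >= 0, artifact_homalt_rate <= 1,
            fail_metric_fraction >= 0, fail_metric_fraction <= 1)
  cfg <- as.list(environment())
  for (p in transition_prob_by_stratum)
    stopifnot(all(p >= 0), all(p <= 1),
              all(c("context", "other") %in% names(p)))
  if (!is.null(subclade_spec))
    for (e in subclade_spec)
      stopifnot(is.list(e), length(e$clones) >= 2, e$n_events >= 0)
  cfg$seed <- as.integer(seed)
  class(cfg) <- c("cloneSimConfig", "list")
  cfg
}

#' @describeIn cloneSimConfig the clone sample labels of a configuration
#' @param config a `cloneSimConfig`
#' @export
cloneLabels <- function(config) sprintf("clone%02d", seq_len(config$n_clones))

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- base::setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  STOP_CODONS)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Simulate an annotated reference genome
#'
#' Random background sequence at the configured GC content, multi-exon
#' UTR-less genes laid out with intergenic gaps, well-formed CDS (length
#' divisible by 3, ATG start, stop-codon end, no internal stop on the coding
#' strand, both strands used), and repeat intervals confined to intergenic
#' space. Every base of every contig belongs to exactly one feature class.
#'
#' @param config a [cloneSimConfig()].
#' @return a [CloneGenome-class].
#' @export
simulateReference <- function(config) {
  stopifnot(inherits(config, "cloneSimConfig"))
  set.seed(config$seed)
  contigs <- sprintf("ctg%d", seq_len(config$n_contigs))
  contigLengths <- setNames(rep(as.integer(config$contig_length),
                                config$n_contigs), contigs)
  minGap <- 200L

  ## gene structures (exon/intron lengths; CDS length forced to 3k)
  geneStruct <- lapply(seq_len(config$n_genes), function(g) {
    k <- config$exons_per_gene
    ex <- pmax(30L, round(rnorm(k, config$exon_length_mean,
                                config$exon_length_mean / 5)))
    ex[k] <- ex[k] - sum(ex) %% 3L
    intr <- if (k > 1)
      pmax(50L, round(rnorm(k - 1, config$intron_length_mean,
                            config$intron_length_mean / 5)))
      else integer(0)
    list(exons = as.integer(ex), introns = as.integer(intr),
         len = as.integer(sum(ex) + sum(intr)))
  })
  geneContig <- rep(contigs, length.out = config$n_genes)

  gffRows <- list()
  gapRanges <- list()
  for (ctg in contigs) {
    idx <- which(geneContig == ctg)
    lens <- vapply(geneStruct[idx], `[[`, integer(1), "len")
    nGaps <- length(idx) + 1L
    free <- contigLengths[[ctg]] - sum(lens) - nGaps * minGap
    if (free < 0)
      stop("infeasible layout: requested gene content exceeds contig ",
           ctg, " length (need ", sum(lens) + nGaps * minGap, " bp, have ",
           contigLengths[[ctg]], ")")
    extra <- if (nGaps > 0 && free > 0)
      as.integer(rmultinom(1, free, rep(1, nGaps))) else rep(0L, nGaps)
    gaps <- minGap + extra
    cur <- 0L
    for (j in seq_along(idx)) {
      cur <- cur + gaps[j]
      g <- geneStruct[[idx[j]]]
      gStart <- cur + 1L
      ## exon coordinates in genomic order
      exS <- integer(0); exE <- integer(0); p <- gStart
      for (e in seq_along(g$exons)) {
        exS <- c(exS, p); exE <- c(exE, p + g$exons[e] - 1L)
        p <- p + g$exons[e]
        if (e <= length(g$introns)) p <- p + g$introns[e]
      }
      gEnd <- p - 1L
      strand <- sample(c("+", "-"), 1)
      gid <- sprintf("gene%03d", idx[j])
      tid <- paste0(gid, ".t1")
      gffRows[[length(gffRows) + 1]] <- data.frame(
        contig = ctg, start = c(gStart, gStart, exS, exS),
        end = c(gEnd, gEnd, exE, exE),
        type = c("gene", "mRNA", rep("exon", length(exS)),
                 rep("CDS", length(exS))),
        strand = strand,
        ID = c(gid, tid, paste0(tid, ".exon", seq_along(exS)),
               paste0(tid, ".cds", seq_along(exS))),
        Parent = c(NA, gid, rep(tid, 2 * length(exS))),
        stringsAsFactors = FALSE)
      cur <- gEnd
    }
    ## intergenic gaps (for repeat placement)
    geneRows <- do.call(rbind, gffRows)
    gOnCtg <- geneRows[geneRows$type == "gene" & geneRows$contig == ctg, ]
    bounds <- sort(c(0L, gOnCtg$start, gOnCtg$end,
                     contigLengths[[ctg]] + 1L))
    starts <- bounds[seq(1, length(bounds), 2)] + 1L
    ends <- bounds[seq(2, length(bounds), 2)] - 1L
    keep <- ends >= starts
    gapRanges[[ctg]] <- data.frame(contig = ctg, start = starts[keep],
                                   end = ends[keep])
  }
  gff <- do.call(rbind, gffRows)

  ## repeats: one interval per intergenic gap covering the configured
  ## fraction of it, at a random offset
  repRows <- list()
  if (config$intergenic_repeat_fraction > 0) {
    for (gap in do.call(rbind, gapRanges) |> split(seq_len(sum(
      vapply(gapRanges, nrow, integer(1)))))) {
      L <- gap$end - gap$start + 1L
      cov <- as.integer(round(config$intergenic_repeat_fraction * L))
      if (L < 20L || cov < 1L) next
      off <- sample.int(L - cov + 1L, 1) - 1L
      repRows[[length(repRows) + 1]] <- data.frame(
        contig = gap$contig, start = gap$start + off,
        end = gap$start + off + cov - 1L)
    }
  }
  repeats <- if (length(repRows) > 0) {
    rr <- do.call(rbind, repRows)
    GRanges(rr$contig, IRanges(rr$start, rr$end))
  } else GRanges()

  ## background sequence
  baseProb <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
                G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  seqChars <- lapply(contigs, function(ctg)
    sample(names(baseProb), contigLengths[[ctg]], replace = TRUE,
           prob = baseProb))
  names(seqChars) <- contigs

  ## make every CDS well-formed on its coding strand
  cdsRows <- gff[gff$type == "CDS", ]
  for (tid in unique(cdsRows$Parent)) {
    cc <- cdsRows[cdsRows$Parent == tid, ]
    cc <- cc[order(cc$start), ]
    ctg <- cc$contig[1]; strand <- cc$strand[1]
    posList <- unlist(lapply(seq_len(nrow(cc)), function(i)
      seq(cc$start[i], cc$end[i])))
    coding <- seqChars[[ctg]][posList]
    if (strand == "-") coding <- unname(COMPLEMENT[rev(coding)])
    nc <- length(coding) / 3
    codons <- vapply(seq_len(nc), function(i)
      paste(coding[(3 * i - 2):(3 * i)], collapse = ""), character(1))
    codons[1] <- "ATG"
    codons[nc] <- sample(STOP_CODONS, 1)
    internal <- which(codons[-c(1, nc)] %in% STOP_CODONS) + 1L
    if (length(internal) > 0)
      codons[internal] <- sample(SENSE_CODONS, length(internal),
                                 replace = TRUE)
    coding <- unlist(strsplit(codons, ""))
    if (strand == "-") coding <- unname(COMPLEMENT[rev(coding)])
    seqChars[[ctg]][posList] <- coding
  }
  sequence <- DNAStringSet(vapply(seqChars, paste, character(1),
                                  collapse = ""))

  ## GFF3-layout GRanges
  genes <- GRanges(gff$contig, IRanges(gff$start, gff$end),
                   strand = gff$strand)
  mcols(genes)$source <- "somaclone-sim"
  mcols(genes)$type <- gff$type
  mcols(genes)$ID <- gff$ID
  mcols(genes)$Parent <- IRanges::CharacterList(
    lapply(gff$Parent, function(p) if (is.na(p)) character(0) else p))
  phase <- rep(NA_integer_, nrow(gff))
  for (tid in unique(cdsRows$Parent)) {
    sel <- which(gff$type == "CDS" & !is.na(gff$Parent) &
                   gff$Parent == tid)
    sel <- sel[order(gff$start[sel])]
    if (gff$strand[sel[1]] == "-") sel <- rev(sel)
    w <- gff$end[sel] - gff$start[sel] + 1L
    phase[sel] <- as.integer((3L - cumsum(c(0L, w))[seq_along(w)] %% 3L)
                             %% 3L)
  }
  mcols(genes)$phase <- phase
  GenomeInfoDb::seqlevels(genes) <- contigs
  GenomeInfoDb::seqlengths(genes) <- contigLengths
  if (length(repeats) > 0) {
    GenomeInfoDb::seqlevels(repeats) <- contigs
    GenomeInfoDb::seqlengths(repeats) <- contigLengths
  }

  index <- buildFeatureIndex(genes, repeats, contigLengths)
  new("CloneGenome", sequence = sequence, genes = genes, repeats = repeats,
      index = index, config = unclass(config))
}

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulate clone variants over a reference
#'
#' Places ancestral heterozygous sites (all clones 0/1), per-clone somatic
#' mutations at the configured per-feature rates (star pedigree: each event
#' private to one clone unless assigned to a configured subclade), TE
#' insertions and structural variants, with SNV transition/transversion
#' identity drawn per feature-and-context stratum. Optionally spikes
#' artifactual homozygous-alt genotypes and failing caller metrics, both
#' labeled in the truth table.
#'
#' @param config a [cloneSimConfig()].
#' @param genome the matching [simulateReference()] output.
#' @return a [CloneSimulation-class].
#' @export
simulateCloneVariants <- function(config, genome) {
  stopifnot(inherits(config, "cloneSimConfig"), is(genome, "CloneGenome"))
  set.seed(config$seed + 1L)
  clones <- cloneLabels(config)
  samples <- c(config$reference_sample, clones)
  index <- genome@index
  contigLengths <- index@contigLengths
  seqChars <- lapply(names(contigLengths), function(ctg)
    strsplit(as.character(genome@sequence[[ctg]]), "")[[1]])
  names(seqChars) <- names(contigLengths)
  occupied <- lapply(contigLengths, function(L) logical(L))

  ## per-class position pools
  tiles <- index@tiles
  classPool <- lapply(FEATURE_CLASSES, function(f) {
    t2 <- tiles[mcols(tiles)$featureClass == f]
    data.frame(contig = rep(as.character(seqnames(t2)), width(t2)),
               pos = unlist(lapply(seq_along(t2), function(i)
                 seq(start(t2)[i], end(t2)[i]))))
  })
  names(classPool) <- FEATURE_CLASSES
  allPool <- do.call(rbind, classPool)

  recs <- list()
  addVariant <- function(contig, pos, origin, carriers, featureClass) {
    ## returns TRUE if the event was placed
    isIndel <- runif(1) < config$indel_fraction
    occ <- occupied[[contig]]
    L <- contigLengths[[contig]]
    if (!isIndel) {
      refBase <- seqChars[[contig]][pos]
      if (occ[pos] || !refBase %in% c("A", "C", "G", "T")) return(FALSE)
      ctx <- cytosineContext(genome@sequence, contig, pos)
      stratum <- if (ctx %in% c("CpG", "CHG", "CHH")) "context" else "other"
      pTr <- config$transition_prob_by_stratum[[featureClass]][[stratum]]
      isTr <- runif(1) < pTr
      altBase <- if (isTr) TRANSITION_PARTNER[[refBase]] else
        sample(base::setdiff(c("A", "C", "G", "T"),
                             c(refBase, TRANSITION_PARTNER[[refBase]])), 1)
      occupied[[contig]][pos] <<- TRUE
      recs[[length(recs) + 1]] <<- list(
        contig = contig, position = pos, ref = refBase, alt = altBase,
        vartype = "SNV", carriers = carriers, origin = origin,
        feature = featureClass, context = ctx, isTransition = isTr)
      return(TRUE)
    }
    len <- min(rgeom(1, 0.5) + 1L, 10L)
    isDel <- runif(1) < 0.5
    if (isDel) {
      if (pos < 2L || pos + len - 1L > L) return(FALSE)
      span <- (pos - 1L):(pos + len - 1L)
      if (any(occ[span])) return(FALSE)
      ref <- paste(seqChars[[contig]][span], collapse = "")
      alt <- seqChars[[contig]][pos - 1L]
      if (grepl("N", ref)) return(FALSE)
      occupied[[contig]][span] <<- TRUE
      recPos <- pos - 1L
    } else {
      if (occ[pos]) return(FALSE)
      ref <- seqChars[[contig]][pos]
      if (!ref %in% c("A", "C", "G", "T")) return(FALSE)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = ""))
      occupied[[contig]][pos] <<- TRUE
      recPos <- pos
    }
    recs[[length(recs) + 1]] <<- list(
      contig = contig, position = recPos, ref = ref, alt = alt,
      vartype = "INDEL", carriers = carriers, origin = origin,
      feature = featureClass, context = "NA", isTransition = NA)
    TRUE
  }

  placeEvents <- function(n, pool, origin, carriersFor, featureOf = NULL) {
    placed <- 0L; tries <- 0L
    while (placed < n && tries < 50L * n + 100L) {
      tries <- tries + 1L
      i <- sample.int(nrow(pool), 1)
      feat <- if (is.null(featureOf))
        classifyPosition(index, pool$contig[i], pool$pos[i]) else featureOf
      if (addVariant(pool$contig[i], pool$pos[i], origin, carriersFor(),
                     feat))
        placed <- placed + 1L
    }
    placed
  }

  ## ancestral heterozygosity: all clones 0/1
  nAnc <- rbinom(1, sum(contigLengths), config$ancestral_het_rate)
  placeEvents(nAnc, allPool, "ancestral", function() clones)

  ## somatic: per clone x feature class, star pedigree
  rates <- config$somatic_rate_by_feature
  for (cl in clones) {
    for (f in FEATURE_CLASSES) {
      bp <- nrow(classPool[[f]])
      if (bp == 0) {
        if (rates[[f]] > 0)
          warning("no mutable bases in class ", f, "; class skipped")
        next
      }
      nEv <- rbinom(1, bp, rates[[f]])
      if (nEv > 0)
        placeEvents(nEv, classPool[[f]], "somatic", function() cl,
                    featureOf = f)
    }
  }

  ## subclade-shared somatic events (descent within the subclade)
  if (!is.null(config$subclade_spec)) {
    classW <- vapply(FEATURE_CLASSES, function(f)
      nrow(classPool[[f]]) * rates[[f]], numeric(1))
    for (e in config$subclade_spec) {
      stopifnot(all(e$clones %in% clones))
      for (k in seq_len(e$n_events)) {
        f <- sample(FEATURE_CLASSES, 1, prob = classW)
        placeEvents(1L, classPool[[f]], "somatic", function() e$clones,
                    featureOf = f)
      }
    }
  }

  n <- length(recs)
  getf <- function(k) vapply(recs, `[[`, character(1), k)
  contig <- getf("contig")
  position <- vapply(recs, `[[`, numeric(1), "position")
  ord <- order(match(contig, names(contigLengths)), position)
  recs <- recs[ord]
  contig <- contig[ord]; position <- position[ord]

  gt <- matrix("0/0", nrow = n, ncol = length(samples),
               dimnames = list(NULL, samples))
  for (i in seq_len(n))
    gt[i, recs[[i]]$carriers] <- "0/1"

  ## artifact homozygous-alt spikes
  artifactIn <- rep("", n)
  if (config$artifact_homalt_rate > 0) {
    targets <- if (is.null(config$artifact_samples)) samples else
      config$artifact_samples
    for (i in seq_len(n)) {
      hitS <- targets[runif(length(targets)) < config$artifact_homalt_rate]
      if (length(hitS) > 0) {
        gt[i, hitS] <- "1/1"
        artifactIn[i] <- paste(hitS, collapse = ",")
      }
    }
  }

  ## caller metrics: passing values, with a configured failing fraction
  metrics <- data.frame(DP = rep(12L, n), QD = 25, FS = 3, MQ = 60,
                        MQRankSum = 0.2, ReadPosRankSum = -0.3)
  qual <- rep(800, n)
  filterOk <- rep(TRUE, n)
  if (config$fail_metric_fraction > 0 && n > 0) {
    nBad <- rbinom(1, n, config$fail_metric_fraction)
    bad <- sample.int(n, nBad)
    for (i in bad) {
      rule <- sample(c("DP_high", "DP_low", "QUAL", "QD", "FS", "MQ",
                       "MQRS", "RPRS"), 1)
      switch(rule,
        DP_high = { metrics$DP[i] <- 60L },
        DP_low = { metrics$DP[i] <- 3L },
        QUAL = { qual[i] <- 10 },
        QD = { metrics$QD[i] <- 1.0 },
        FS = { metrics$FS[i] <- 80 },
        MQ = { metrics$MQ[i] <- 25 },
        MQRS = { metrics$MQRankSum[i] <- -14 },
        RPRS = { metrics$ReadPosRankSum[i] <- -9 })
      filterOk[i] <- FALSE
    }
  }

  vt <- makeVariantTable(
    contig = contig, position = position,
    ref = getf2(recs, "ref"), alt = getf2(recs, "alt"),
    genotypes = gt, qual = qual, metrics = metrics,
    contigLengths = contigLengths)

  truth <- data.frame(
    variant_id = sprintf("var%05d", seq_len(n)),
    contig = contig, position = as.integer(position),
    ref_allele = getf2(recs, "ref"), alt_allele = getf2(recs, "alt"),
    vartype = getf2(recs, "vartype"),
    carriers = vapply(recs, function(r) paste(r$carriers, collapse = ","),
                      character(1)),
    origin = getf2(recs, "origin"),
    feature_class = getf2(recs, "feature"),
    cytosine_context = getf2(recs, "context"),
    is_transition = vapply(recs, function(r)
      if (is.na(r$isTransition)) NA else r$isTransition, logical(1)),
    effect_label = NA_character_,
    artifact_in = artifactIn,
    filter_ok = filterOk,
    stringsAsFactors = FALSE)

  ## TE insertions
  te <- simulateTeTable(config, index, clones)
  sv <- simulateSvTable(config, contigLengths, clones)
  truth <- rbind(truth, teSvTruth(te, sv, index, nrow(truth)))

  new("CloneSimulation", genome = genome, variants = vt, truth = truth,
      te = te, sv = sv)
}

getf2 <- function(recs, k) vapply(recs, `[[`, character(1), k)

TE_CATALOG <- data.frame(
  te_class = c("RNA", "RNA", "RNA", "DNA", "DNA", "DNA"),
  te_order = c("LTR", "LTR", "LINE", "TIR", "TIR", "Helitron"),
  te_superfamily = c("Copia", "Gypsy", "L1", "hAT", "Mutator", "Helitron"),
  stringsAsFactors = FALSE)

simulateTeTable <- function(config, index, clones) {
  nTe <- config$n_te_ancestral + config$n_te_private
  if (nTe == 0)
    return(data.frame(contig = character(), position = integer(),
                      te_class = character(), te_order = character(),
                      te_superfamily = character(), carriers = character()))
  ctg <- sample(names(index@contigLengths), nTe, replace = TRUE)
  pos <- vapply(ctg, function(cc)
    sample.int(index@contigLengths[[cc]], 1), numeric(1))
  fam <- TE_CATALOG[sample.int(nrow(TE_CATALOG), nTe, replace = TRUE), ]
  carriers <- c(rep(paste(clones, collapse = ","), config$n_te_ancestral),
                sample(clones, config$n_te_private, replace = TRUE))
  d <- data.frame(contig = ctg, position = as.integer(pos),
                  te_class = fam$te_class, te_order = fam$te_order,
                  te_superfamily = fam$te_superfamily, carriers = carriers,
                  stringsAsFactors = FALSE)
  rownames(d) <- NULL
  d[order(d$contig, d$position), ]
}

SV_SIM_TYPES <- c("deletion", "duplication", "insertion", "inversion")

simulateSvTable <- function(config, contigLengths, clones) {
  nSv <- config$n_sv_ancestral + config$n_sv_private
  if (nSv == 0)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), type = character(),
                      length = integer(), carriers = character()))
  type <- sample(SV_SIM_TYPES, nSv, replace = TRUE,
                 prob = c(0.45, 0.2, 0.2, 0.15))
  len <- pmin(pmax(round(stats::rlnorm(nSv, log(400), 0.7)), 50L), 5000L)
  ctg <- sample(names(contigLengths), nSv, replace = TRUE)
  ## distinct events: re-draw starts that would reciprocally overlap an
  ## earlier same-type event by >= 50% (such records would be ambiguous)
  start <- integer(nSv)
  for (i in seq_len(nSv)) {
    for (try in 1:50) {
      s <- sample.int(max(contigLengths[[ctg[i]]] - len[i] - 1L, 1L), 1) + 1L
      e <- s + len[i] - 1L
      clash <- FALSE
      for (j in seq_len(i - 1L)) {
        if (type[j] != type[i] || ctg[j] != ctg[i]) next
        ov <- min(e, start[j] + len[j] - 1L) - max(s, start[j]) + 1L
        if (type[i] == "insertion") {
          if (abs(s - start[j]) <= 10L) { clash <- TRUE; break }
        } else if (ov > 0 && (ov / len[i] >= 0.5 || ov / len[j] >= 0.5)) {
          clash <- TRUE; break
        }
      }
      if (!clash) break
    }
    start[i] <- s
  }
  end <- ifelse(type == "insertion", start, start + len - 1L)
  carriers <- c(rep(paste(clones, collapse = ","), config$n_sv_ancestral),
                sample(clones, config$n_sv_private, replace = TRUE))
  d <- data.frame(contig = ctg, start = as.integer(start),
                  end = as.integer(end), type = type,
                  length = as.integer(len), carriers = carriers,
                  stringsAsFactors = FALSE)
  rownames(d) <- NULL
  d[order(d$contig, d$start), ]
}

teSvTruth <- function(te, sv, index, offset) {
  rows <- list()
  if (nrow(te) > 0)
    rows[[1]] <- data.frame(
      variant_id = sprintf("te%04d", seq_len(nrow(te))),
      contig = te$contig, position = te$position,
      ref_allele = NA_character_, alt_allele = NA_character_,
      vartype = "TEI", carriers = te$carriers,
      origin = ifelse(grepl(",", te$carriers), "ancestral", "somatic"),
      feature_class = classifyPosition(index, te$contig, te$position),
      cytosine_context = "NA", is_transition = NA,
      effect_label = NA_character_, artifact_in = "", filter_ok = TRUE,
      stringsAsFactors = FALSE)
  if (nrow(sv) > 0)
    rows[[length(rows) + 1]] <- data.frame(
      variant_id = sprintf("sv%04d", seq_len(nrow(sv))),
      contig = sv$contig, position = sv$start,
      ref_allele = NA_character_, alt_allele = paste0("<", sv$type, ">"),
      vartype = "SV", carriers = sv$carriers,
      origin = ifelse(grepl(",", sv$carriers), "ancestral", "somatic"),
      feature_class = classifyPosition(index, sv$contig, sv$start),
      cytosine_context = "NA", is_transition = NA,
      effect_label = NA_character_, artifact_in = "", filter_ok = TRUE,
      stringsAsFactors = FALSE)
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}
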