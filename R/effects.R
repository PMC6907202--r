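## Minimal variant-effect classification over gene models.

EFFECT_SEVERITY <- c("gene_fusion", "exon_loss", "frameshift", "stop_gained",
                     "stop_lost", "start_lost", "splice_acceptor",
                     "splice_donor", "start_gained", "missense",
                     "inframe_indel", "synonymous", "noncoding_exonic",
                     "intronic", "intergenic")

EFFECT_IMPACT <- c(
  gene_fusion = "HIGH", exon_loss = "HIGH", frameshift = "HIGH",
  stop_gained = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
  splice_acceptor = "HIGH", splice_donor = "HIGH", start_gained = "HIGH",
  missense = "MODERATE", inframe_indel = "MODERATE", synonymous = "LOW",
  noncoding_exonic = "MODIFIER", intronic = "MODIFIER",
  intergenic = "MODIFIER")

#' Impact tier of effect categories
#'
#' The HIGH tier collects the putatively deleterious categories: exon loss,
#' start/stop gain or loss, frameshift, gene fusion, and splice
#' acceptor/donor disruption — changes expected to disrupt the encoded
#' protein.
#'
#' @param category character vector of effect categories.
#' @return character vector of HIGH/MODERATE/LOW/MODIFIER.
#' @export
effectImpact <- function(category) {
  unknown <- base::setdiff(unique(category), names(EFFECT_IMPACT))
  if (length(unknown) > 0)
    stop("unknown effect category: ", paste(unknown, collapse = ", "))
  unname(EFFECT_IMPACT[category])
}

#' Load gene models for effect classification
#'
#' Extracts per-transcript CDS and exon intervals from a GFF3 file or an
#' imported `GRanges`. Transcripts whose total CDS length is not a multiple
#' of 3 are flagged and skipped with a warning.
#'
#' @param gff GFF3 path or `GRanges` with `type`, `ID`, `Parent` metadata.
#' @return list of transcript models; each has tx_id, gene_id, contig,
#'   strand, cds (`GRanges`, genomic order), exons (`GRanges`).
#' @export
readGeneModels <- function(gff) {
  if (is.character(gff)) gff <- rtracklayer::import(gff)
  typ <- as.character(mcols(gff)$type)
  firstParent <- function(g) vapply(as.list(mcols(g)$Parent), function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  mrna <- gff[typ %in% c("mRNA", "transcript")]
  txGene <- setNames(firstParent(mrna), as.character(mcols(mrna)$ID))
  cds <- gff[typ == "CDS"]
  exons <- gff[typ == "exon"]
  cdsBy <- split(cds, firstParent(cds))
  exonsBy <- split(exons, firstParent(exons))
  models <- list()
  for (tx in names(cdsBy)) {
    g <- GenomicRanges::sort(cdsBy[[tx]], ignore.strand = TRUE)
    if (sum(width(g)) %% 3 != 0) {
      warning("transcript ", tx, " has CDS length not divisible by 3; ",
              "skipped")
      next
    }
    ex <- if (tx %in% names(exonsBy))
      GenomicRanges::sort(exonsBy[[tx]], ignore.strand = TRUE) else g
    models[[tx]] <- list(
      tx_id = tx,
      gene_id = if (tx %in% names(txGene)) txGene[[tx]] else tx,
      contig = as.character(seqnames(g))[1],
      strand = as.character(strand(g))[1],
      cds = granges(g), exons = granges(ex))
  }
  models
}

## coding-strand CDS sequence of a transcript model
modelCdsSeq <- function(model, reference) {
  parts <- vapply(seq_along(model$cds), function(i)
    as.character(subseq(reference[[model$contig]],
                        start(model$cds)[i], end(model$cds)[i])),
    character(1))
  s <- paste(parts, collapse = "")
  if (model$strand == "-")
    s <- as.character(reverseComplement(DNAString(s)))
  s
}

## 1-based coding-strand CDS coordinate of a genomic position (NA if outside)
cdsCoord <- function(model, pos) {
  w <- width(model$cds)
  offs <- cumsum(c(0, w))[seq_along(w)]
  for (i in seq_along(w)) {
    s <- start(model$cds)[i]; e <- end(model$cds)[i]
    if (pos >= s && pos <= e) {
      within <- pos - s + 1
      cdspos <- offs[i] + within
      if (model$strand == "-") cdspos <- sum(w) - cdspos + 1
      return(cdspos)
    }
  }
  NA_integer_
}

## single mid-CDS codon: must not be treated as an initiator codon
translateCodon <- function(codon) {
  as.character(translate(DNAString(codon), no.init.codon = TRUE,
                         if.fuzzy.codon = "X"))
}

## effect of one variant on one transcript; returns categories (possibly
## several, e.g. a deletion hitting both a splice site and CDS)
effectOnTranscript <- function(model, reference, pos, ref, alt) {
  cats <- character()
  refLen <- nchar(ref); altLen <- nchar(alt)
  isIndel <- refLen != altLen
  ## reference-affected genomic span
  span <- if (refLen > altLen) c(pos + 1, pos + refLen - 1) else c(pos, pos)
  affected <- seq(span[1], span[2])

  ## exon_loss: deletion covering at least one whole exon
  if (refLen > altLen) {
    del <- IRanges(span[1], span[2])
    ex <- IRanges(start(model$exons), end(model$exons))
    if (any(start(ex) >= start(del) & end(ex) <= end(del)))
      cats <- c(cats, "exon_loss")
  }

  ## splice sites: the 2 intronic bases flanking each exon
  if (length(model$exons) > 1) {
    exn <- model$exons
    intrS <- end(exn)[-length(exn)] + 1
    intrE <- start(exn)[-1] - 1
    for (k in seq_along(intrS)) {
      if (intrE[k] < intrS[k]) next
      fiveSide <- c(intrS[k], min(intrS[k] + 1, intrE[k]))
      threeSide <- c(max(intrE[k] - 1, intrS[k]), intrE[k])
      donor <- if (model$strand == "+") fiveSide else threeSide
      acceptor <- if (model$strand == "+") threeSide else fiveSide
      if (any(affected >= donor[1] & affected <= donor[2]))
        cats <- c(cats, "splice_donor")
      if (any(affected >= acceptor[1] & affected <= acceptor[2]))
        cats <- c(cats, "splice_acceptor")
    }
  }

  ## CDS consequences
  cdsHit <- vapply(affected, function(p)
    !is.na(cdsCoord(model, p)), logical(1))
  if (any(cdsHit)) {
    cdsSeq <- modelCdsSeq(model, reference)
    nCodon <- nchar(cdsSeq) / 3
    if (!isIndel) {
      cpos <- cdsCoord(model, pos)
      b <- if (model$strand == "+") alt else
        as.character(reverseComplement(DNAString(alt)))
      codonIdx <- (cpos - 1) %/% 3 + 1
      codon <- substring(cdsSeq, (codonIdx - 1) * 3 + 1, codonIdx * 3)
      off <- (cpos - 1) %% 3 + 1
      mutCodon <- codon
      substring(mutCodon, off, off) <- b
      aaRef <- translateCodon(codon)
      aaMut <- translateCodon(mutCodon)
      cats <- c(cats, if (aaRef == aaMut) "synonymous"
                else if (codonIdx == 1) "start_lost"
                else if (aaMut == "*") "stop_gained"
                else if (aaRef == "*") "stop_lost"
                else "missense")
    } else {
      nCds <- sum(cdsHit) # CDS bases removed (deletion) ...
      if (altLen > refLen) nCds <- altLen - refLen # ... or inserted
      if (nCds %% 3 != 0) {
        cats <- c(cats, "frameshift")
      } else {
        mutCds <- tryCatch(
          mutateCdsSequence(model, reference, pos, ref, alt),
          error = function(e) NULL)
        if (is.null(mutCds)) {
          cats <- c(cats, "inframe_indel")
        } else {
          protMut <- translateCodons(mutCds)
          nStopAt <- regexpr("*", protMut, fixed = TRUE)
          cats <- c(cats,
            if (nStopAt > 0 && nStopAt < nchar(protMut)) "stop_gained"
            else "inframe_indel")
        }
      }
    }
  } else if (length(cats) == 0) {
    ## inside the gene but neither CDS nor splice: exon (noncoding) or intron
    inExon <- any(vapply(affected, function(p)
      any(start(model$exons) <= p & end(model$exons) >= p), logical(1)))
    cats <- c(cats, if (inExon) "noncoding_exonic" else "intronic")
  }
  unique(cats)
}

translateCodons <- function(s) {
  s <- substring(s, 1, (nchar(s) %/% 3) * 3)
  if (nchar(s) == 0) return("")
  as.character(translate(DNAString(s), if.fuzzy.codon = "X"))
}

## rebuild the coding-strand CDS with an in-CDS indel applied; errors if the
## edit is not fully contained in one CDS exon
mutateCdsSequence <- function(model, reference, pos, ref, alt) {
  cdsSeq <- modelCdsSeq(model, reference)
  if (nchar(ref) > nchar(alt)) {           # deletion
    from <- cdsCoord(model, pos + 1)
    to <- cdsCoord(model, pos + nchar(ref) - 1)
    if (is.na(from) || is.na(to)) stop("edit crosses CDS boundary")
    lo <- min(from, to); hi <- max(from, to)
    paste0(substring(cdsSeq, 1, lo - 1), substring(cdsSeq, hi + 1))
  } else {                                  # insertion after `pos`
    at <- cdsCoord(model, pos)
    if (is.na(at)) stop("edit outside CDS")
    ins <- substring(alt, 2)
    if (model$strand == "-") {
      at <- at - 1                          # insert 5' of the anchor base
      ins <- as.character(reverseComplement(DNAString(ins)))
    }
    paste0(substring(cdsSeq, 1, at), ins, substring(cdsSeq, at + 1))
  }
}

#' Classify variant effects against gene models
#'
#' A minimal, deterministic effect classifier. Per variant and overlapping
#' transcript: CDS SNVs are translated codon-wise
#' (synonymous / missense / stop_gained / stop_lost / start_lost); CDS
#' INDELs are frameshift when the number of coding bases gained or lost is
#' not a multiple of 3, otherwise inframe_indel (an inframe event that
#' introduces a premature stop is stop_gained); variants hitting the two
#' canonical intronic bases flanking an exon are splice_donor (5' side of
#' the intron) or splice_acceptor (3' side), orientation following the
#' strand; deletions covering a whole exon are exon_loss; deletions touching
#' the CDS of two distinct genes are gene_fusion; everything outside genes
#' is intergenic. The most severe category across transcripts is reported
#' (severity order: `r paste(EFFECT_SEVERITY, collapse = " > ")`).
#'
#' `start_gained` (an upstream SNV creating a novel ATG in annotated 5'
#' exonic UTR sequence) is only reachable for gene models that annotate UTR
#' exons; with CDS-only models the category never fires.
#'
#' @param variants `data.frame` with columns contig, position, ref, alt, or
#'   a [VariantTable-class] (first alt used).
#' @param models gene models from [readGeneModels()].
#' @param reference `DNAStringSet` or FASTA path.
#' @param perTranscript return every (variant, transcript) call instead of
#'   the most severe per variant.
#' @return `data.frame` with contig, position, ref, alt, category, impact,
#'   gene_id (NA outside genes; `perTranscript` adds tx_id).
#' @export
classifyEffect <- function(variants, models, reference,
                           perTranscript = FALSE) {
  if (is(variants, "VariantTable")) {
    alts <- vapply(as.list(altAlleles(variants)), `[[`, character(1), 1)
    variants <- data.frame(
      contig = as.character(seqnames(rowRanges(variants))),
      position = start(rowRanges(variants)),
      ref = refAllele(variants), alt = alts)
  }
  if (is.character(reference)) reference <- readDNAStringSet(reference)
  names(reference) <- sub("\\s.*", "", names(reference))
  ## transcript lookup by contig with gene spans
  spans <- do.call(rbind, lapply(models, function(m) data.frame(
    tx = m$tx_id, contig = m$contig,
    start = min(start(m$exons), start(m$cds)),
    end = max(end(m$exons), end(m$cds)))))
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    ctg <- variants$contig[i]; pos <- variants$position[i]
    ref <- variants$ref[i]; alt <- variants$alt[i]
    refObs <- as.character(subseq(reference[[ctg]], pos,
                                  pos + nchar(ref) - 1))
    if (refObs != ref)
      stop(sprintf("reference mismatch at %s:%d (VCF %s, FASTA %s)",
                   ctg, pos, ref, refObs))
    span <- if (nchar(ref) > nchar(alt)) c(pos + 1, pos + nchar(ref) - 1)
            else c(pos, pos)
    hit <- if (is.null(spans)) logical(0) else
      spans$contig == ctg & spans$start <= span[2] & spans$end >= span[1]
    calls <- list()
    if (any(hit)) {
      for (tx in spans$tx[hit]) {
        m <- models[[tx]]
        cats <- effectOnTranscript(m, reference, pos, ref, alt)
        for (cc in cats)
          calls[[length(calls) + 1]] <- data.frame(
            tx_id = tx, gene_id = m$gene_id, category = cc)
      }
      ## gene_fusion: deletion overlapping CDS of two distinct genes
      if (nchar(ref) > nchar(alt)) {
        cdsGenes <- unique(unlist(lapply(spans$tx[hit], function(tx) {
          m <- models[[tx]]
          if (any(start(m$cds) <= span[2] & end(m$cds) >= span[1]))
            m$gene_id else NULL
        })))
        if (length(cdsGenes) >= 2)
          calls[[length(calls) + 1]] <- data.frame(
            tx_id = NA_character_, gene_id = paste(sort(cdsGenes),
                                                   collapse = "+"),
            category = "gene_fusion")
      }
    }
    if (length(calls) == 0)
      calls[[1]] <- data.frame(tx_id = NA_character_,
                               gene_id = NA_character_,
                               category = "intergenic")
    cd <- do.call(rbind, calls)
    cd$impact <- effectImpact(cd$category)
    base <- data.frame(contig = ctg, position = pos, ref = ref, alt = alt)
    if (perTranscript) {
      out[[i]] <- cbind(base[rep(1, nrow(cd)), , drop = FALSE], cd)
    } else {
      sev <- match(cd$category, EFFECT_SEVERITY)
      best <- which.min(sev) # ties: first in severity order, then tx order
      out[[i]] <- cbind(base, cd[best, c("category", "impact", "gene_id"),
                                 drop = FALSE])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Deleterious fraction by sharing level
#'
#' The proportion of exonic variants at each sharing level N that carry a
#' HIGH-impact (putatively deleterious) effect call. Bins with zero exonic
#' variants are reported absent.
#'
#' @param effects `data.frame` with at least `impact` and `N` columns, one
#'   row per exonic variant site.
#' @param nClones panel size (rows of the output run N = 1..nClones).
#' @return `data.frame` with N, nExonic, nHigh, fraction.
#' @export
deleteriousFractionBySharing <- function(effects, nClones = max(effects$N)) {
  out <- do.call(rbind, lapply(seq_len(nClones), function(n) {
    sel <- effects$N == n
    if (!any(sel)) return(NULL)
    data.frame(N = n, nExonic = sum(sel),
               nHigh = sum(effects$impact[sel] == "HIGH"),
               fraction = mean(effects$impact[sel] == "HIGH"))
  }))
  if (is.null(out))
    out <- data.frame(N = integer(), nExonic = integer(),
                      nHigh = integer(), fraction = numeric())
  rownames(out) <- NULL
  out
}
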