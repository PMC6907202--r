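## Construction, io and genotype semantics for VariantTable.

#' Build a VariantTable from in-memory vectors
#'
#' Low-level constructor used by the simulator and by tests. All arguments are
#' parallel over records except `genotypes`, a records x samples character
#' matrix of diploid GT strings.
#'
#' @param contig,position character/integer vectors; `position` is 1-based.
#' @param ref character vector of reference alleles.
#' @param alt list (or `CharacterList`) of alternate alleles per record, or a
#'   character vector for uniformly biallelic input.
#' @param genotypes character matrix, rows = records, columns = samples.
#' @param qual numeric site quality (default 100).
#' @param metrics `data.frame`/`DataFrame` with any of the columns
#'   `r paste(VARIANT_METRICS, collapse = ", ")`; missing columns become NA.
#' @param filter filter status strings (default `"."` = unannotated).
#' @param contigLengths optional named vector; recorded as seqlengths.
#' @return a [VariantTable-class].
#' @export
makeVariantTable <- function(contig, position, ref, alt, genotypes,
                             qual = NULL, metrics = NULL, filter = NULL,
                             contigLengths = NULL) {
  n <- length(position)
  if (is.character(alt)) alt <- as.list(alt)
  alt <- IRanges::CharacterList(alt)
  if (is.null(qual)) qual <- rep(100, n)
  if (is.null(filter)) filter <- rep(".", n)
  m <- S4Vectors::DataFrame(matrix(nrow = n, ncol = 0))
  for (k in VARIANT_METRICS) {
    m[[k]] <- if (!is.null(metrics) && k %in% colnames(metrics))
      as.numeric(metrics[[k]]) else rep(NA_real_, n)
  }
  gr <- GRanges(contig, IRanges(start = as.integer(position),
                                width = nchar(ref)))
  if (!is.null(contigLengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(contigLengths)
    GenomeInfoDb::seqlengths(gr) <- contigLengths
  }
  mcols(gr) <- cbind(S4Vectors::DataFrame(REF = ref, ALT = alt,
                                          QUAL = as.numeric(qual),
                                          FILTER = filter), m)
  genotypes <- as.matrix(genotypes)
  stopifnot(nrow(genotypes) == n)
  se <- SummarizedExperiment(assays = list(GT = genotypes), rowRanges = gr)
  new("VariantTable", se)
}

#' @describeIn makeVariantTable genotype string matrix (records x samples)
#' @param x a `VariantTable`
#' @export
genotypes <- function(x) assay(x, "GT")

#' @describeIn makeVariantTable reference alleles
#' @export
refAllele <- function(x) mcols(rowRanges(x))$REF

#' @describeIn makeVariantTable alternate alleles as a `CharacterList`
#' @export
altAlleles <- function(x) mcols(rowRanges(x))$ALT

#' @describeIn makeVariantTable filter status per record
#' @export
filterStatus <- function(x) mcols(rowRanges(x))$FILTER

#' @describeIn makeVariantTable site quality scores
#' @export
variantQual <- function(x) mcols(rowRanges(x))$QUAL

#' @describeIn makeVariantTable caller metrics as a `DataFrame`
#' @export
variantMetrics <- function(x) mcols(rowRanges(x))[, VARIANT_METRICS]

#' Read a multi-sample VCF into a VariantTable
#'
#' Lossless load of a VCF v4.2 file through
#' [VariantAnnotation::readVcf()]: all records, all alternate alleles, all
#' samples, the GT field, QUAL, FILTER, and whichever of the six caller
#' metrics (`DP`, `QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`) are
#' present in INFO.
#'
#' @param path a VCF (optionally bgzipped) file with a GT FORMAT field.
#' @return a [VariantTable-class].
#' @export
readVariantTable <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  if (!"GT" %in% names(geno(vcf)))
    stop("VCF has no GT field: ", path)
  gt <- geno(vcf)$GT
  inf <- info(vcf)
  met <- S4Vectors::DataFrame(matrix(nrow = nrow(gt), ncol = 0))
  for (k in VARIANT_METRICS) {
    v <- if (k %in% colnames(inf)) suppressWarnings(as.numeric(inf[[k]]))
         else rep(NA_real_, nrow(gt))
    met[[k]] <- v
  }
  rr <- rowRanges(vcf)
  flt <- as.character(mcols(rr)$FILTER)
  flt[is.na(flt)] <- "."
  gt <- matrix(as.character(gt), nrow = nrow(gt),
               dimnames = list(NULL, colnames(gt)))
  sl <- GenomeInfoDb::seqlengths(vcf)
  makeVariantTable(
    contig = as.character(seqnames(rr)),
    position = start(rr),
    ref = as.character(ref(vcf)),
    alt = lapply(alt(vcf), as.character),
    genotypes = gt,
    qual = as.numeric(mcols(rr)$QUAL),
    metrics = met,
    filter = flt,
    contigLengths = if (length(sl) && !anyNA(sl)) sl else NULL)
}

#' Write a VariantTable as VCF v4.2
#'
#' Fixed-format emitter for the package's fixtures: GT-only FORMAT, the six
#' caller metrics in INFO (omitted when NA). Coordinates are 1-based as the
#' format requires; output is plain text.
#'
#' @param x a [VariantTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVariantTable <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  sl <- GenomeInfoDb::seqlengths(rowRanges(x))
  for (ctg in names(sl)) {
    if (!is.na(sl[[ctg]]))
      writeLines(sprintf("##contig=<ID=%s,length=%d>", ctg, sl[[ctg]]), con)
  }
  descr <- c(DP = "Approximate read depth", QD = "Quality by depth",
             FS = "Fisher strand bias (phred)", MQ = "RMS mapping quality",
             MQRankSum = "Mapping quality rank sum",
             ReadPosRankSum = "Read position rank sum")
  typ <- c(DP = "Integer", QD = "Float", FS = "Float", MQ = "Float",
           MQRankSum = "Float", ReadPosRankSum = "Float")
  for (k in VARIANT_METRICS)
    writeLines(sprintf(
      "##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">", k, typ[[k]],
      descr[[k]]), con)
  writeLines(
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">", con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(x)), collapse = "\t"), con)
  if (nrow(x) == 0) return(invisible(path))
  met <- as.data.frame(variantMetrics(x))
  infoStr <- vapply(seq_len(nrow(x)), function(i) {
    v <- unlist(met[i, ])
    keep <- which(!is.na(v))
    if (length(keep) == 0) return(".")
    parts <- vapply(keep, function(j) {
      if (names(v)[j] == "DP") sprintf("DP=%d", as.integer(v[j]))
      else sprintf("%s=%.2f", names(v)[j], v[j])
    }, character(1))
    paste(parts, collapse = ";")
  }, character(1))
  altStr <- vapply(as.list(altAlleles(x)), paste, character(1), collapse = ",")
  qualStr <- ifelse(is.na(variantQual(x)), ".",
                    formatC(variantQual(x), format = "g"))
  body <- paste(as.character(seqnames(rowRanges(x))), start(rowRanges(x)),
                ".", refAllele(x), altStr, qualStr, filterStatus(x), infoStr,
                "GT", sep = "\t")
  gtBody <- apply(genotypes(x), 1, paste, collapse = "\t")
  writeLines(paste(body, gtBody, sep = "\t"), con)
  invisible(path)
}

## ---- genotype string semantics ------------------------------------------

gtSplit <- function(gt) strsplit(gt, "[/|]")

#' Diploid genotype predicates
#'
#' Vectorized helpers over VCF GT strings. A genotype is missing when any
#' allele is `"."`; heterozygous when its two alleles differ; a carrier of
#' alt `k` (1-based alt index) when heterozygous with one allele equal to
#' `k`.
#'
#' @param gt character vector of GT strings (`"0/1"`, `"1|0"`, `"./."`, ...).
#' @param altIndex integer alt allele index (1 = first ALT).
#' @return logical vector.
#' @export
gtIsMissing <- function(gt) {
  vapply(gtSplit(gt), function(a) any(a == ".") || length(a) == 0, logical(1))
}

#' @rdname gtIsMissing
#' @export
gtIsHet <- function(gt) {
  vapply(gtSplit(gt), function(a)
    length(a) == 2 && !any(a == ".") && a[1] != a[2], logical(1))
}

#' @rdname gtIsMissing
#' @export
gtIsHomRef <- function(gt) {
  vapply(gtSplit(gt), function(a)
    length(a) == 2 && all(a == "0"), logical(1))
}

#' @rdname gtIsMissing
#' @export
gtIsHomAlt <- function(gt) {
  vapply(gtSplit(gt), function(a)
    length(a) == 2 && !any(a == ".") && a[1] == a[2] && a[1] != "0",
    logical(1))
}

#' @rdname gtIsMissing
#' @export
gtHasNonRef <- function(gt) {
  vapply(gtSplit(gt), function(a) any(a != "." & a != "0"), logical(1))
}

#' @rdname gtIsMissing
#' @export
gtCarriesAltHet <- function(gt, altIndex = 1) {
  k <- as.character(altIndex)
  vapply(gtSplit(gt), function(a)
    length(a) == 2 && !any(a == ".") && a[1] != a[2] && any(a == k),
    logical(1))
}

#' Dosage of non-reference alleles
#'
#' `0`, `1`, `2` or `NA` (missing). Counts alleles equal to `altIndex`;
#' genotypes involving other alt alleles still count only that alt.
#'
#' @inheritParams gtIsMissing
#' @return integer vector.
#' @export
gtDosage <- function(gt, altIndex = 1) {
  k <- as.character(altIndex)
  vapply(gtSplit(gt), function(a) {
    if (any(a == ".") || length(a) != 2) return(NA_integer_)
    sum(a == k)
  }, integer(1))
}

#' Classify variant records as SNV or INDEL
#'
#' Per alternate allele: SNV iff reference and alternate are both a single
#' base; symbolic alleles (`<DEL>`, `<INS>`, ...) are `"SV"` and are excluded
#' from SNV/INDEL tallies downstream; everything else is an INDEL.
#'
#' @param ref,alt character vectors (recycled) of reference and alternate
#'   alleles.
#' @return character vector in `c("SNV", "INDEL", "SV")`.
#' @export
classifyVariantType <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  out <- ifelse(grepl("^<.*>$", alt), "SV",
         ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV", "INDEL"))
  out
}

#' Per-record variant type of a table (first alt by default)
#'
#' @param x a [VariantTable-class].
#' @param altIndex which alternate allele to classify.
#' @return character vector, NA where the record has fewer alts.
#' @export
variantType <- function(x, altIndex = 1) {
  alts <- as.list(altAlleles(x))
  a1 <- vapply(alts, function(a)
    if (length(a) >= altIndex) a[[altIndex]] else NA_character_, character(1))
  ifelse(is.na(a1), NA_character_, classifyVariantType(refAllele(x), a1))
}
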