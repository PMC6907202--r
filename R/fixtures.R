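## Serialization of simulated fixtures: FASTA + GFF3 + BED + VCF + TSV.

#' Write a simulation to disk as standard-format fixtures
#'
#' Emits `reference.fa` (+ `.fai` index), `genes.gff3` (1-based closed),
#' `repeats.bed` (0-based half-open), `variants.vcf` (VCF v4.2, all samples,
#' GT plus the six caller metrics in INFO), `te_insertions.tsv`, `svs.vcf`
#' (symbolic-ALT records with SVTYPE/SVLEN/END and per-clone GT) and
#' `truth.tsv`. Identical simulations produce byte-identical files.
#'
#' @param sim a [CloneSimulation-class].
#' @param outdir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
writeFixture <- function(sim, outdir) {
  stopifnot(is(sim, "CloneSimulation"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  p <- function(f) file.path(outdir, f)

  writeXStringSet(sim@genome@sequence, p("reference.fa"))
  Rsamtools::indexFa(p("reference.fa"))
  rtracklayer::export(sim@genome@genes, p("genes.gff3"), format = "gff3")
  if (length(sim@genome@repeats) > 0) {
    rtracklayer::export(sim@genome@repeats, p("repeats.bed"), format = "bed")
  } else {
    writeLines(character(0), p("repeats.bed"))
  }
  writeVariantTable(sim@variants, p("variants.vcf"))
  write.table(sim@te, p("te_insertions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeSvVcf(sim@sv, sim@genome@sequence,
             colnames(sim@variants)[colnames(sim@variants) %in%
                                      cloneLabels2(sim)], p("svs.vcf"))
  write.table(sim@truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(reference = p("reference.fa"), genes = p("genes.gff3"),
              repeats = p("repeats.bed"), variants = p("variants.vcf"),
              te = p("te_insertions.tsv"), sv = p("svs.vcf"),
              truth = p("truth.tsv")))
}

cloneLabels2 <- function(sim)
  sprintf("clone%02d", seq_len(sim@genome@config$n_clones))

SV_SYMBOL <- c(deletion = "DEL", duplication = "DUP", insertion = "INS",
               inversion = "INV", `duplicated insertion` = "DUP:INS",
               `inverted duplication` = "INV:DUP")

writeSvVcf <- function(sv, sequence, samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (ctg in names(sequence))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ctg,
                       length(sequence[[ctg]])), con)
  writeLines(c(
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    paste0("##ALT=<ID=DEL,Description=\"Deletion\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  for (i in seq_len(nrow(sv))) {
    carriers <- strsplit(sv$carriers[i], ",")[[1]]
    gt <- ifelse(samples %in% carriers, "0/1", "0/0")
    refBase <- as.character(subseq(sequence[[sv$contig[i]]],
                                   sv$start[i], sv$start[i]))
    writeLines(paste(c(
      sv$contig[i], sv$start[i], sprintf("sv%04d", i), refBase,
      paste0("<", SV_SYMBOL[[sv$type[i]]], ">"), "100", ".",
      sprintf("SVTYPE=%s;SVLEN=%d;END=%d", SV_SYMBOL[[sv$type[i]]],
              sv$length[i], sv$end[i]),
      "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a simulator truth table
#'
#' @param path `truth.tsv` as written by [writeFixture()].
#' @return `data.frame` with one row per emitted variant.
#' @export
readTruthTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}
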