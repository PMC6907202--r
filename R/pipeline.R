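## End-to-end orchestration: sanitize -> classify -> analyze -> write tables.

#' Pipeline run configuration
#'
#' Collects paths, sample roles and analysis switches for [runPipeline()].
#'
#' @param reference,genes,repeats,variants,te,sv input file paths (FASTA,
#'   GFF3, BED, small-variant VCF, TE TSV, SV VCF); `repeats`, `te` and `sv`
#'   may be `NULL`.
#' @param outdir output directory.
#' @param cloneSamples clone sample labels (must match VCF columns).
#' @param referenceSample optional label of the assembly-derived sample
#'   whose non-reference calls are removed.
#' @param outgroupSamples optional non-clone cultivar samples (kept for
#'   kinship/PCA, excluded from clone spectra).
#' @param filter a [filterConfig()].
#' @param excludeUniformHet exclude sites identically heterozygous in every
#'   clone from the spectrum (default FALSE).
#' @param svRepeatFilter drop SVs intersecting the repeat annotation
#'   (default TRUE, mirroring short-read SV-call hygiene for clone-vs-clone
#'   input).
#' @param pcaExcludeReference exclude `referenceSample` from the PCA
#'   (default TRUE).
#' @param assemblyLength denominator for SV percent-of-assembly (default:
#'   sum of reference contig lengths).
#' @param seed integer seed recorded in the run manifest.
#' @return validated configuration list.
#' @export
runConfig <- function(reference, genes, variants, outdir, cloneSamples,
                      repeats = NULL, te = NULL, sv = NULL,
                      referenceSample = NULL, outgroupSamples = NULL,
                      filter = filterConfig(), excludeUniformHet = FALSE,
                      svRepeatFilter = TRUE, pcaExcludeReference = TRUE,
                      assemblyLength = NULL, seed = 1L) {
  for (f in c(reference, genes, variants, repeats, te, sv))
    if (!file.exists(f)) stop("input path does not exist: ", f)
  roles <- list(clone = cloneSamples, reference = referenceSample,
                outgroup = outgroupSamples)
  all <- unlist(roles)
  if (anyDuplicated(all)) stop("sample roles overlap")
  cfg <- list(reference = reference, genes = genes, repeats = repeats,
              variants = variants, te = te, sv = sv, outdir = outdir,
              cloneSamples = cloneSamples, referenceSample = referenceSample,
              outgroupSamples = outgroupSamples, filter = filter,
              excludeUniformHet = excludeUniformHet,
              svRepeatFilter = svRepeatFilter,
              pcaExcludeReference = pcaExcludeReference,
              assemblyLength = assemblyLength, seed = as.integer(seed))
  class(cfg) <- c("somaclone_run_config", "list")
  cfg
}

#' Run the full clonal-diversification analysis
#'
#' Executes, in order: load -> hard filters -> reference-sample sanitation ->
#' complete-call restriction -> feature index -> sharing spectra ->
#' normalized rates -> Ti/Tv and cytosine-context signatures -> effect
#' classification and deleterious fractions -> kinship, PCA, dendrogram ->
#' TE and SV summaries. Each output table is written as TSV (tagged with the
#' configuration hash and seed in a leading comment line); counts entering
#' and leaving each stage are logged and returned.
#'
#' @param config a [runConfig()].
#' @param force overwrite a non-empty output directory (default FALSE:
#'   refuses).
#' @return (invisibly) a list with the computed tables, the stage log and
#'   the manifest.
#' @export
runPipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "somaclone_run_config"))
  out <- config$outdir
  if (dir.exists(out) && length(dir(out)) > 0 && !force)
    stop("output directory is not empty (use force = TRUE): ", out)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfgHash <- rlang::hash(config[base::setdiff(names(config), "outdir")])
  tag <- sprintf("# somaclone config_hash=%s seed=%d", cfgHash, config$seed)
  logLines <- character()
  note <- function(...) {
    line <- sprintf(...)
    logLines <<- c(logLines, line)
    message(line)
  }
  emit <- function(tab, name) {
    path <- file.path(out, name)
    con <- file(path, "w")
    writeLines(tag, con)
    suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    close(con)
  }

  reference <- readDNAStringSet(config$reference)
  names(reference) <- sub("\\s.*", "", names(reference))
  contigLengths <- setNames(Biostrings::width(reference), names(reference))

  vt <- readVariantTable(config$variants)
  note("stage load: %d records, %d samples", nrow(vt), ncol(vt))

  vt <- applyHardFilters(vt, config$filter)
  vtP <- passingRecords(vt)
  note("stage hard_filter: in %d, out %d (removed %d)", nrow(vt),
       nrow(vtP), nrow(vt) - nrow(vtP))

  if (!is.null(config$referenceSample)) {
    n0 <- nrow(vtP)
    vtP <- dropReferenceNonref(vtP, config$referenceSample)
    note("stage reference_sanitation: in %d, out %d (removed %d)", n0,
         nrow(vtP), n0 - nrow(vtP))
  }
  n0 <- nrow(vtP)
  vtP <- completeCallSites(vtP)
  note("stage complete_calls: in %d, out %d (removed %d)", n0, nrow(vtP),
       n0 - nrow(vtP))

  genes <- rtracklayer::import(config$genes)
  repeats <- if (!is.null(config$repeats) &&
                 file.size(config$repeats) > 0)
    rtracklayer::import(config$repeats) else GRanges()
  index <- buildFeatureIndex(genes, repeats, contigLengths)
  note("stage feature_index: %d tiles over %d bp",
       length(featureTiles(index)), sum(contigLengths))

  clones <- config$cloneSamples
  te <- if (!is.null(config$te)) readTeTable(config$te) else NULL
  sv <- if (!is.null(config$sv)) readSvTable(config$sv) else NULL

  spectrum <- buildSpectrum(vtP, cloneSamples = clones, index = index,
                            te = te, sv = sv,
                            excludeUniformHet = config$excludeUniformHet,
                            usePass = FALSE)
  emit(spectrum, "fig5a_spectrum.tsv")
  note("stage spectrum: %d strata rows", nrow(spectrum))

  rates <- normalizedRates(countByFeature(vtP, index, samples = clones),
                           index)
  emit(rates, "fig4_rates.tsv")

  ## clone-unique heterozygous SNVs for the signature analyses
  N <- sharingLevel(vtP, clones)
  vtSnv <- vtP[variantType(vtP) == "SNV" & N == 1, ]
  gt <- genotypes(vtSnv)[, clones, drop = FALSE]
  uniq <- do.call(rbind, lapply(seq_len(nrow(vtSnv)), function(i) {
    who <- clones[gtCarriesAltHet(gt[i, ])]
    data.frame(clone = who,
               contig = as.character(seqnames(rowRanges(vtSnv)))[i],
               position = start(rowRanges(vtSnv))[i],
               ref = refAllele(vtSnv)[i],
               alt = as.list(altAlleles(vtSnv))[[i]][1])
  }))
  if (is.null(uniq))
    uniq <- data.frame(clone = character(), contig = character(),
                       position = integer(), ref = character(),
                       alt = character())
  uniq$feature <- if (nrow(uniq) > 0)
    classifyPosition(index, uniq$contig, uniq$position) else character(0)
  titv <- titvRatio(uniq, by = c("feature", "clone"))
  emit(titv, "fig5c_titv.tsv")

  ctx <- contextTransitionPercentages(uniq, reference, index, clones)
  emit(ctx$summary, "fig5d_context.tsv")
  note("stage signature: %d unique het SNVs", nrow(uniq))

  models <- readGeneModels(genes)
  exonic <- which(classifyPosition(
    index, as.character(seqnames(rowRanges(vtP))),
    affectedPosition(start(rowRanges(vtP)), refAllele(vtP),
                     vapply(as.list(altAlleles(vtP)), `[[`, character(1),
                            1))) == "exon" &
    variantType(vtP) %in% c("SNV", "INDEL"))
  impactTab <- if (length(exonic) > 0) {
    eff <- classifyEffect(vtP[exonic, ], models, reference)
    eff$N <- N[exonic]
    deleteriousFractionBySharing(eff, nClones = length(clones))
  } else data.frame(N = integer(), nExonic = integer(), nHigh = integer(),
                    fraction = numeric())
  emit(impactTab, "fig5e_impact.tsv")
  note("stage effects: %d exonic variants", length(exonic))

  kinSamples <- c(clones, config$outgroupSamples)
  gm <- genotypeMatrix(vtP, samples = kinSamples, usePass = FALSE)
  kin <- kinshipMatrix(gm)
  emit(cbind(sample = rownames(kin), as.data.frame(kin)),
       "fig3_kinship.tsv")
  pca <- genotypePCA(gm, exclude = if (config$pcaExcludeReference)
    config$referenceSample else NULL)
  pcaTab <- cbind(sample = rownames(pca$scores),
                  as.data.frame(pca$scores))
  emit(pcaTab, "fig3_pca.tsv")
  dend <- kinshipDendrogram(kin)
  writeLines(dend$newick, file.path(out, "tree.nwk"))
  note("stage relatedness: %d samples, %d sites", ncol(gm), nrow(gm))

  if (!is.null(te)) {
    teDist <- nearestGeneDistances(te, genes)
    teSpec <- teClassificationSpectrum(te, clones)
    emit(cbind(teDist$summary,
               nGenic = teDist$nGenic, nIntergenic = teDist$nIntergenic),
         "fig6_te.tsv")
    emit(teSpec, "fig6b_te_types.tsv")
  }
  if (!is.null(sv)) {
    svSumm <- summarizeSVs(
      sv, genes,
      assemblyLength = if (is.null(config$assemblyLength))
        sum(contigLengths) else config$assemblyLength,
      dropRepeatOverlap = if (config$svRepeatFilter && length(repeats) > 0)
        repeats else NULL)
    emit(svSumm$summary, "table3_sv.tsv")
  }

  manifest <- list(configHash = cfgHash, seed = config$seed,
                   nRecordsLoaded = nrow(vt), nRecordsAnalyzed = nrow(vtP),
                   samples = colnames(vt), log = logLines)
  jsonlite::write_json(manifest, file.path(out, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(logLines, file.path(out, "run.log"))
  invisible(list(spectrum = spectrum, rates = rates, titv = titv,
                 context = ctx, impact = impactTab, kinship = kin,
                 pca = pca, dendrogram = dend, log = logLines,
                 manifest = manifest))
}
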