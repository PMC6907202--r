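## Shared simulated fixtures, built once per test run.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(GenomicRanges)
})

defaultSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cloneSimConfig(seed = 1)
      g <- simulateReference(cfg)
      cache <<- list(cfg = cfg, genome = g,
                     sim = simulateCloneVariants(cfg, g))
    }
    cache
  }
})

## a small hand-buildable variant table
handTable <- function(genotypes, ref = NULL, alt = NULL, contig = "ctg1",
                      position = NULL, metrics = NULL, qual = NULL) {
  n <- nrow(genotypes)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  if (is.null(position)) position <- seq(100, by = 100, length.out = n)
  makeVariantTable(contig = rep(contig, n), position = position, ref = ref,
                   alt = alt, genotypes = genotypes, metrics = metrics,
                   qual = qual)
}
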