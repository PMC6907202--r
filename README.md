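# somaclone

Somatic variant diversification analysis for clonally propagated genomes.

## The problem

Vegetatively propagated crops — grapevine clones are the motivating case —
are genetically a single individual copied through decades or centuries of
cuttings. Their genomes still diverge: somatic mutations arise in meristem
cell lineages and are inherited by every downstream clone of that branch.
Because the whole panel descends from one heterozygous mother plant, each
heterozygous variant in a multi-clone resequencing panel carries a signal in
its **sharing level N** — the number of clones heterozygous for it:

* `N = panel size` — ancestral heterozygosity inherited from the mother's
  parents;
* `N = 1` (or a small subclade) — a somatic mutation that arose during
  propagation.

somaclone implements the downstream analysis of such a panel for people who
already have multi-sample variant calls: call sanitation, the sharing
spectrum, where in the genome somatic mutations concentrate, what signature
they carry, how deleterious they are, and how the clones relate to one
another.

## What it computes

Given a multi-sample VCF, a reference FASTA, gene models (GFF3), repeat
intervals (BED), and optionally TE-insertion and SV tables:

* **Sanitation** (`applyHardFilters`, `dropReferenceNonref`,
  `completeCallSites`) — GATK-style hard-filter annotation
  (DP > 20, DP < 5, QUAL < 20, QD < 2.0, FS > 60.0, MQ < 40.0,
  MQRankSum < −12.5, ReadPosRankSum < −8.0; each rule individually
  switchable), removal of non-reference calls in the assembly-derived
  sample, restriction to sites called in every sample, and multi-caller
  concordance partitions (`callSetConcordance`).
* **Feature stratification** (`buildFeatureIndex`, `classifyPosition`,
  `normalizedRates`) — every base assigned to exactly one of exon, intron,
  intergenic repeat, non-repetitive intergenic; variant rates reported as
  count / feature bp × 1000.
* **Sharing spectrum** (`sharingLevel`, `buildSpectrum`) — counts of
  heterozygous SNVs, INDELs, SVs and TE insertions shared by only N clones,
  overall and per feature class.
* **Mutation signatures** (`isTransition`, `titvRatio`, `cytosineContext`,
  `contextTransitionPercentages`) — Ti/Tv per feature class for
  clone-unique SNVs, and the percentage of CpG/CHG/CHH cytosine sites per
  class carrying a unique C→T (strand-mirrored G→A) transition. Methylated
  cytosines deaminate to thymine, so methylation-dense repeat space is
  expected to show elevated values of both.
* **Effect classification** (`classifyEffect`,
  `deleteriousFractionBySharing`) — a minimal, deterministic classifier over
  gene models (synonymous/missense/stop gain/loss, start loss, frameshift,
  inframe indel, splice donor/acceptor, exon loss, gene fusion) with a HIGH
  "putatively deleterious" tier, and the fraction of exonic variants that
  are HIGH at each sharing level.
* **Relatedness** (`kingPhi`, `kinshipMatrix`, `genotypePCA`,
  `kinshipDendrogram`) — the KING-robust kinship estimator
  `PHI = (N_Aa,Aa − 2 N_AA,aa) / (N_Aa(i) + N_Aa(j))`
  (0.5 = self, ~0.25 = parent–offspring, ~0 = unrelated), genotype PCA on
  centered dosages, and an average-linkage dendrogram on `0.5 − PHI`.
* **TE and SV summaries** (`nearestGeneDistances`, `summarizeSVs`,
  `mergeSvRecords`) — insertion-to-gene distances with quartile summaries,
  and per-type SV counts, median sizes, totals, percent of assembly, and
  genes intersected.
* **Simulator** (`cloneSimConfig`, `simulateReference`,
  `simulateCloneVariants`, `writeFixture`) — a forward simulator of an
  annotated diploid genome plus a star pedigree of clones with
  feature-dependent somatic rates, context-dependent transition
  probabilities, TE/SV events, optional artifact genotypes, and a complete
  ground-truth table; fixtures are byte-reproducible from the seed.

`runPipeline()` chains everything into one run that writes figure-ready TSV
tables and a manifest; `inst/scripts/run-pipeline.R` is a thin shell
wrapper.

## Worked example

```r
library(somaclone)

cfg    <- cloneSimConfig(seed = 1)          # 50 kb genome, 15 clones
genome <- simulateReference(cfg)
sim    <- simulateCloneVariants(cfg, genome)
sim
#> CloneSimulation: 700 small variants, 50 TE insertions, 16 SVs over 15 samples

sp <- buildSpectrum(sim@variants, cloneLabels(cfg), index = genome@index,
                    te = sim@te, sv = sim@sv)
spectrumHeadlines(sp)
#>   vartype total sharedByAll fractionSharedByAll fractionAtMostFew
#> 1   INDEL   101          16           0.1584158         0.8415842
#> 2     SNV   599          78           0.1302170         0.8697830
#> 3      SV    16          12           0.7500000         0.2500000
#> 4     TEI    50          40           0.8000000         0.2000000

gm  <- genotypeMatrix(sim@variants)
kin <- kinshipMatrix(gm)
round(range(kin[upper.tri(kin)]), 3)
#> [1] 0.329 0.364
kingPhi(gm[, "clone01"], gm[, "clone01"])
#> [1] 0.5
```

Reading the output: `fractionSharedByAll` is the ancestral-heterozygosity
share of each variant type (high for TE insertions and SVs, which the
generator makes mostly ancestral; lower for SNVs/INDELs, where per-clone
somatic mutation dominates at this somatic-to-ancestral rate ratio), and
`fractionAtMostFew` is the recent somatic share (N ≤ 2). Clone pairs share
their ancestral heterozygous background but differ by private mutations, so
their kinship sits between unrelated (0) and self (0.5); a sample against
itself is exactly 0.5.

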