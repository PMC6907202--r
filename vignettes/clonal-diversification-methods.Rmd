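---
title: "Methods: measuring somatic diversification in clonal panels"
author: "somaclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring somatic diversification in clonal panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaclone)
```

## The model

A panel of vegetatively propagated clones is genetically one diploid
individual plus the somatic mutations accumulated along each propagation
branch. somaclone's analyses all derive from one observable per
heterozygous variant: its *sharing level* N, the number of clones
heterozygous for it at a site called in every sample. Under a star pedigree
(every clone an independent descent from one mother), N has only two
interpretable values — the panel size (ancestral heterozygosity of the
mother) and 1 (a private somatic mutation); configured subclades add
intermediate levels by shared descent. Somatic mutations in a bulk-tissue
panel are expected heterozygous: a new mutation arises on one chromosome
copy in one meristem lineage. Homozygous non-reference genotypes in a clone
panel are therefore treated as likely technical artifacts — they are kept
in the table but never counted as het carriers, and an option drops whole
sites containing them.

Four genomic strata carry the biology: exon, intron, intergenic repeat, and
non-repetitive intergenic sequence. Plant DNA methylation concentrates in
repeats (where it silences transposons) and occurs at CpG, CHG and CHH
cytosine contexts (H = A, C or T); methylated cytosines spontaneously
deaminate to thymine. Two statistics are designed to expose that mechanism:
the transition/transversion ratio of clone-unique SNVs per stratum, and the
percentage of context cytosines per stratum carrying a clone-unique C→T
(strand-mirrored G→A) transition.

Relatedness uses the KING-robust kinship estimator over biallelic SNV
dosages,

$$\phi_{ij} = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa}(i) + N_{Aa}(j)},$$

which is 0.5 for self-comparison by construction (the identity is exact,
not asymptotic, for any sample with at least one heterozygous site:
opposite homozygotes cannot occur against oneself and the both-het count
equals each copy's het count). Unrelated individuals under Hardy–Weinberg
equilibrium have expectation 0; a parent–offspring pair 0.25. Clone pairs
sharing H ancestral het sites and carrying m private het mutations each sit
at $\phi = H/(2H + 2m)$, approaching 0.5 as $m/H \to 0$ — kinship close to
but below self is exactly the signature of clonal propagation with somatic
divergence.

## Pipeline order and why it matters

`runPipeline()` fixes the stage order: load → hard-filter annotation →
reference-sample sanitation → complete-call restriction → feature indexing
→ spectra → rates → signatures → effects → relatedness → TE/SV summaries.
Filtering is annotation, not deletion, so the PASS definition is auditable;
sanitation and completeness are per-record predicates (they commute, and
the test suite asserts it). Everything downstream sees only PASS,
reference-clean, complete-call records, because N is meaningless at sites
where some clones are uncalled.

## Tunable parameters

Hard-filter thresholds (defaults: DP > 20, DP < 5, QUAL < 20, QD < 2.0,
FS > 60.0, MQ < 40.0, MQRankSum < −12.5, ReadPosRankSum < −8.0; a record
*fails* a rule when the condition holds) are each independently switchable.
The DP pair deserves a flag: as written it retains only records with depth
in [5, 20], which at ~30× panel coverage would discard most true sites. We
apply the rules exactly as written by default — a tool that silently
reinterprets its own configuration is worse than one that documents a
suspect default — and recommend users of high-coverage data disable or
re-threshold `DP>20` (likely intended as a much higher high-depth cap).

Other switches, all on `runConfig()`/`buildSpectrum()`:

* `excludeUniformHet` (default FALSE): sites identically heterozygous in
  every clone can be read either as ancestral heterozygosity (and counted
  in the top spectrum bin) or as non-variant background between the clones
  (and excluded). Both conventions appear in practice; both are
  first-class here, and enabling the flag can only shrink bins (tested as
  a monotonicity property).
* SV matching (`mergeSvRecords`): records of the same type merge at ≥ 80%
  reciprocal overlap (insertions: ±10 bp), an explicit stand-in for the
  underspecified notion of "the same SV" across samples and callers.
* Feature assignment of INDELs/SVs uses the leftmost reference-affected
  base (`affectedPosition`): deletions classify at the first deleted base,
  insertions at their anchor. An any-overlap alternative would count one
  record in several classes and break the rate normalization's additivity.
* Multi-allelic records are kept losslessly on load, decomposed per alt
  for typing and spectra (focal alt = first), and excluded from the dosage
  matrix, where 0/1/2 coding is undefined for three alleles.

## The simulator: what it emulates, and what it does not

`cloneSimConfig()` defaults *are* the study conditions of the package's
validation: 2 contigs × 25 kb at 34.5% GC (grapevine-like), 12 UTR-less
four-exon genes (exon ≈ 250 bp, intron ≈ 300 bp, CDS forced to ATG…stop
with no internal stop, both strands), repeats covering 40% of intergenic
space, 15 clones, ancestral heterozygosity 0.002/bp, somatic per-clone
rates ranked intergenic-repeat 0.002 > intron 0.001 >
non-repetitive-intergenic 0.0005 > exon 0.0002 per bp, transition
probability 2/3 in repeats versus 1/3 elsewhere, 15% of small variants
INDELs (geometric 1–10 bp), mostly-ancestral TE insertions (40 shared, 10
private) and SVs (12 shared, 4 private). The genome size keeps every test
and the full pipeline inside seconds while leaving hundreds of somatic
events per stratum — enough for 3-standard-error recovery checks on rates
and signatures.

Design choices where the biology is open:

* The pedigree is a star; subclades are configuration
  (`subclade_spec`), not inference, and subclade sharing is descent-only —
  recurrent mutation producing convergent sharing is not modeled.
* Somatic events are uniform within a feature class; no fine-scale rate
  heterogeneity.
* Artifact homozygous-alt genotypes are spiked independently per record and
  sample at a configured rate (optionally restricted, e.g. to a synthetic
  reference-derived sample) and labeled in the truth table so sanitation
  can be scored exactly.
* Caller metrics default to passing values; a configured fraction of
  records receives one failing metric, also labeled.
* Truth `effect_label` is left NA: realized protein consequences of
  randomly placed exonic mutations are not controlled by the generator, so
  the effect classifier is validated against a translate-and-diff oracle
  and constructed splice/exon-loss cases instead.

What passing tests on this generator do *not* show about real data: no
read-level error model (the simulator writes genotypes, not reads), no
mapping bias or repeat-induced miscalling — precisely the failure mode that
inflates SNV counts in repeats in real panels — no cell-layer chimerism
(bulk genotypes only), and no linkage structure. Recovery of a configured
rate here validates the *estimator*, not the upstream caller.

## Numerical and degenerate-input choices

* Sharing level errors on missing genotypes rather than guessing; run
  `completeCallSites()` first.
* Ti/Tv with zero transversions is reported absent (NA), not infinite.
* Cytosine context within 2 bp of a contig end, or beside an N, is "none";
  context denominators count cytosine *sites* (a CpG dinucleotide = two
  sites, one per strand).
* Context percentages are averaged over clones (mean ± SE across the
  panel), matching a per-clone reading of the statistic; a pooled
  alternative (pool SNVs, divide once) is a one-line variant the per-clone
  table supports. Clones with zero unique SNVs contribute 0%, not NA.
* Effect severity is a fixed documented order (gene_fusion > exon_loss >
  frameshift > stop_gained > stop_lost > start_lost > splice_acceptor >
  splice_donor > start_gained > missense > inframe_indel > synonymous >
  noncoding_exonic > intronic > intergenic); the most severe call per
  variant is reported regardless of transcript iteration order.
  `start_gained` requires annotated 5′ UTR exons and never fires on
  CDS-only models. Inframe indels that introduce a premature stop are
  upgraded to stop_gained. Single mid-CDS codons are translated with
  initiator-codon handling disabled (a lone CTG is leucine, not
  methionine).
* Kinship with a zero denominator (no het sites in either sample over
  pairwise-complete sites) is an error for a single pair and NA-with-warning
  in the matrix. PCA uses centered, unscaled dosages (no allele-frequency
  scaling option is enabled by default); constant matrices are a
  degeneracy error.
* The dendrogram clusters `0.5 − φ` with average linkage — the linkage is a
  documented choice, cross-checked against a naive agglomeration oracle;
  negative distances (φ > 0.5 from sampling noise) clip to 0 with a
  warning; ties break by `stats::hclust`'s label-order behaviour.
* Tukey HSD provides the family-wise error control for multi-group
  comparisons; no additional FDR layer is stacked on top.

## Problem sizes used by the validation suite

The test suite simulates 50 kb, 15-clone panels (hundreds of somatic
events per stratum) for exact truth-table recovery; 50,000-site
Hardy–Weinberg matrices for the unrelated-kinship calibration (±0.02);
520 random CDS variants on both strands for the effect-classifier oracle;
and 8-sample random kinship matrices for the clustering oracle. All
randomness is seeded; fixtures are byte-reproducible.

## Known limitations

Bulk diploid genotypes only (no phasing, no genotype likelihoods, no
cell-layer resolution); CDS-only gene models make `start_gained` and
`noncoding_exonic` effectively unreachable; SV effect classification is
limited to exon loss and deletion-type gene fusion; methylation is inferred
by proxy through context-dependent transition rates, never measured.
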