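---
title: "Methods: binning, quality estimation and population analysis in flavbin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binning, quality estimation and population analysis in flavbin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`flavbin` reconstructs partial environmental genomes ("phylogenetic bins")
from an assembled Sanger metagenome and analyses the population structure
of the reads underneath them. This vignette records the models, the
parameters that matter, and the design decisions taken where the
procedure left genuine freedom.

# Composition-based binning

Every scaffold longer than 3,000 bp receives an oligonucleotide frequency
profile: for each word size k in {3, 4, 5, 6}, counts of all k-mers are
taken strand-merged (the scaffold's counts plus its reverse complement's),
each per-k block is normalised to sum to one, and the blocks are
concatenated. Strand merging is our choice — assembly orientation is
arbitrary, so a profile should not depend on it — and windows containing
ambiguous bases are skipped. Scaffolds from the same genome have highly
correlated profiles; scaffolds from compositionally distinct genomes do
not.

Scaffolds are clustered agglomeratively with **average linkage** on the
distance d = 1 − r (Pearson correlation of concatenated profiles). The
linkage and distance transform are open choices here;
average linkage is the conventional choice for correlation-derived
distances and behaved robustly on synthetic communities. Clusters are
extracted by a **flat cut at d = 1 − 0.90**, i.e. the "correlation ≥ 0.90"
rule is implemented as a threshold on merge height, and only clusters containing
at least one scaffold that carries a single-copy phylogenetic marker are
kept as bin candidates.

Two filters follow, both with strict inequalities, exactly as in the
configuration defaults: a first-pass cumulative-size filter (> 1.9 Mbp,
the scale of known genomes of the group) and a second pass restricted to
scaffolds > 5,000 bp requiring > 10,000 reads. Pipelines of this kind
re-assemble reads between passes; `flavbin` deliberately replaces
re-assembly with an identity pass-through, because assembly is outside the
package's scope and the synthetic generator emits final scaffolds
directly.

When a bin's estimated single-copy-gene duplication is ≥ 10%, the bin is
**subdivided**: its members are re-clustered, split at the internal
dendrogram root into two subtrees, and each part is recursed on until
every part is below 10% or cannot be split (singletons). The choice of
subdivision operator is genuinely open; splitting at the root
is the most conservative refinement consistent with the dendrogram.
Subdivision conserves the scaffold multiset and flags parts that hit the
recursion cap instead of looping.

# Bin refinement and quality

Two refinement rules operate on injected annotation evidence (protein
searches themselves are out of scope; their results arrive as tables):

* **Taxonomy vote**: a scaffold is removed when, among its CDS that have
  any database hit, strictly fewer than 60% hit the target phylum.
  Scaffolds with no annotated CDS are retained and flagged
  `"no-evidence"`: removal would discard sequence on no evidence at all.
* **Duplicate scaffolds**: over an injected CDS homology relation, if the
  shorter scaffold of a pair shares ≥ 85% of its genes with a longer one
  it is dropped. Scaffolds are processed longest-first so the longer
  scaffold is always the keeper; length ties break lexicographically by
  id. Both rules are idempotent.

The **core genome** of a reference pangenome is the set of gene families
present in every member, each with expected multiplicity equal to the
minimum count across members; families at exactly one copy everywhere are
the conserved single-copy genes (CSCGs). Completeness is identified core
occurrences over expected occurrences × 100; identified counts are
**capped at each family's expected multiplicity**, so surplus copies
count toward duplication, not completeness (the capping is the package's
reading of "identified core genes" and is configurable). Duplication is the number
of CSCGs found more than once over the number of CSCGs × 100. Both are
reported to two decimals.

The genome size of a partial bin is extrapolated as

    total_bp / (pct_complete / 100) * (1 - pct_duplication / 100)

rounded to the nearest integer. The formula is verified against all four
reference bin-table rows from their size, completeness and duplication
columns; one cell sits 1 bp off nearest rounding, hence the package
tests accept ±2 bp.

# Read-level variant analysis

Pileups are built from the alignment table (read bases are stored in
scaffold orientation, qualities as Phred+33). Three rules, in order:

1. **Quality correction**: a call below Q30 whose base appears in no
   other read at that site reverts to the column consensus; two
   low-quality reads sharing a base support each other and are kept.
2. **SNP calling**: a site is a SNP at coverage ≥ 4 when ≥ 2 reads carry
   the same non-consensus base. Consensus ties break by summed quality,
   then lexicographically (an explicit, configurable convention).
3. **CDS selection**: mean read depth over the CDS span must be strictly
   > 7× — the draft-genome convention is 8×, and 7× admits more CDS while
   still excluding poorly covered ones. Depth (not breadth) is used, by
   analogy with draft-genome coverage.

**Variant tracks** group reads by single-link compatibility: two reads
link when they overlap at ≥ 1 SNP site and agree at every shared SNP
site; connected components are tracks. This grouping is traditionally
done by eye, so the automated policy is explicit: a component whose transitive closure
contains two disagreeing reads is classified `undetermined` (the variants
cannot be separated), as is a SNP-bearing CDS that collapses to a single
component; a CDS without SNPs is one track (`no_snps`); otherwise
`multi_variant`. For pairwise comparisons the reference track is the one
with most supporting reads, ties broken by identity to the CDS consensus,
then by read id. Each track is classified `summer_only`, `winter_only` or
`both` from its reads' season labels.

**dN/dS** is estimated with an in-package Nei–Gojobori (1986) pathway
counting estimator under genetic code 11 rather than external
maximum-likelihood machinery (PAML/codeml) — a deliberate choice: NG86
is transparent, dependency-free
and sufficient for the purifying/saturation screening done here, and the
package's tests verify it recovers a simulated ω = 0.2 within ±0.1.
Details:

* Gapped codons and codon columns containing an in-frame stop are removed
  before counting (mirroring the "remove gaps, inframe stop codons"
  convention).
* Synonymous site counts treat single-site changes to a stop codon as
  nonsynonymous; for codons differing at 2–3 positions, all mutational
  pathways are averaged, excluding pathways through stop codons whenever
  a stop-free pathway exists.
* Jukes–Cantor correction d = −3/4 ln(1 − 4p/3). At p ≥ 3/4 the
  correction has no finite solution; the distance is reported `Inf` and
  flagged, which keeps "saturated ⇔ dS > 2.0" coherent at extreme
  divergence.
* dN/dS < 1 is purifying; dS > 2.0 flags synonymous saturation (and
  possibly a disparate gene history, e.g. recombination); dS doubles as a
  relative divergence-time proxy. When dS = 0 the ratio is undefined.

# Biogeography

Because the sequencing depth is orders of magnitude below the standing
population, each read is treated as one individual: a bin's abundance in
a sample is 100 × (reads on the bin's scaffolds) / (reads in the sample),
with seasonal columns pooling the samples of each season and a TOTAL row
summing the bins. Scaffolds whose summer-read fraction falls outside the
Tukey fences (Q1 − 1.5·IQR, Q3 + 1.5·IQR) of their bin are flagged
outliers — Tukey fences are the package's choice of robust outlier
rule — and bins with fewer than four
scaffolds carrying reads yield no calls. Group differences use a
two-sided permutation t-test (pooled-variance t, default B = 10,000,
add-one p-value p = (1 + #{|t*| ≥ |t|}) / (B + 1), so p ≥ 1/(B+1)). The
permutation unit is per-scaffold read fractions within a bin — the only
replicate structure the data model supports.

# The synthetic community generator

The generator exists so every stage can be scored against known ground
truth. Its defaults describe the reference community used throughout the
tests:

| parameter | default | rationale |
|---|---|---|
| genomes | 4 × 2 Mbp | the scale of the flavobacterial genomes being binned |
| composition model | order-2 Markov chain, independent random transitions per genome | produces the k-mer signal binning exploits without modelling real genomes |
| scaffolds | 5–20 kb slices | the post-filter scaffold size range |
| read length | normal, mean 1,008 bp, sd 150 | Sanger clone reads |
| samples | 3 winter + 3 summer sites | two seasons, six sites, six samples |
| reads per sample | 800 | desk-scale; enough for binomial recovery of the abundance matrix |
| abundance | genome-specific seasonal profiles (summer-skewed to winter-skewed) | creates the seasonal contrasts biogeography measures |
| planted CSCGs | 199 families, one copy per genome | matches the size of the reference CSCG set |
| errors | substitutions at 10⁻³; 97% of bases ≥ Q30 | Sanger-appropriate; implies a visible sub-Q30 tail |

Planted variants are stop-free coding sequences spliced into a scaffold;
each non-reference haplotype differs from haplotype 1 by exactly the
requested number of synonymous and nonsynonymous point changes
(verified per codon against the genetic code), at positions distinct
across haplotypes, and its reads span the full CDS and are error-free so
recovery tests are exact. Haplotype reads carry the planned
summer-fraction labels.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: chimeric reads and indels, cloning
and coverage bias, conserved regions shared between genomes (real
inter-genome k-mer correlation is higher than between independent Markov
chains, so real binning purity will be lower), assembly errors, and reads
spanning scaffold joins. Generation is byte-identical under a fixed seed.

# Problem sizes and numerical conventions

The test suite exercises the full reference community (4 genomes × 2 Mbp,
seed 42) for binning recovery and subdivision, 1,000 random pileups
against a brute-force SNP oracle, 100 replicate ω = 0.2 codon simulations
of 200 codons each, and exhaustive 5+5 permutation enumeration — all
chosen to complete in well under a minute each on one CPU. Coordinates
are 0-based half-open everywhere inside the package; file formats convert
at the boundary. Read alignments travel as TSV rather than SAM/BAM:
Sanger clone mapping predates those conventions, the generator controls
the schema, and the table carries sample/season labels that SAM would
push into tags.

# Known limitations

* Composition binning assumes compositionally distinct genomes; closely
  related strains will merge (the subdivision loop mitigates, but only
  down to what the dendrogram separates).
* The identity pass-through in place of between-pass re-assembly means bin boundaries are only as good as the input scaffolds.
* NG86 underestimates dN/dS under strong transition/transversion bias
  compared with ML codon models; conclusions here are screening-level
  (purifying vs not, saturated vs not).
* Track reconstruction is exact only when adjacent SNP pairs are spanned
  by reads; sparse coverage degrades to `undetermined` by design.
* The permutation test treats per-scaffold fractions as exchangeable
  replicates; spatial autocorrelation between samples is not modelled.
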