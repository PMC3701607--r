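---
title: "Methods: contrasting toxin and nontoxin molecular evolution between two venom-gland transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrasting toxin and nontoxin molecular evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxdiverge)
```

# The scientific problem

Rattlesnake venoms fall into two broad phenotypes: type I venoms rich in
metalloproteinases that cause hemorrhage, and type II venoms dominated by
neurotoxic heterodimeric phospholipases (crotoxin homologs). `toxdiverge`
implements a desk-scale pipeline for asking, with two congeneric
venom-gland transcriptomes, two questions:

1. **Expression**: how differently are toxin classes expressed between the
   two species, and how conserved is nontoxin expression?
2. **Sequence evolution**: are toxin genes evolving faster than the
   genomic background, and is the gene-family history of the major toxin
   classes one of lineage-specific duplication and loss?

The crucial methodological idea is the *nontoxin null distribution*:
thousands of orthologous nontoxin pairs from the same two transcriptomes
provide an internal genome-wide null for pairwise substitution rates, so
toxins can be judged against the genome they live in rather than against
an external expectation.

# Pipeline stages and their models

## Read merging

Paired-end reads from short fragments overlap at their 3' ends. A pair is
merged by reverse-complementing the mate and scanning candidate overlap
lengths (default minimum 10 nt); among candidates whose mismatch fraction
is at most 0.1 the one with fewest mismatches wins, ties to the longest.
`N` bases are mismatch-neutral. Quality recombination treats phred scores
as approximately additive log-evidence: agreeing overlap bases get
`min(q1 + q2, 93)`, disagreeing bases keep the higher-quality base with
quality `|q1 - q2|` (on an exact tie, the forward-read base at quality 2).
These two thresholds are exposed because the merging tools this mirrors do
not publish fixed values; both defaults are deliberately permissive for
50-nt overlaps at per-base error rates below 1%.

## Expression as read percentages

Composite reads are mapped back to transcripts with a k-mer-seeded,
ungapped matcher (identity = matching bases / read length, threshold 0.95,
mirroring a 95% minimum match percentage). Reads tying across distinct
transcripts are counted *ambiguous* and discarded rather than split:
toxin transcripts are pre-clustered at 1% nucleotide divergence precisely
so that ~150-nt composites map uniquely. Abundance is compositional — the
percentage of all reads assigned to a cluster — with a second column
giving the percentage of toxin-assigned reads, which is how the published
toxin tables are laid out. The row-wise ratio of the two columns recovers
the overall toxin fraction of the library, a useful consistency check on
any printed table.

Cross-species nontoxin expression is compared by ordinary least squares
of one species' counts on the other's. Equal read subsamples make raw
counts comparable. A single outlier may be removed automatically: the
point with the largest Cook's distance, if it exceeds 4/n — a
formalisation of removing one visually dominant point — and both fits are
always reported.

## Toxin clustering

Single-linkage clustering with an edge whenever the pairwise p-distance
(mismatches over ungapped aligned columns) is *strictly* below 0.01. The
strict inequality and the single-linkage reading follow the criterion
"grouped whenever less than 1% divergent" taken literally. Alignment is
global with affine gaps (match 5, mismatch -4, gap open -10, extend -1)
computed by `Biostrings::pairwiseAlignment`; a gap run of length L costs
`open + L*ext`.

## Orthology by dual reciprocal best hits

Each sequence of each species is searched against the other species in
two modes: nucleotide (the full transcript including untranslated
regions) and protein (the translated coding region). A pair is an
ortholog only if the two sequences are each other's best hits in *both*
modes, all four searches under an E-value cutoff of 1e-6. Mitochondrial
sequences are excluded; coding regions with internal stops are skipped.

The search itself is self-contained: exact k-mer seeds (k = 11 nt, 4
protein) nominate candidate subjects, Smith-Waterman local alignment
scores them, and significance uses ungapped Karlin-Altschul statistics,
`E = K m n exp(-lambda S)`. `lambda` is the positive root of
`sum p_i p_j exp(lambda s_ij) = 1`, solved by bracketed root-finding to
1e-12; `K` defaults to the published ungapped constants (0.62 for the
+1/-2 nucleotide system, 0.13 for BLOSUM62). At a 1e-6 cutoff the exact
value of K is immaterial — a decade of slack separates true orthologs
from noise in every synthetic experiment — which is why computing K
exactly was not worth its complexity.

## Pairwise substitution rates (NG86)

Coding pairs are aligned at the protein level and the gaps mapped back
onto whole codons, so gaps never break frame. Alignments with more than
24 gapped nucleotide positions are excluded outright — such pairs are more
likely to contain annotation errors than genuine orthology.

Rates use the Nei-Gojobori (1986) counting method. Per codon, each
position contributes a synonymous site fraction equal to synonymous
single-nucleotide changes over non-stop changes; differences between two
codons are averaged over all orderings of the differing positions,
excluding pathways through stop codons (if every pathway is blocked, all
orderings are used with stop-crossing steps counted nonsynonymous —
declared explicitly because NG86 variants differ here). Proportions are
corrected with Jukes-Cantor, `d = -(3/4) log(1 - 4p/3)`, with `p >= 3/4`
reported as saturated.

Two dS windows control interpretation:

* `dS < 0.001` — too little synonymous signal for a stable ratio; dS and
  dN are kept but omega is suppressed.
* `dS > 0.1` — implausibly divergent for two congeners, flagged as a
  likely spurious ortholog (often a mispaired paralog) and excluded from
  all three analyses.

A deliberate modelling deviation: maximum-likelihood codon models are
replaced by NG86 + JC. The original analysis this mirrors used an ML
implementation whose settings are not printed, so bit-compatibility was
unattainable regardless; counting is transparent, dependency-free, and at
`dS <= 0.1` the difference is small. One bias matters and is measured in
the test suite: unweighted NG86 ignores transition/transversion bias, so
with a transition-biased generating process (kappa = 2) omega is
underestimated by roughly 0.05-0.09 at omega 0.5-1.0. Parameter-recovery
validation therefore runs the generator at kappa = 1, where the counting
model matches the process; the toxin-vs-nontoxin *contrast* is validated
at kappa = 2, because ordering is unaffected by the shared bias.

## Exceedance statistics

For each statistic (dN/dS, dN, dS) the nontoxin values form an empirical
null; the threshold is the 95th percentile computed with linear
interpolation between order statistics (`quantile` type 7 — conventions
differ by at most one rank and the choice is declared). Toxin values
*strictly* greater count as exceedances; under the null the expected
count is `(1 - q) * n_toxins` (1.45 at n = 29, 1.5 at n = 30), and an
exact binomial tail probability accompanies the observed count. Group
comparisons use the Wilcoxon rank-sum test, exact when the smaller sample
has at most 8 values without ties, otherwise the tie- and
continuity-corrected normal approximation. No multiple-testing correction
is applied across the three statistics, by design — dS serves as the
negative control for dN rather than an independent hypothesis.

## Duplication-loss reconciliation

Toxin gene trees are rooted with an outgroup and reconciled against the
known three-taxon species tree by LCA mapping: each gene node maps to the
species-tree LCA of its descendants' species, computed in post-order. A
node is a duplication iff it maps to the same species node as one of its
children. Losses on the edge to child `c` number
`depth(M(c)) - depth(M(g)) - 1` below a speciation and
`depth(M(c)) - depth(M(g))` below a duplication, and each loss is
attributed to the species branch whose lineage disappeared, enabling
per-species statements like "one loss in species A". The test suite
verifies that this LCA reconciliation attains the brute-force minimum of
D + L over all ancestor-consistent mappings, which is the parsimony
guarantee.

Gene-tree *inference* is intentionally out of scope: trees are inputs
(newick), and a neighbor-joining builder is provided only so synthetic
end-to-end runs are self-contained. Multifurcating gene trees are
rejected rather than silently resolved.

# The synthetic-data generator

Because the study's raw data live in external archives, every stage is
validated against a generator with complete ground truth. It emulates:

* two congeneric ingroup species (A, B) plus an outgroup, on a species
  tree `((A:0.015, B:0.015):0.085, Out:0.1)` whose branch lengths are
  expected substitutions per codon at omega = 1 — giving ingroup
  synonymous divergence near 1%, the regime where ratio estimation is
  hardest and the dS windows matter;
* 150 shared nontoxin genes (order 10^2) with omega 0.18, conserved
  lognormal expression (between-species noise sd 0.2 on the log scale);
* 16 toxin families named for the venom toxin classes, with omega 0.4-1.0
  (mean 0.6) undergoing birth-death duplication/loss along the
  species tree (each birth a duplication, each death a loss, tallied per
  species branch as ground truth); family expression shares shifted
  between species by lognormal factors (sd 1.5), toxins drawing 41% of
  all reads;
* 100-nt read pairs from 150-nt fragments (3' overlap 50 nt), per-base
  error 1e-4, constant phred scores at `round(-10 log10(error_rate))`.

Codon sequences evolve by exact per-site Gillespie simulation of a
GY94/M0-style process: neighbour rates kappa for transitions, times omega
for nonsynonymous changes, zero into stops; rates are normalised so the
mean total rate over the 61 sense codons at omega = 1 equals 1, which
defines the branch-length unit. Ancestral sequences are uniform over
sense codons (no base-composition model is claimed). Untranslated regions
are random per gene with simple per-site divergence between species.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: indels within coding sequences, GC or
positional composition bias, coverage-dependent error profiles, chimeric
or partial transcripts, allelic variation within a species, and
assembly artifacts. The generator validates the estimators, not the
upstream assembly.

Determinism: every public generator entry point is driven by the config
seed, and pipeline reruns with the same config produce byte-identical
output files (hash-verified in the manifest).

# Numerical choices and degeneracies

* Alignment tie-breaking is delegated to the alignment engine and is
  deterministic; only scores are contract-level.
* Best-hit ties break by higher raw score, then lexicographic subject
  identifier.
* Cluster representatives are the longest member, ties lexicographic.
* `exceedance > threshold` is strict; equality does not count.
* Zero mapped reads, empty databases, all-gap comparisons, zero predictor
  variance, and stop-codon inputs raise immediate errors naming the
  offender; saturation (p >= 3/4) is flagged, not raised.
* Percentages are kept at full precision internally and rounded to three
  decimals only in the written reports.

# Problem sizes used in validation

The shipped tests and reproduction script run entirely on synthetic data
at deliberately desk-scale sizes: recovery experiments use 30-kb coding
pairs over 20 seeds; the toxin/nontoxin contrast uses 30 toxin against
1,600 nontoxin pairs of 450 nt over 20 seeds; reconciliation is checked
against brute force on 200 random gene trees of up to 8 leaves; ortholog
recovery uses 30 planted pairs plus 10% singletons over 10 seeds; the
end-to-end pipeline runs with 40-150 nontoxins and a few thousand read
pairs. These sizes were chosen so each property is tested with comfortable
statistical margins while the whole suite stays fast on a single CPU.

# Known limitations

* NG86 underestimates omega under transition bias (quantified above);
  rate *contrasts* are robust to this, absolute omega values near 1
  should be read with that bias in mind.
* The ungapped Karlin-Altschul E-values are compatible-in-spirit with,
  not bit-identical to, gapped search tools.
* Reconciliation assumes a correct, rooted, binary gene tree; with real
  inferred trees, weakly supported nodes propagate directly into event
  counts.
* Duplication-loss events hidden by subsequent loss are unidentifiable;
  estimated counts are lower bounds, exact only for loss-free histories
  (asserted on simulations).
* Compositional (percentage) expression cannot distinguish up-regulation
  of one class from down-regulation of the rest; the cross-species
  regression is on equal-sized read subsamples for exactly this reason.
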