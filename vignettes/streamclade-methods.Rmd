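---
title: "Models and methods behind streamclade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind streamclade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(streamclade)
```

streamclade analyses clades of streamlined marine prokaryotes sampled as
single-amplified genomes (SAGs): how genomes cluster into genera and
genomospecies, how abundant each cluster is across metagenomes, how
reduced the genomes are, and how gene content and core-gene sequence
diverge under intrapopulation homologous recombination. This vignette
explains the models, the tunable parameters, the numerical choices, and
what the synthetic-data generator does and does not emulate.

## The recombination-driven delay model

The statistical heart of the package relates two distances between a pair
of genomes: the core-gene sequence divergence *s* (substitutions/site,
Jukes–Cantor corrected) and the gene-content divergence *g* (expected
gains + losses per gene). If *m* denotes the latent "true" divergence of
the pair (a proxy for time), homologous recombination inside a cohesive
population keeps overwriting early substitutions, so observed sequence
divergence lags behind:

$$ s(m) = m - \Delta\,\bigl(1 - e^{-m/\Delta}\bigr), \qquad g(m) = r\,m $$

* `delta` (Δ, substitutions/site) is the *recombination delay*: the
  asymptotic number of substitutions per site that never becomes visible
  because recombination erased them. `m - s(m)` increases monotonically to
  Δ. Δ = 0 recovers clock-like divergence (s = m).
* `r` (events per gene per substitution/site) is the gene
  turnover-to-substitution ratio of the *linear regime*, where
  g ≈ r (s + Δ).

Two regimes follow: a *bound regime* at small *m* (s ≈ 0 while g grows up
to ≈ rΔ — genomospecies stay sequence-cohesive while swapping genes) and
a *linear regime* at large *m*. `fit_delay_model()` reports
`breakpoint_s = s(Δ)`, the observed divergence at which the latent
divergence equals the delay, as a regime-transition diagnostic.

The exact functional form of published delay models varies; this
two-parameter saturating-erasure form was adopted because it reproduces
both fit-level quantities that such analyses report — the linear-regime
slope r and the extrapolated delay Δ — with the fewest assumptions.

### Fitting

For each observed s the monotone s(m) is inverted by a damped Newton
iteration (`m ∈ [s, s + Δ]`, tolerance 1e-13), and the residual sum of
squares in g is minimised over (r, Δ). For fixed Δ the optimal r has a
closed form, so the optimisation is one-dimensional in Δ: a 41-point
grid up to `max(5 Δ0, 2 max(s), 1)` followed by golden-section
refinement (tolerance 1e-10). Initialisation follows the linear regime
(slope and extrapolated intercept of the upper-quartile-s pairs).

Residuals are taken on the **log scale by default**. Distance estimates
carry multiplicative (relative) error, and under lognormal noise the
log-residual sum of squares is the likelihood-consistent objective; in
simulation it recovers Δ with ≈ 2 % median bias where absolute residuals
show ≈ +10 %. `objective = "linear"` provides plain least squares in g;
pairs with g = 0 or s = 0 carry no log-scale information and are dropped
from the log objective (the fit falls back to linear residuals when
fewer than three informative pairs remain). Data with all s ≈ 0 cannot
identify Δ and are flagged `non_identifiable` rather than fitted.

## Alignment primitives

All identity computations share one convention: match +1, mismatch −1,
linear gap −2; identity = matches / alignment columns (gaps included);
N/X never count as matches. Three kernels cover the use cases:

* **Full Smith–Waterman** for desk-scale pairs (the exactness reference;
  property tests compare scores against an independent implementation).
  Co-optimal local alignments can differ in column count at equal score,
  so identity comparisons in tests allow a small band for short noisy
  alignments.
* **Seeded banded extension** for genome-scale targets: exact 13-mer
  seeds vote for diagonals, the top diagonals (at least 1/8 of the best
  vote) are extended by banded DP (default band 16). This is a desk-scale
  replacement for BLASTN; word size and gap scores of any particular
  BLAST release are not reproduced.
* **Banded fit alignment** for protein clustering: the shorter sequence
  is aligned end-to-end into the longer around the best shared-3-mer
  diagonal (cd-hit-style). Identity-based local scoring cannot report
  long alignments below ~50 % identity (the score turns negative), so
  orthology at the 30 % floor requires this global-style kernel. The
  word filter (at least two shared 3-mers on the winning diagonal)
  rejects ~94 % of unrelated pairs and loses well under 1 % of true
  pairs at the floor; single-linkage clustering recovers most of those
  through other family members.

## ANI and ranks

`ani_pair()` implements the fragment convention associated with the
standard ANIb tools: 1,020-bp fragments, fragments kept when they align
at ≥ 30 % identity over ≥ 70 % of their length, ANI = two-way mean of
kept-fragment identities. Because each fragment reports its best local
alignment, measured ANI sits a few points above `100 × (1 − divergence)`
at high divergence — the familiar behaviour of fragment-based ANI, which
is also why inter-genus pairs cluster near "~70 % ANI" in published
surveys. Pairs whose fragments all fail the filter are *undefined* and
enter clustering as ANI 0.

`cluster_ranks()` cuts one average-linkage dendrogram (distance
100 − ANI) at the genus (70), genomospecies (90) and species (95)
thresholds; cuts of a single tree are automatically nested, and labels
are ordered by each cluster's lexicographically smallest genome id so
they do not depend on input order.

## Recruitment statistics

Reads pass QC when mean Phred ≥ 30 (the per-base vs mean semantics of
published pipelines differ; mean is used and configurable), length ≥ 50
and no ambiguous bases. The annotated rRNA operon (rRNA genes merged
within 1 kb, ±500 bp) is masked by overwriting with N before alignment,
so conserved operon hits can neither map nor count toward the effective
genome length. Each read keeps its best hit (ties: lowest target start,
then "+"). RPKG = hits / (kb of effective genome × Gb of metagenome);
presence requires RPKG ≥ 5 (the threshold is inclusive) *and* footprint
coverage > 70 % at the abundance cutoff (≥ 98 % identity / ≥ 50 nt).
ANIr averages hit identities at the permissive cutoff (≥ 80 % / ≥ 50 nt)
and 1 %-bin histograms carry the 95 % species threshold as an attribute.
Whether metagenome size is counted before or after QC is a config
choice; QC'd size is the default.

## Pangenome, gene-content distances

Genomospecies with at least five genomes are dereplicated at 70 %
identity (greedy, length-descending, longest member representative);
ortholog families across units are single-linkage components at 30 %
identity over ≥ 75 % of the shorter sequence. Coverage is measured on
the shorter sequence; the fit kernel aligns it end-to-end, so the
identity threshold does the real work — a deliberate, documented
difference from tools that also bound the length ratio. The core is the
set of families present in all units, and `core_fraction_of_avg_genome`
divides the core count by the mean per-unit family count.

Gene-content distances map each family's presence/absence onto a guide
tree by Fitch parsimony with a deterministic most-parsimonious
reconstruction (down-pass state sets; top-down pass keeps the parent
state when allowed, preferring absence otherwise). Per-branch events are
summed over families and leaf-to-leaf path sums are divided by the mean
family count per unit — the normalisation that makes g "events per
gene"; published analyses do not print their units, so this choice is
flagged. Near the orthology floor a deep family can split into
genus-private families, which inflates deep-branch event counts; the
delay-model fit on fully mechanistic simulations therefore recovers the
regime structure faithfully but can overestimate the end-to-end slope.

Sequence distances use Jukes–Cantor on the concatenated single-copy-core
alignment (saturation at p ≥ 0.75 is an error, never extrapolated).
Star alignment places each member into the longest member's frame by
best-alignment offset (no internal gaps; core genes in the simulator are
indel-free, and real-length mismatches are end-padded), and columns with
more than 90 % gaps are dropped. NJ trees come from the standard
agglomeration with column-bootstrap support.

## Islands and composites

Universal single-copy families act as synteny anchors; an anchor
adjacency shared by all genomes whose cargo family sets overlap at
Jaccard ≤ 0.5 (boundary inclusive) is a flexible-island call.
tRNA hallmarks are exact occurrences of a tRNA's 3′-terminal 15 bp
(configurable) on the same strand within 100 kb downstream; at 15 bp the
expected number of chance hits per tRNA is L·4⁻¹⁵ ≈ 10⁻³ on a 1-Mb
genome, so exact matching is both sensitive for recent insertions and
essentially false-positive-free. Degenerate (older) repeats are out of
scope.

Composite reconstruction enforces the three group rules (> 99 % pairwise
ANI, ≥ 5 SAGs, per-position fragment coverage ≥ 2). The largest SAG is
the tiling reference — tiling, not re-assembly, is the documented
reading of "coassembly" here — and the consensus is majority-rule with
ties to the reference base. Under-covered positions are masked to N (and
reported as intervals) rather than excised, so coordinates remain
usable. Placements whose alignment contains indels are skipped (the
consensus is gapless; at > 99 % ANI this loses essentially nothing).
Rotation to *dnaA* assumes circularity, reverse-complements first when
the gene is on "−", and drops any gene that would span the new junction
(with a warning).

## The synthetic clade generator

Two generators serve different purposes. The *phenomenological*
generator (`simulate_pair_divergences()`) draws (s, g) pairs directly
from the delay model with multiplicative lognormal noise (mean 1); it is
the reference condition for estimator testing because the published
(r, Δ) are fit-level quantities — this decouples estimator validation
from simulator calibration. The *mechanistic* generator
(`simulate_clade()`) evolves gene-resolved genomes along a fixed
genus / genomospecies / strain hierarchy:

* **Divergence strata.** Per-branch substitution fractions are chosen in
  the Jukes–Cantor eigenvalue domain so pairwise divergence composes
  exactly to the targets (defaults 0.12 / 0.30 / 0.62 within
  genomospecies before recombination, within genus, between genera).
  With fragment-ANI inflation these yield measured strata of ≈ 99.8 %,
  ≈ 80 % and ≈ 61 % — each ≥ 5 ANI points from the rank thresholds, so
  partition recovery is exact by construction.
* **Purifying-selection emulation.** 80 % of coding substitutions go to
  third codon positions, keeping cross-genus protein identity above the
  30 % orthology floor (a neutral model would drive amino-acid identity
  below it at these depths). Replacement bases follow the genome's
  stationary composition so GC (default 32.5 %) does not drift.
* **Gene turnover.** Poisson gains + losses at rate r × branch length ×
  gene count (default r = 0.08); gains draw from a fixed accessory pool
  (pool gene = family truth), losses hit accessory genes only — core
  genes are treated as essential.
* **Recombination.** On terminal branches, up to 60 proposed events per
  branch each succeed with probability exp(−m/decay) (decay 0.25) and
  restore a 10-gene tract to the genomospecies-ancestor sequence. With
  the defaults this homogenises ≈ 90 % of the genome, producing the
  bound regime: near-zero observed s at substantial latent m while gene
  content keeps turning over.
* **Architecture.** ~97 % gene density with few-bp median spacers,
  operon-like strand runs, tRNAs, a single rRNA operon placed just after
  the terminus, and a replichore GC-skew bias (default 0.12) flipping at
  mid-genome.
* **Event log.** Every substitution block, gain, loss and recombination
  event is logged with a replayable payload; `replay_clade()`
  reconstructs each leaf byte-for-byte, which is the primary correctness
  oracle for the simulator itself.

What the simulator does *not* emulate: codon usage and amino-acid
substitution matrices, indels inside core genes, rearrangements and
inversions, varying gene lengths within a family, selection beyond the
core-immunity and third-position heuristics, chimerism/contamination of
real SAGs, and read quality-score profiles (simulated reads carry
uniform Q40). Passing tests therefore demonstrate correctness of the
computations under a clean, known-truth regime — not robustness to every
artefact of real single-cell data.

## Problem sizes and determinism

Test and example workloads use toy genomes of ~20–100 kb with 25–150
genes and clades of 8–12 genomes; these sizes exercise every code path
while keeping the default suite fast, and all algorithms scale to
megabase genomes (the ANIr example recruits 20,000 reads against 1 Mb).
Every stochastic routine takes an explicit seed; the pipeline driver
threads a single config seed through all stages and stamps every output
with the package version, the seed and a config hash, so reruns are
byte-identical.
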