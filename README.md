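# streamclade

Comparative ecogenomics of streamlined marine prokaryote clades sampled as
single-amplified genomes (SAGs). The package re-implements, as a tested R
pipeline, the analyses used to characterise low-GC, small-genome marine
clades with genus / genomospecies population structure:

- **ANI and rank clustering** — fragment-based average nucleotide identity
  (1,020-bp fragments, fragments kept at ≥30 % identity over ≥70 % of
  their length, two-way mean) and average-linkage clustering at the
  conventional rank thresholds (genus ≈ 70 %, genomospecies 90 %, species
  95 % ANI).
- **Metagenomic recruitment** — read QC (mean Phred ≥ 30, ≥ 50 bp, no
  ambiguous bases), best-hit recruitment with rRNA-operon masking, RPKG
  (reads per kb of genome per Gb of metagenome), presence calls
  (RPKG ≥ 5 and genome coverage > 70 % at ≥ 98 % identity), read-based ANI
  (ANIr, ≥ 80 % identity over ≥ 50 nt) and 1 %-bin identity histograms.
- **Streamlining metrics** — GC content, coding density, intergenic
  spacers (signed), paralog counts by iterative 90→30 % identity
  clustering, an operon heuristic, and the cumulative GC-skew
  origin/terminus signal.
- **Pangenome** — per-genomospecies protein dereplication at 70 %
  identity (at least five genomes per genomospecies), ortholog families
  across units at 30 % identity over 75 % of the shorter sequence
  (single linkage), core/accessory partitioning.
- **Recombination-delay model** — the core statistical model: for a pair
  of genomes with latent true divergence *m*, intrapopulation homologous
  recombination erases early substitutions so that observed core-sequence
  divergence is

      s(m) = m − Δ (1 − exp(−m/Δ)),

  while gene content keeps turning over linearly, *g(m) = r·m*. For small
  *m* this produces a *bound regime* (s ≈ 0 while g grows, up to ≈ r·Δ);
  for large *m* a *linear regime* g ≈ r·(s + Δ). `fit_delay_model()`
  recovers (r, Δ) by nonlinear least squares, inverting the monotone s(m)
  numerically and profiling r out in closed form.
- **Gene-content distances** — Fitch parsimony of family
  presence/absence on a guide tree, per-branch gain/loss events summed
  along leaf-to-leaf paths, normalised by the mean family count per
  genome; sequence distances are Jukes–Cantor on the concatenated
  single-copy core alignment, with neighbour-joining trees and column
  bootstrap.
- **Genomic islands** — flexible-island calls from universal single-copy
  anchor synteny (cargo Jaccard ≤ 0.5), and tRNA 3′-fragment direct-repeat
  hallmarks of site-specific cassette integration.
- **Composite genomes** — reconstruction from groups of SAGs under three
  rules (all pairwise ANI > 99 %, at least five SAGs, every emitted
  position covered by ≥ 2 fragments), with dnaA rotation.
- **Synthetic clade simulator** — `simulate_clade()` evolves
  gene-resolved genomes along a genus/genomospecies/strain hierarchy with
  substitutions, Poisson gene gain/loss, within-genomospecies
  recombination and cassette insertion, logging every event so that
  `replay_clade()` reproduces each leaf byte-for-byte. Every stage of the
  pipeline is therefore testable against known truth without downloads.

## Worked example

```r
library(streamclade)

# simulate a small clade: 2 genera x 2 genomospecies x 2 strains
cl <- simulate_clade(sim_params(core_genes = 25, accessory_pool = 15,
                                trna_count = 2,
                                strains_per_genomospecies = 2, seed = 31))

# ANI and ranks
ani <- ani_matrix(cl$genomes)
cluster_ranks(ani)
#> # A tibble: 8 x 4
#>   genome_id genus genomospecies species
#> 1 G1.1-01   G1    G1.1          G1.1.1
#> 2 G1.1-02   G1    G1.1          G1.1.1
#> 3 G1.2-01   G1    G1.2          G1.2.1
#> 4 G1.2-02   G1    G1.2          G1.2.1
#> 5 G2.1-01   G2    G2.1          G2.1.1
#> 6 G2.1-02   G2    G2.1          G2.1.1
#> 7 G2.2-01   G2    G2.2          G2.2.1
#> 8 G2.2-02   G2    G2.2          G2.2.1
```

Measured ANI sits near 99.8 % within genomospecies, ≈ 80 % within genera
and ≈ 61 % between genera (below the alignable range, reported as
`defined = FALSE`), so the rank cuts at 90 % / 70 % recover the simulated
partition exactly.

```r
# the delay model at the fitted scale of a streamlined marine order
pairs <- simulate_pair_divergences(r = 0.08, delta = 1, n = 500,
                                   noise_sd_rel = 0.05, seed = 1)
fit <- fit_delay_model(pairs)
glance(fit)
#> # A tibble: 1 x 6
#>        r delta residual_ss n_pairs breakpoint_s non_identifiable
#> 1 0.0792  1.03        2.03     500        0.379 FALSE
autoplot(fit)   # bound regime, fitted curve, regime breakpoint
```

Here `r` is the gene gain+loss rate per gene per core substitution/site
in the linear regime, and `delta` the recombination delay in
substitutions/site: the fit recovers the generating values (0.08, 1)
within a few percent from 500 noisy pairs.

```r
# read recruitment and intrapopulation diversity
ref <- random_genome(1e6, gc = 0.5, seed = 42)
gr <- genome_record("ref", tibble::tibble(replicon_id = "chr",
                                          sequence = ref, circular = TRUE))
reads <- simulate_reads(gr, 20000, read_len = 150, divergence = 0.03,
                        seed = 42)
prof <- recruit(gr, reads, min_identity = 80, min_len = 50,
                mask_rrna = FALSE)
anir(prof)
#> [1] 97.05516
```

Reads drawn from a population diverged 3 % per base recruit with a mean
identity of ≈ 97 % — the ANIr scale typical of a cohesive, low-diversity
population sitting above the 95 % species threshold.

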