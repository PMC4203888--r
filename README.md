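# dendrodiv

Cross-species divergence analysis for neuronal dendritic
transcriptomes assayed on species-specific microarray platforms.

Comparing expression between two rodent species is harder than an
ordinary two-group contrast: each species is measured on its own array
platform, so probe sets must first be tied together through an
ortholog map, and many-to-many probe-set/transcript relationships must
be collapsed into common quantification units before any statistic is
meaningful. `dendrodiv` implements that whole chain for dendrite-level
expression data, together with the rank-based divergence statistics,
molecular-evolution rate estimates and in situ fluorescence
quantification that put the expression divergence in context.

## What it computes

**Ortholog map and metagenes.** Reciprocal best blastn hits between
the two species' transcript sets (e-value ≤ 1e-5; ties broken by
bitscore, then subject id) give transcript orthologs. Probe sets are
anchored to transcripts by requiring ≥ 24/25 matched bases for a
probe's call and ≥ 9 of 11 probes agreeing on the same mRNA. Unique
1:1 matches pass through directly; the remaining many-to-many
relationships are resolved as connected components of the combined
match graph. Each retained component is a *metagene*, quantified per
species by the median of its member probe sets.

**Normalization.** Probe-level intensities are summarized per probe
set with the upper-decile (90th percentile) statistic; each array is
then median-centered and scaled by its 10th–90th percentile range, so
all arrays share a common scale (median 0, interdecile range 1).

**Divergence statistics.** Per metagene, a Welch two-sample *t* test
on normalized log expression with Benjamini–Hochberg FDR control at
0.1%; top-5% highly expressed sets by median expression rank across
replicates with per-species overlap fractions; an arcsine
(`asin √p`)-transformed one-sample *t* test for comparing overlap
percentages; and the rankmap: for each rank *k* in 31…500, the
fraction of one species' top-*k* genes whose orthologs are also within
the other species' top *k*, with exact Clopper–Pearson confidence
bands Bonferroni-corrected by a factor of 500.

**Molecular evolution.** Per-class (nondegenerate / twofold /
fourfold) site counts and transition/transversion proportions from
pairwise codon alignments feed Kimura two-parameter components
`A = ½ln(1/(1−2P−Q)) − ¼ln(1/(1−2Q))`, `B = ½ln(1/(1−2Q))`, combined
by the Li (1993)/Pamilo–Bianchi estimator:

    Ks = (L2·A2 + L4·A4)/(L2 + L4) + B4
    Ka = A0 + (L0·B0 + L2·B2)/(L0 + L2)

with a ≥ 100 amino-acid length filter, saturation ("degenerate
estimate") flagging, K2P distances for UTR alignments, and a
Kruskal–Wallis comparison of rates between gene groups.

**Imaging quantification.** Distance-binned dendrite/soma (D/S)
intensity-ratio profiles over 0–40 µm from traced transects,
per-dendrite median D/S summaries over 5–40 µm (proximal pixels
excluded), and a *t* test on log D/S ratios between species.

**Simulators.** Every input class — two-species replicate expression
with a planted divergent fraction, orthology hit tables with a known
metagene partition, codon pairs evolved under a K2P process with
selection strength ω and a full event log, and soma/dendrite transects
at a planted D/S ratio — can be generated from a seed, so the entire
pipeline is testable end to end without external data.

## Worked example

```r
library(dendrodiv)

# simulate a small two-species study: 9 vs 14 replicate arrays,
# 20% of 2000 orthologs divergent by 2 noise-SDs
sim <- simulate_two_species_expression(n_genes = 2000, n_reps_A = 9,
                                       n_reps_B = 14,
                                       divergent_fraction = 0.2,
                                       effect_size = 2, seed = 1)
tab <- welch_ttest_table(sim$expr_A, sim$expr_B, q = 0.001)
sum(tab$q_flag)                                  # flagged divergent

top_A <- median_rank_top_set(sim$expr_A, 0.05)
top_B <- median_rank_top_set(sim$expr_B, 0.05)
overlap_fraction(top_A, top_B, "A")              # top-5% overlap

pair <- simulate_codon_pair(n_codons = 2000, t = 0.2, omega = 0.2,
                            seed = 1)
est <- li_ka_ks(count_pairwise_substitutions(pair$seq_A, pair$seq_B))

tr <- simulate_transects(n_cells = 3, n_dendrites_per_cell = 3,
                         planted_ratio = 0.2, seed = 1)
ds <- summarize_transects(tr$transects, tr$soma)
```

Output:

```
genes flagged divergent at FDR 0.1%: 158
true positives among them: 158
top-5% overlap (A denominator): 0.446
concordance at rank 100: 0.48
Ka = 0.0424  Ks = 0.1905  Ka/Ks = 0.223
per-dendrite D/S ratios: 0.207 0.21 0.221 0.218 0.187 0.155 0.215 0.182 0.193
```

At FDR 0.1% every flagged gene is a true planted divergence (the
procedure trades sensitivity for an essentially clean discovery set);
the top-5% overlap and the rankmap concordance sit far above the
random level (0.05 and k/N) because 80% of genes share their baseline
between species; the ω = 0.2 codon simulation is recovered as
Ka/Ks ≈ 0.22; and the per-dendrite D/S summaries scatter around the
planted ratio 0.2.

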