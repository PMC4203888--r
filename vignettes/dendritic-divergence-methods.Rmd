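---
title: "Methods: cross-species dendritic transcriptome divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species dendritic transcriptome divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrodiv)
```

# The problem

Dendrites of CNS neurons maintain their own local pool of mRNAs, and
the question this package serves is how strongly that dendritically
localized transcriptome differs between two closely related rodent
species. The measurement design creates specific methodological
obligations: each species is assayed on its own array platform, with
different probe designs for homologous genes, so cross-species
comparison requires (i) a conservative ortholog map between the
platforms, (ii) a common expression scale, and (iii) statistics robust
to residual platform effects — which is why rank-based comparisons sit
alongside the parametric *t* tests throughout.

# Ortholog map and metagenes

Transcript orthologs are reciprocal best blastn hits at an e-value
threshold of 1e-5. Best-hit ranking is lowest e-value, ties broken by
highest bitscore, then lexicographically smallest subject id. The
last tie-break makes the map deterministic under permutations of the
hit table; genuinely ambiguous ties (identical e-value and bitscore
for distinct subjects) are resolved lexicographically rather than
discarded, a choice that errs toward retaining a pair and is
documented here because hit tables rarely carry exact score ties in
practice.

Probe sets anchor to transcripts in two stages. A probe's call is its
top blast hit, and the call counts only when the hit covers at least
24 of the probe's 25 bases (matched bases = alignment length −
mismatches). A probe set maps to a transcript when at least 9 of its
11 probes call it. For platforms with other probe-set sizes the
quorum generalizes to `ceiling(0.818 * n_probes)`, which reproduces
9-of-11 exactly; the per-probe constraint stays an absolute count
(default 24) because it reflects probe length, not probe-set size.

Unique 1:1 matches are emitted directly; everything else is collapsed
by connected components of the combined graph (ortholog pairs +
probe-set/transcript links), computed with `igraph`. A component is a
*metagene*; components containing probe sets from only one species are
dropped (no cross-species quantification is possible) with a logged
count. Per species, a metagene's expression is the per-array median
of its member probe sets, so single-member metagenes equal their
member exactly, and even-sized memberships use the mean of the two
central values (R's default median).

# Normalization

Probe-level intensities are summarized per probe set with the
upper-decile statistic (90th percentile of member probes, per array).
Each array is then median-centered and scaled by its 10th–90th
percentile range. Percentiles everywhere use linear interpolation
between order statistics (R quantile type 7); no convention was
prescribed, and this is the common default in scientific computing.
After normalization every column has median 0 and interdecile range 1
(asserted to 1e-9 in the tests), and the transform is invariant to
positive affine rescaling of an input column — the property that makes
arrays comparable. An array whose 10th and 90th percentiles coincide
has no defined scale and is rejected by name rather than silently
passed through. Inputs are assumed to be on a log scale already; the
package does not re-implement RMA-style background correction.

# Divergence statistics

**t test.** The per-metagene test is Welch's unequal-variance *t*:
replicate counts are unequal by design (9 rat, 14 and 5 mouse arrays),
which is exactly the situation where the pooled-variance test is
fragile. Rows with zero variance in both groups and equal means get
p = 1 (no evidence of difference), and zero-variance rows with
unequal means get p = 0 — the limit of the test as jitter vanishes.

**FDR.** Benjamini–Hochberg step-up control at q = 0.001 (0.1%),
computed via `stats::p.adjust`; a test is flagged iff its adjusted
p-value is at most q, which equals the classical step-up rejection
set (the unit tests pin this against an enumeration oracle).

**Top sets and overlap.** Genes are ranked within each replicate
(rank 1 = highest, average ranks on ties), the per-gene median rank
taken across replicates, and the `floor(0.05 N)` smallest median
ranks kept, expanding to include all rows tied at the boundary so the
set is order-independent. Overlap between two species' top sets is
reported with each species' own top-set size as denominator, which is
why the two directions can differ (the study's per-species overlap
percentages are asymmetric in the same way). Boundary-tie expansion
can make a top set slightly exceed `floor(0.05 N)`; the denominator
follows the realized set size.

**Arcsine test.** Overlap percentages are variance-stabilized by
`asin(sqrt(p))` before a one-sample two-sided *t* test against the
transformed reference overlap.

**Rankmap.** Both species' summary expression (median over
replicates) is ranked with average ties; for each k in 31…500 the
concordance is, among species-A genes of rank ≤ k, the fraction whose
ortholog has species-B rank ≤ k. Confidence bands are exact
Clopper–Pearson intervals at level 1 − 0.05/500: the exact interval is
used because at k = 31 the normal approximation is poor, and the
Bonferroni factor equals the number of ranks compared. With average
ties the number of genes at rank ≤ k need not equal k; the realized
count is the binomial denominator.

**Binomial proportions test.** The default variant is the pooled
z test without continuity correction (p = 1 at equal sample
proportions); chi-square (with continuity correction) and Fisher's
exact variants are exposed. For the reference SNP-count comparison
(29/54 vs 25/54) all variants agree the difference is far from
significant (z-pooled p ≈ 0.44), but no common variant reproduces the
originally printed bound of 0.78; the package documents this
discrepancy rather than matching a number it cannot derive.

# Molecular evolution

Site classes come from codon-position degeneracy under the standard
genetic code (`Biostrings::GENETIC_CODE`): nondegenerate when no
substitution at the position is synonymous, fourfold when all three
are, twofold otherwise. Three-fold degenerate positions (isoleucine)
are pooled with twofold, the standard convention. Stop codons,
gap-containing codon columns and codons with ambiguous bases are
skipped with a logged count.

Per codon pair, the class-i site count L_i is the mean of the two
sequences' counts, and a differing site contributes weight ½ to the
class it has in each sequence — the two sequences need not agree on a
position's class once they differ. Codons differing at more than one
position classify each differing site independently by its own
position (no pathway averaging); at rodent-scale divergence
(K ≈ 0.17) the bias from ignoring within-codon substitution order is
negligible relative to the sampling noise of per-gene estimates.

Transition (P_i) and transversion (Q_i) proportions per class feed
the Kimura two-parameter components, and Ka/Ks uses the Li (1993) /
Pamilo–Bianchi combination stated in the README: transitions at
twofold sites are synonymous, transversions non-synonymous. The
estimator's "degenerate estimate" condition — any required K2P
component saturated (1 − 2P − Q ≤ 0 or 1 − 2Q ≤ 0), or no sites in
the classes a rate needs — excludes the gene rather than producing an
undefined number. The rate table additionally applies a minimum
compared length of 100 amino acids; UTR alignments get a plain K2P
distance over non-gap columns, appropriate for short non-coding
regions. Group comparisons of rates use the Kruskal–Wallis rank test
with tie correction.

# Imaging quantification

A transect is a sequence of (distance, intensity) samples from the
dendrite path origin. The profile bins distances at 1 µm (the source
data are plotted as continuous curves; 1 µm is chosen to be below the
structure of interest while keeping several samples per bin) and
divides per-bin mean dendrite intensity by the **mean** soma
intensity. The per-dendrite summary divides the **median** in-window
(5–40 µm) dendrite intensity by the **median** soma pixel value:
"average median soma value" is read as the median soma pixel value
averaged over soma traces, and the median is kept as the robust
estimator on the dendrite side. Proximal pixels (< 5 µm) are excluded
from the summary to limit soma bleed-through. Dendrites with fewer
than 3 in-window samples are excluded with a logged reason. Species
are compared by a two-sided *t* test on natural-log D/S ratios, since
multiplicative noise is the natural error model for fluorescence
ratios; untransformed group means are reported alongside.

# Simulators: what they emulate, and what they do not

The expression simulator draws a shared per-gene baseline
(Normal(0, 1.5) on the log scale), plants a divergent fraction π of
genes with a species-B shift ±δ, and adds i.i.d. Gaussian replicate
noise σ. Defaults are the study's design: 9 vs 14 replicates,
π = 0.2, δ = 2σ, σ = 1. It emulates the statistical structure the
divergence tests assume — independent genes, homoscedastic Gaussian
log-scale noise — and deliberately not probe-level hybridization
physics, platform-specific probe biases, or inter-gene correlation.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated, not that real cross-platform data meet these
assumptions.

The orthology simulator generates true 1:1 transcript pairs with
reciprocal best hits, worse-scoring decoy hits, above-threshold noise
hits, and a many-to-many fraction of transcripts carrying two probe
sets — the mechanism that actually creates multi-member metagenes in
this pipeline (probe sets map to at most one transcript, and
reciprocal best hits form a matching, so components larger than one
pair arise through shared transcripts). Sub-threshold (23/25) probe
sets can be injected to exercise the per-probe filter.

The codon simulator evolves two descendants from a random sense-codon
ancestor under a K2P proposal process (transition probability
κ/(κ+2), default κ = 2) with non-synonymous proposals accepted with
probability ω and stop-creating proposals rejected; every accepted
event is logged with its site, class and type, so substitution
counting can be reconciled against the generator's own bookkeeping at
low divergence. The branch parameter t is the expected number of
proposed substitutions per site summed over both branches, i.e. the
neutral-equivalent divergence; realized divergence is lower under
ω < 1. Stop-codon rejection slightly depresses the neutral Ka/Ks
below 1 (it removes a class of non-synonymous proposals), which is
visible but within the ±0.1 recovery band the tests assert.

The transect simulator plants a D/S ratio r as the geometric mean of
per-dendrite ratios: each dendrite draws a log-normal multiplier
(log-sd 0.1 by default, 0.4 in the power analysis reproducing the
published probe contrast of 0.214 vs 0.088), and the distance shape is
normalized so its in-window median is 1 — hence with zero noise the
per-dendrite summary equals r exactly for every shape. Recovery is
therefore assessed on the geometric mean, the natural estimator under
multiplicative noise.

All simulators derive their randomness from explicit integer seeds;
the end-to-end pipeline writes byte-identical files when rerun with
the same seed, and the acceptance script derives all sub-seeds from
one root seed.

# Problem sizes and numerical tolerances

The test suite uses 5,000-gene expression simulations (100–200
replicate runs for calibration), a 3,839-gene universe for rank-based
checks (the size of the cross-platform tissue mapping the rank
analyses are designed around), 50 genes × 2,000 codons for rate
recovery, and 50 dendrites for imaging recovery — sizes at which
Monte-Carlo error is small relative to the asserted bands while the
suite stays fast. Exactness claims (oracle equivalence, planted
partition recovery, byte determinism) are asserted with no tolerance;
closed-form checks at 1e-12 relative; normalization post-conditions at
1e-9; Monte-Carlo quantities within explicit multiples of their
standard error.

# Known limitations

* The divergence machinery assumes a complete, normalized matrix;
  missing values are rejected, not imputed, because the analysis chain
  has no imputation step.
* The recovery rate of planted divergent genes at the default design
  (δ = 2σ, 9 vs 14 replicates, q = 0.001) is limited by the power of
  the Welch test at the very stringent FDR level: the expected
  noncentrality is ≈ 4.7 while the effective BH cutoff sits near
  2·10⁻⁴, so roughly half the planted genes are detected and the
  flagged set is essentially free of false positives. Recovering
  nearly all planted genes requires δ ≈ 2.5–3σ, as the property tests
  at δ = 3σ demonstrate.
* Ka/Ks is a pairwise counting estimator, not a likelihood codon
  model; it is the right tool at rodent divergence but saturates for
  distant pairs (such genes are flagged and excluded, not guessed).
* The imaging module consumes extracted transects; segmentation,
  tracing and background estimation are upstream concerns, with only
  a constant-offset background subtraction provided.
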