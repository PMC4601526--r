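---
title: "Methods: miRNA expression dynamics in the DNA damage response"
author: "mirddr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA expression dynamics in the DNA damage response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirddr)
```

# Scope and model

`mirddr` analyses changes in microRNA expression after DNA damage from
small-RNA sequencing with *technical* replication only: replicate
libraries prepared from the same RNA, no biological replicates. That
design choice pervades the statistics — the between-condition variation
that the tests model is counting (sampling) noise, not biological
variance — and every default below follows from it.

The pipeline has six stages: read quantification, count-based
differential expression, a robustness filter for DNA-damage-responsive
(DDR) miRNAs, genomic-context classification, cross-species p53 motif
ranking of miRNA regulatory regions, and preranked gene-set enrichment of
the DDR set on that ranking. A synthetic-data generator with complete
ground-truth bookkeeping backs the test suite.

# Quantification

Reads are adapter-trimmed at the left-most exact adapter occurrence, with
a terminal suffix/prefix overlap of at least `min_overlap` (default 6 nt)
accepted as adapter evidence; an empty insert is a rejection. Reads
shorter than 18 nt or longer than 30 nt are removed, as are low-complexity
(polyN) reads, defined here as mono-nucleotide fraction > 0.8 *or* a
homopolymer run of ≥ 15 nt — a definition chosen to catch adapter dimers
and poly(A) carry-over while retaining AU-rich mature miRNAs. Counting
requires 100% identity with a mature reference sequence (an optional end
tolerance admits short 5′/3′ overhangs; the default is strict). Reads
matching several identical mature sequences (e.g. paralogous arms)
increment all of them and are flagged ambiguous, so that the later
redundancy step — not the counter — decides which representative
survives. `N` bases never match. We match directly against the mature
reference rather than first aligning to a genome: at exact identity the
genome pass can only remove reads, and keeping the matcher self-contained
makes the round trip (simulated reads → counts) exactly testable.

# Differential expression

Normalization proceeds in a fixed order: (1) zero cells are replaced by a
pseudocount of 1; (2) miRNAs with an aggregate raw count below 100 across
all samples are dropped (strictly below; 100 is kept); (3) each sample is
scaled so that its miRNA-mapped total equals the mean raw library size.
Scaling to the *mean* library keeps counts on their native scale, so the
abundance threshold A ≥ 5 corresponds to ≈ 32 reads and the fold-change
threshold |M| ≥ 0.75 to a 2^0.75 ≈ 1.68-fold change — the count
equivalences quoted with the MA plots.

For a condition against its 0 h control, M and A are computed on
normalized merged counts, while the test runs on raw merged counts with
raw library sizes, because the exact test needs integers. The default
test is the two-sided exact test of the 2×2 table
[[x_t, L_t−x_t], [x_c, L_c−x_c]]: the sum of hypergeometric point
probabilities no larger than the observed table's. The implementation
exploits unimodality of the hypergeometric mass — the rejection region is
a left and a right tail whose boundaries are located by binary search and
summed with `phyper()` — making the test O(log support) and exact for
libraries of tens of millions of reads; the suite verifies it against
full enumeration (to 1e-12) and against `fisher.test()`. A binomial
alternative (x_t ~ Binomial(x_t+x_c, L_t/(L_t+L_c)), two-sided) is
provided and converges to the exact test as libraries grow. Correction
is Bonferroni with the number of miRNAs tested, applied per comparison
(the conservative, literal choice for this design; the correction scheme
is recorded in the output attributes). Significance requires
|M| ≥ 0.75 and A ≥ 5 (boundaries inclusive) and corrected p < 0.05
(strict).

Two caveats of total-count scaling are worth stating. First, it is
composition-sensitive: if one feature occupies a large fraction of the
library, its induction depresses the normalized abundance of everything
else (the test suite demonstrates this deliberately). Second, the exact
test treats all variation as sampling noise; with biological replicates
it would be anti-conservative, which is why dispersion-modelling
frameworks exist. Both are inherent to the method implemented, not
implementation artifacts.

# DDR selection

The robustness cascade keeps a miRNA when, in some cell line, (1) M has
the same sign at 4 h and 24 h (zero fails), and (2) the change is
significant at either time; and (3) overall the miRNA is significant in
at least two cell lines and/or two replicates. Redundancy is then
resolved: when both arms of one stem-loop pass, the higher-coverage arm
is kept (the star arm discarded); identical mature sequences collapse to
one representative, the lexicographically smallest id, for determinism.

Kinetic clusters are assigned by an explicit deterministic rule rather
than hierarchical clustering: direction is the sign of M at the time of
max |M|, the peak time is that time, and |M| ties go to 24 h (late
induction dominates the slower-responding cell line). The mapping of
(direction, peak) to the labels A–D is a preset (`cluster_presets()`)
because the two published label conventions differ between cell lines.
p53 dependence of a miRNA is called by contrasting the wild-type and
TP53-null backgrounds: dependent if significant in wild type while the
knockout shows no significant change and a residual |M| below half the
fold-change threshold; independent if significant with the same sign in
both; otherwise indeterminate. The half-threshold residual bound is a
package choice (no published cutoff exists) and is configurable.

# Genomic context

A locus is intragenic when fully contained in a same-strand annotated
transcript; with nested transcripts the smallest containing one is the
host (deterministic). Containment on the opposite strand is intergenic.
Grouping uses single-linkage chaining with a strict < 10 kb gap (a gap of
exactly 10,000 bp does not link), strand-agnostic, with components of
size ≥ 2 as clusters; the implementation rides on
`GenomicRanges::reduce()` and is property-tested against an all-pairs
union-find oracle. Category enrichment uses the same exact test as the
expression stage on the DDR/non-DDR × in/out-of-category table; loci
without annotation are reported separately and excluded from the tables.

# Motif ranking

Regulatory windows are delineated from three anchor rules (0-based
half-open, mirrored on the minus strand): [−5 kb, +500 bp) around
intergenic miRNA or cluster starts, [−4 kb, +2 kb) around host-gene TSSs,
and [−3.5 kb, −500 bp) around intragenic starts. An intragenic miRNA
therefore has two candidate regions, and its score is the maximum over
them.

PWM scanning computes log₂-odds against a zero-order background
(estimated from the scanned region set with pseudocount 0.01, or supplied)
at every position on both strands; windows containing `N` score −∞.
Homotypic CRM scoring slides a 500 bp window over the region, greedily
selects the best non-overlapping hits above a log-odds floor of 0 (any
PWM, either strand), and sums them; the region score is the maximum over
windows, floored at 0 so that every region is scored. This windowed
best-hit summation is a deterministic approximation of hidden-state CRM
scanners; it preserves the homotypic-cluster semantics (more
non-overlapping sites ⇒ monotonically higher score) and is testable
against an exhaustive oracle on short sequences.

Within each species, features are ranked by score (descending; the best
of N has normalized rank 1/N; ties share mean positions). Per-feature
rank vectors across species are aggregated by order statistics:

q = P(U₍₁₎ ≤ r₍₁₎, …, U₍ₙ₎ ≤ r₍ₙ₎)

for n independent uniforms, computed with the recursion
V_k = Σᵢ (−1)^{i−1} V_{k−i} r_{n−k+1}^i / i! over ascending sorted
ranks, q = n!·V_n — stable in double precision for n ≤ 20. Missing
species count as rank 1 (no evidence, no penalty beyond it). The final
score is −log q (natural log; the base is a monotone rescaling), and
final ties break lexicographically by feature id.

One calibration subtlety: q is a *joint* cumulative probability, and a
multivariate CDF evaluated at a random vector is not uniformly
distributed (only the univariate case is). Raw q values therefore rank
correctly but are not significance-calibrated. Where a calibrated
probability is needed, `calibrate_rank_aggregation()` maps the scalar Q
statistic through its Monte-Carlo null CDF — uniform under the null by
the probability integral transform, and a monotone transform, so the
ranking is unchanged.

# Preranked GSEA

Walking down the ranked list, a set member at rank i adds
|s_i|^p / Σ_set |s|^p (default p = 1) and a non-member subtracts
1/(N−N_hits); the ES is the running value furthest from zero (earliest
position on ties, which fixes the leading edge deterministically), and
the leading-edge/core members are the hits at or before a positive peak.
The running sum closes to zero by construction, and with p = 1 the ES is
invariant under uniform positive rescaling of the rank metric — both are
tested, and the statistic is cross-checked against an independent
implementation (fgsea) on random inputs. The permutation null draws
same-size random sets from the ranked ids (seeded, bit-reproducible);
NES = ES / mean(|same-sign null ES|) ("mean div"), the nominal p is the
fraction of same-sign null ES at least as extreme (zero exceedances
report 0), and FDR q follows the standard pooled sign-matched procedure.

# The synthetic-data generator

The generator emulates the study design, and its defaults are the study
conditions: 3 cell lines (one mammary epithelial line and a colorectal
line with its TP53-null derivative) × {0, 4, 24} h × 2 technical
replicates = 18 samples; 965 miRNAs (the count surviving the aggregate
filter); library sizes log-normal around 12 million miRNA-mapped reads
with CV 0.15 (the published per-library range). Baseline relative
abundances are log-normal (sdlog 2, spanning the orders of magnitude of
real miRNA libraries). Per condition, one "biological" draw per miRNA is
negative-binomial; the two technical replicates are independent binomial
thinnings of it, carrying the library-size variation — merging replicates
therefore re-assembles the biological draw, exactly the operation the
pipeline performs. The default dispersion is 0.001, i.e. near-Poisson:
with technical replication from one RNA sample, inter-sample
overdispersion is limited to library preparation, and this choice follows
from the replication design, not from any test outcome. Setting
dispersion to 0 gives exact Poisson for closed-form checks.

Spiked miRNAs follow archetypes A–D (induced/repressed × peak 4 h/24 h),
sized 23/24/4/31 as in the early-responding cell line, with a peak effect
of 2 log₂ units (4-fold) and an off-peak effect a third of it (same sign,
so the trend criterion is exercised); 75% of induced spikes are flagged
p53-dependent (mirroring the published ">70%") and have their effects
zeroed in the TP53-null line. Annotation geometry places ~50%/21%/23%/6%
of loci as intragenic-single/intragenic-clustered/intergenic-single/
intergenic-clustered, with intra-cluster gaps < 10 kb and all other gaps
≥ 20 kb, so context classification on generator output is exactly
checkable. Promoter simulation uses i.i.d. background at GC 0.41 over
1000 bp regions across 10 pseudo-species — a desk-scale proximal-promoter
choice; planted features receive 3 non-overlapping sites sampled from the
PWM (so planted scores vary realistically) in 60% of species.

What the generator does *not* model: sequencing error, GC and ligation
bias, isomiRs, biological replicate hierarchies, phylogenetic
correlation between species, and real promoter sequence composition.
Passing tests therefore demonstrate correctness of the computations and
calibration under the stated statistical model, not robustness to those
real-data phenomena.

# Problem sizes and numerical choices

The test suite runs the calibration properties at the study scale
(965 miRNAs, 12 M-read libraries, 20 seeds for spike recovery and null
calibration; 500 features × 10 species for the motif-ranking
calibration) and uses reduced sizes (≈150 miRNAs, 0.5 M reads, 5 species,
300 bp regions) for orchestration tests where only wiring is at stake —
these sizes are the package's choice of test granularity. Exact-test
ties use the customary 1 + 1e-7 relative slack; the running-score
zero-sum is asserted to 1e-9; PWM scans match a naive oracle to 1e-12.
Degenerate inputs error early: all-zero libraries, empty references,
empty PWM lists, out-of-range ranks, gene sets that are empty or cover
the whole list.

# Known limitations

* Total-count normalization is composition-sensitive (see above); no
  TMM/median-of-ratios alternative is provided because the method under
  study is total-count scaling.
* The exact test assumes sampling noise only; it is the right test for
  technical replication and anti-conservative beyond it.
* The CRM scorer's greedy non-overlapping selection can differ from an
  optimal-subset or hidden-state scorer on adversarial hit layouts.
* Cross-species aggregation treats species as independent rankings;
  phylogenetic non-independence would sharpen, not change, the machinery.
* The kinetic clustering is a two-time-point rule; richer time courses
  would need a different assignment.
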