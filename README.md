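# mirddr

Genome-wide miRNA expression dynamics in the DNA damage response (DDR),
from small-RNA sequencing reads to a ranked list of candidate direct p53
target miRNAs.

When human cells suffer DNA breakage (for example after ionizing
radiation), transcription-factor programmes — p53 chief among them —
reshape the expression of hundreds of microRNAs over the following 4–24 h.
`mirddr` implements the full analysis chain used to characterise such a
response from sequencing data, together with a seeded synthetic-data
generator that reproduces the study design (cell lines × time points ×
technical replicates, planted effect archetypes, planted promoter motifs)
so that every stage can be validated against known ground truth. It is
aimed at computational biologists analysing small-RNA count data with
technical (not biological) replication, and at anyone who wants a tested,
reusable implementation of the motif-ranking / enrichment machinery below.

## What it computes

1. **Quantification** — adapter trimming, length (18–30 nt) and
   low-complexity filtering, and exact-identity matching of reads against
   a mature-miRNA reference (`trim_adapter()`, `filter_reads()`,
   `quantify_exact()`).
2. **Differential expression** — per-sample library-size scaling with a
   pseudocount and an aggregate-count filter, then for each condition
   versus its 0 h control the MA statistics
   *M* = log₂(n_treat/n_ctrl), *A* = log₂((n_treat+n_ctrl)/2),
   a two-sided exact test on the 2×2 count table
   [[x_t, L_t−x_t], [x_c, L_c−x_c]] (or its binomial approximation),
   Bonferroni correction, and calls at |M| ≥ 0.75, A ≥ 5,
   corrected p < 0.05 (`run_diffexpr()`, `count_test()`).
3. **DDR selection** — a robustness cascade (consistent trend at 4 h and
   24 h, significance at either time, support in ≥ 2 cell lines and/or
   replicates), redundancy resolution (star-arm removal by coverage,
   identical-mature collapse), kinetic clusters A–D by direction and peak
   time, cross-cell-line set comparison, and p53-dependence calls against
   a TP53-null background (`robust_filter()`, `resolve_redundancy()`,
   `assign_kinetic_clusters()`, `p53_dependence()`).
4. **Genomic context** — intragenic/intergenic classification by
   same-strand containment in host transcripts, single/clustered
   classification by single-linkage chaining at a strict < 10 kb gap, and
   exact-test category enrichment (`classify_location()`,
   `classify_grouping()`, `category_enrichment()`).
5. **Motif ranking** — promoter-window delineation, PWM log-odds scanning
   on both strands, homotypic cis-regulatory-module scoring (best
   non-overlapping hit sum within a sliding window, floored at 0),
   per-species ranking, and cross-species aggregation by order
   statistics: q = P(U₍₁₎ ≤ r₍₁₎, …, U₍ₙ₎ ≤ r₍ₙ₎) with final score
   −log q (`crm_score()`, `rank_motif_features()`,
   `aggregate_order_statistics()`).
6. **Preranked GSEA** — running enrichment score (hit increment
   |s_i|ᵖ/Σ|s|ᵖ, miss decrement 1/(N−N_hits)), ES at the extremum,
   leading-edge ("core") membership, and permutation NES/FDR with a
   seeded gene-set null (`running_es()`, `gsea_preranked()`).

## Worked example

The package ships a published worked example: the 20 most highly induced
DDR miRNAs with their ranks and rank-metric scores in a genome-wide
ranking of N = 1531 miRNA regulatory features by p53 motif content.

```r
library(mirddr)
rl  <- ddr_example_ranked_list()
res <- running_es(rl$ids, rl$scores, rl$set)
```

This prints (via `res$ES`, `res$peak`, `res$leading_edge`):

```
ES = 0.67305356 at 0-based rank 101
leading edge: mir-34a, mir-34c, mir-486, mir-139, let-7a-2, mir-125b-1
```

The running score climbs while the top-ranked set members accumulate and
peaks at rank 101 with ES = 0.673; the six miRNAs at or before the peak
are the core (leading-edge) members — the candidates called direct p53
targets. A full synthetic run exercises every stage end to end:

```r
out <- run_pipeline(pipeline_config(sim = sim_config(seed = 17,
         n_mirnas = 150, library_size_mean = 5e5, n_species = 5,
         region_length = 300), gsea_n_perm = 200))
out$gsea[, c("set_id", "size", "ES", "NES", "p_nominal", "fdr_q")]
#>        set_id size        ES      NES p_nominal fdr_q
#> 1 ddr_induced   16 0.9625904 2.293473         0     0
```

Here the 16 robustly induced synthetic miRNAs (true planted archetypes)
are strongly enriched at the top of the planted-motif ranking — NES 2.29,
no permutation null as extreme — exactly the behaviour the analysis is
designed to detect; `out$log$p53` reports that 12 of the 24 assessed DDR
miRNAs lose their induction in the simulated TP53-null background.

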