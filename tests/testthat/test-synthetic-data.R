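small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_mirnas = 150, library_size_mean = 5e5,
             spike_sets = list(
               A = list(n = 6, effect = 2, p53_dependent_frac = 0.5),
               B = list(n = 6, effect = 2, p53_dependent_frac = 0.5),
               C = list(n = 2, effect = -2, p53_dependent_frac = 0),
               D = list(n = 6, effect = -2, p53_dependent_frac = 0)), ...)
}

test_that("count simulation is deterministic in the seed and distinct across seeds", {
  s1 <- simulate_counts(small_cfg(3))
  s2 <- simulate_counts(small_cfg(3))
  expect_identical(SummarizedExperiment::assay(s1$table, 1),
                   SummarizedExperiment::assay(s2$table, 1))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_counts(small_cfg(4))
  expect_false(identical(SummarizedExperiment::assay(s1$table, 1),
                         SummarizedExperiment::assay(s3$table, 1)))
})

test_that("the simulated design matches the study layout and spike construction", {
  sim <- simulate_counts(small_cfg(5))
  cd <- as.data.frame(SummarizedExperiment::colData(sim$table))
  expect_equal(nrow(cd), 18)                       # 3 lines x 3 times x 2 reps
  expect_equal(sort(unique(cd$time_h)), c(0, 4, 24))
  expect_equal(sum(cd$genotype == "TP53KO"), 6)
  expect_equal(table(sim$truth$archetype)[["A"]], 6)

  # archetype A: expected 4-fold at 4 h in WT (construction check)
  m <- SummarizedExperiment::assay(sim$table, 1)
  a_ids <- sim$truth$mirna[sim$truth$archetype == "A" &
                             sim$truth$expected_count > 500]
  t0 <- rowSums(m[a_ids, cd$cell_line == "MCF10A" & cd$time_h == 0,
                  drop = FALSE])
  t4 <- rowSums(m[a_ids, cd$cell_line == "MCF10A" & cd$time_h == 4,
                  drop = FALSE])
  expect_equal(median(t4 / t0), 4, tolerance = 0.35)

  # p53-dependent effects are absent in the TP53KO line
  dep <- sim$truth$mirna[sim$truth$p53_dependent &
                           sim$truth$archetype == "A" &
                           sim$truth$expected_count > 500]
  k0 <- rowSums(m[dep, cd$genotype == "TP53KO" & cd$time_h == 0,
                  drop = FALSE])
  k4 <- rowSums(m[dep, cd$genotype == "TP53KO" & cd$time_h == 4,
                  drop = FALSE])
  expect_lt(median(k4 / k0), 1.5)
})

test_that("read simulation round-trips through trimming and quantification", {
  ref <- tiny_reference(5)
  m <- matrix(c(3L, 0L, 7L, 1L, 2L,
                1L, 4L, 0L, 0L, 5L), ncol = 2,
              dimnames = list(ref$id, c("s1", "s2")))
  tab <- count_table(m, data.frame(cell_line = "CL", genotype = "WT",
                                   time_h = c(0, 4), replicate = 1L))
  reads <- simulate_reads(tab, ref, ADAPTER, seed = 2)
  for (j in 1:2) {
    tr <- trim_adapter(reads[[j]], ADAPTER)
    q <- quantify_exact(tr$trimmed[tr$status == "trimmed"], ref)
    expect_equal(unname(q$counts), unname(m[, j]))   # exact recovery
    expect_equal(q$unmatched, 0)
  }

  # contaminants are fully removed by the complexity/length filter
  reads_c <- simulate_reads(tab, ref, ADAPTER, seed = 2,
                            contaminant_frac = 0.2)
  tr <- trim_adapter(reads_c[["s1"]], ADAPTER)
  fr <- filter_reads(tr$trimmed[tr$status == "trimmed"])
  q <- quantify_exact(fr$retained, ref)
  expect_equal(unname(q$counts), unname(m[, 1]))

  # empty table gives empty read sets
  empty <- simulate_reads(count_table(matrix(0L, 1, 2,
      dimnames = list(ref$id[1], c("a", "b"))),
      data.frame(cell_line = "CL", genotype = "WT", time_h = c(0, 4),
                 replicate = 1L), library_sizes = c(1, 1)),
    ref[1, , drop = FALSE], ADAPTER)
  expect_equal(lengths(empty), c(a = 0L, b = 0L))
})

test_that("simulated annotation reproduces its own ground-truth labels", {
  cfg <- small_cfg(7)
  ann <- simulate_annotation(cfg)
  loc <- classify_location(ann$loci, ann$transcripts)
  grp <- classify_grouping(ann$loci)
  expect_equal(loc$location, ann$truth$location)   # 100% agreement
  expect_equal(grp$grouping, ann$truth$grouping)
  expect_identical(simulate_annotation(cfg)$loci, ann$loci)  # seeded

  # all-singles geometry
  cfg0 <- sim_config(seed = 2, n_mirnas = 20, library_size_mean = 1e5,
                     cluster_geometry = c(intragenic_single = 10,
                                          intragenic_clustered = 0,
                                          intergenic_clustered = 0,
                                          intergenic_single = 10))
  ann0 <- simulate_annotation(cfg0)
  expect_true(all(classify_grouping(ann0$loci)$grouping == "single"))
})

test_that("promoter simulation plants scorable sites in the covered species", {
  pwms <- p53_pwm()
  cfg <- sim_config(seed = 11, n_species = 5, region_length = 300,
                    motif_plant = list(n_features = 4, sites_per_feature = 2,
                                       species_coverage = 0.6))
  prom <- simulate_promoters(cfg, pwms, n_features = 30)
  expect_length(prom$regions, 5)
  expect_true(all(lengths(prom$regions) == 30))
  expect_identical(simulate_promoters(cfg, pwms, n_features = 30)$regions,
                   prom$regions)                     # seeded

  planted <- prom$truth$feature[prom$truth$planted]
  unplanted <- prom$truth$feature[!prom$truth$planted]
  for (sp in unique(prom$sites$species)) {
    seqs <- prom$regions[[sp]]
    sc <- vapply(seqs, crm_score, numeric(1), pwms = pwms)
    here <- unique(prom$sites$feature[prom$sites$species == sp])
    expect_true(all(sc[here] > median(sc[unplanted])))
  }

  # zero coverage plants nothing
  cfg0 <- sim_config(seed = 11, n_species = 5, region_length = 300,
                     motif_plant = list(n_features = 4,
                                        sites_per_feature = 2,
                                        species_coverage = 0))
  # coverage 0 still targets one species by the minimum rule; sites = 0 works
  cfg0$motif_plant$sites_per_feature <- 0L
  prom0 <- simulate_promoters(cfg0, pwms, n_features = 10)
  expect_null(prom0$sites)

  expect_error(simulate_promoters(
    sim_config(seed = 1, region_length = 10), pwms), "longer than")
})
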