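make_records <- function(...) {
  # rows: mirna, cell_line, time_h, M, significant
  df <- data.frame(...)
  df$p_corr <- ifelse(df$significant, 0.01, 0.5)
  df
}

test_that("robust filter enforces trend, significance and cross-line support", {
  rec <- make_records(
    mirna = rep(c("let7a", "mir139", "flat"), each = 4),
    cell_line = rep(rep(c("MCF10A", "HCT116"), each = 2), 3),
    time_h = rep(c(4, 24), 6),
    M = c(1.55, 0.49, 0.89, 0.50,      # consistent induction, both lines
          1.00, -1.00, 0.40, 1.23,     # trend fails in MCF10A
          0.05, 0.08, 0.02, 0.01),     # null
    significant = c(TRUE, FALSE, TRUE, FALSE,
                    TRUE, TRUE, FALSE, TRUE,
                    FALSE, FALSE, FALSE, FALSE))
  got <- robust_filter(rec, "induced")
  expect_true("let7a" %in% got)
  # mir139 passes only in HCT116 -> fails the two-line criterion
  expect_false("mir139" %in% got)
  expect_false("flat" %in% got)
  tr <- attr(got, "trace")
  expect_false(tr[["mir139"]]$cell_line_flags[["MCF10A"]])
  expect_true(tr[["mir139"]]$cell_line_flags[["HCT116"]])

  # replicate-level support rescues a single-cell-line candidate
  reps <- data.frame(mirna = "mir139", cell_line = "HCT116",
                     replicate = 1:2, significant = TRUE)
  got2 <- robust_filter(rec, "induced", replicate_significance = reps)
  expect_true("mir139" %in% got2)

  # all-null input -> empty set
  nullrec <- make_records(mirna = rep("x", 4),
                          cell_line = rep(c("A", "B"), each = 2),
                          time_h = rep(c(4, 24), 2), M = 0,
                          significant = FALSE)
  expect_length(robust_filter(nullrec, "induced"), 0)
})

test_that("redundancy rules collapse the 23 published candidates to 20", {
  cand <- ddr_example_candidates()
  cov <- setNames(cand$coverage, cand$mirna_id)
  ref <- data.frame(id = cand$mirna_id, sequence = cand$sequence,
                    stemloop_id = cand$stemloop_id)
  kept <- resolve_redundancy(cand$mirna_id, ref, cov)
  expect_length(kept, 20)
  removed <- attr(kept, "removed")
  expect_setequal(removed$id[removed$rule == "arm_coverage"],
                  c("miR-139-3p", "miR-486-3p"))
  expect_equal(removed$id[removed$rule == "identical_sequence"],
               "miR-365b-3p")                 # lexicographically later id
  expect_true(all(c("miR-139-5p", "miR-486-5p", "miR-365a-3p") %in% kept))
})

test_that("redundancy resolution commutes with filtering on clean inputs", {
  cand <- ddr_example_candidates()
  cov <- setNames(cand$coverage, cand$mirna_id)
  ref <- data.frame(id = cand$mirna_id, sequence = cand$sequence,
                    stemloop_id = cand$stemloop_id)
  subset_first <- resolve_redundancy(
    intersect(cand$mirna_id, cand$mirna_id[1:23]), ref, cov)
  all_first <- intersect(resolve_redundancy(cand$mirna_id, ref, cov),
                         cand$mirna_id[1:23])
  expect_setequal(as.character(subset_first), as.character(all_first))
})

test_that("kinetic clusters follow direction and peak-time with a 24 h tie rule", {
  rec <- data.frame(mirna = c("early_up", "late_down", "tie_up"),
                    M4 = c(2.0, -0.1, 1.0), M24 = c(0.5, -1.5, -1.0))
  got <- assign_kinetic_clusters(rec, preset = "mcf10a")
  expect_equal(got$label, c("A", "D", "D"))   # tie -> 24 h, sign there
  expect_true(got$tie[3])
  hct <- assign_kinetic_clusters(rec, preset = "hct116")
  expect_equal(hct$label[1], "B")             # early-peak induced is B there

  # partition: every miRNA gets exactly one label
  set.seed(31)
  many <- data.frame(mirna = sprintf("m%d", 1:50),
                     M4 = runif(50, -3, 3), M24 = runif(50, -3, 3))
  lab <- assign_kinetic_clusters(many)
  expect_false(any(is.na(lab$label)))
  expect_equal(nrow(lab), 50)
})

test_that("set comparison matches brute-force set algebra and inclusion-exclusion", {
  a <- sprintf("m%d", 1:88); b <- sprintf("m%d", 89:150)
  v <- compare_ddr_sets(list(MCF10A = a, HCT116 = b))
  expect_equal(v$union_size, 150)
  expect_equal(unname(v$intersections), 0)

  set.seed(4)
  x <- sample(letters, 15); y <- sample(letters, 12)
  v2 <- compare_ddr_sets(list(X = x, Y = y))
  expect_equal(v2$union_size, length(union(x, y)))
  expect_equal(unname(v2$intersections[1]), length(intersect(x, y)))
  expect_equal(v2$union_size,
               length(x) + length(y) - unname(v2$intersections[1]))
  same <- compare_ddr_sets(list(A = x, B = x))
  expect_equal(unname(same$intersections[1]), same$union_size)
})

test_that("timing chi-square equals its closed form and is row-symmetric", {
  flat <- timing_chisq(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  tab <- matrix(c(23, 24, 3, 51), 2, byrow = TRUE)
  got <- timing_chisq(tab)
  n <- sum(tab)
  closed <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab), colSums(tab))
  expect_equal(got$statistic, closed, tolerance = 1e-12)
  swapped <- timing_chisq(tab[2:1, ])
  expect_equal(swapped$statistic, got$statistic)
  expect_error(timing_chisq(matrix(c(0, 0, 3, 5), 2)), "zero margin")
})

test_that("p53 dependence calls follow the wild-type/knockout contrast", {
  wt <- data.frame(mirna = c("dep", "indep", "na"), time_h = 24,
                   M = c(2.0, 1.5, 1.2), significant = TRUE)
  ko <- data.frame(mirna = c("dep", "indep"), time_h = 24,
                   M = c(0.1, 1.4), significant = c(FALSE, TRUE))
  got <- p53_dependence(wt, ko)
  expect_equal(got$call[got$mirna == "dep"], "p53_dependent")
  expect_equal(got$call[got$mirna == "indep"], "p53_independent")
  expect_equal(got$call[got$mirna == "na"], "indeterminate")

  # residual KO induction above m_thresh/2 blocks the dependent call
  ko2 <- data.frame(mirna = "dep", time_h = 24, M = 0.5,
                    significant = FALSE)
  got2 <- p53_dependence(wt[wt$mirna == "dep", ], ko2)
  expect_equal(got2$call, "indeterminate")
})

test_that("a simulated regulon recovers the planted p53-dependent fraction", {
  cfg <- sim_config(seed = 77, n_mirnas = 400, library_size_mean = 2e6,
                    spike_sets = list(
                      A = list(n = 40, effect = 2, p53_dependent_frac = 0.75),
                      B = list(n = 0, effect = 2, p53_dependent_frac = 0),
                      C = list(n = 0, effect = -2, p53_dependent_frac = 0),
                      D = list(n = 0, effect = -2, p53_dependent_frac = 0)))
  sim <- simulate_counts(cfg)
  de <- run_diffexpr(sim$table)
  wt <- de[de$cell_line == "HCT116" & de$genotype == "WT",
           c("mirna", "time_h", "M", "significant")]
  ko <- de[de$genotype == "TP53KO", c("mirna", "time_h", "M", "significant")]
  # condition on spikes abundant enough to be detectable at all
  spiked <- sim$truth$mirna[sim$truth$archetype == "A" &
                              sim$truth$expected_count >= 64]
  dep <- p53_dependence(wt[wt$mirna %in% spiked, ],
                        ko[ko$mirna %in% spiked, ])
  frac <- mean(dep$call == "p53_dependent")
  n <- length(spiked)
  expect_gt(frac, 0.75 - 3 * sqrt(0.75 * 0.25 / n))  # binomial error band
  expect_lt(frac, 0.75 + 3 * sqrt(0.75 * 0.25 / n))
})
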