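test_that("normalization: pseudocount, strict aggregate filter, column scaling", {
  m <- rbind(m1 = c(0L, 120L), m2 = c(60L, 40L), m3 = c(50L, 49L),
             m4 = c(400L, 600L))
  colnames(m) <- c("s1", "s2")
  tab <- count_table(m, data.frame(cell_line = "CL", genotype = "WT",
                                   time_h = c(0, 4), replicate = 1L))
  norm <- normalize_counts(tab)
  x <- SummarizedExperiment::assay(norm, "normalized")

  # aggregate 99 dropped (strict "less than"), aggregate 100 retained
  expect_false("m3" %in% rownames(x))
  expect_true(all(c("m1", "m2", "m4") %in% rownames(x)))
  expect_equal(S4Vectors::metadata(norm)$dropped, "m3")

  # zero replaced by pseudocount before scaling: cell = 1 * target/lib
  lib <- SummarizedExperiment::colData(tab)$library_size
  target <- mean(lib)
  expect_equal(unname(x["m1", "s1"]), 1 * target / lib[1])
  # scaling is column-wise: identical columns stay identical
  m2 <- cbind(a = c(x = 50L, y = 120L), b = c(x = 50L, y = 120L))
  t2 <- count_table(m2, data.frame(cell_line = "CL", genotype = "WT",
                                   time_h = c(0, 4), replicate = 1L))
  x2 <- SummarizedExperiment::assay(normalize_counts(t2), 1)
  expect_equal(x2[, "a"], x2[, "b"])

  zero <- cbind(a = c(x = 0L), b = c(x = 5L))
  tz <- suppressWarnings(try(count_table(zero,
    data.frame(cell_line = "CL", genotype = "WT", time_h = c(0, 4),
               replicate = 1L)), silent = TRUE))
  expect_true(inherits(tz, "try-error"))   # degenerate library rejected
})

test_that("replicate merging sums counts and library sizes, preserving totals", {
  m <- cbind(r1 = c(a = 10L, b = 3L), r2 = c(a = 14L, b = 7L),
             s1 = c(a = 5L, b = 5L))
  tab <- count_table(m, data.frame(cell_line = "CL", genotype = "WT",
                                   time_h = c(0, 0, 4),
                                   replicate = c(1L, 2L, 1L)))
  mg <- merge_replicates(tab)
  x <- SummarizedExperiment::assay(mg, 1)
  expect_equal(ncol(x), 2L)
  expect_equal(unname(x[, "CL_WT_0h"]), c(24L, 10L))
  expect_equal(unname(x[, "CL_WT_4h"]), c(5L, 5L))    # single replicate: identity
  expect_equal(sum(x), sum(m))                         # total conservation
  expect_equal(sum(SummarizedExperiment::colData(mg)$library_size), sum(m))

  set.seed(8)
  big <- matrix(rpois(60, 30), 10,
                dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:6)))
  bt <- count_table(big, data.frame(cell_line = "CL", genotype = "WT",
                                    time_h = rep(c(0, 4, 24), each = 2),
                                    replicate = rep(1:2, 3)))
  bm <- merge_replicates(bt)
  expect_equal(sum(SummarizedExperiment::assay(bm, 1)), sum(big))
})

test_that("M/A anchors: equal counts of 32 give M = 0, A = 5", {
  m <- cbind(t0 = c(a = 32, b = 32, c = 2), t4 = c(a = 32, b = 64, c = 2))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(normalized = m))
  ma <- compute_ma(se, "t4", "t0")
  expect_equal(ma$M[1], 0)
  expect_equal(ma$A[1], 5)
  expect_equal(ma$M[2], 1)
  expect_equal(ma$A[2], log2(48), tolerance = 1e-12)  # ~5.585
})

test_that("exact Fisher test equals the hypergeometric enumeration oracle", {
  # spec example and symmetry cases
  expect_equal(count_test(8, 1000, 1, 1000), fisher_enum(8, 1000, 1, 1000),
               tolerance = 1e-12)
  expect_equal(count_test(5, 500, 5, 500), 1)
  expect_equal(count_test(3, 800, 9, 1200), count_test(9, 1200, 3, 800),
               tolerance = 1e-12)

  set.seed(21)
  for (i in 1:150) {
    l1 <- sample(20:2000, 1); l2 <- sample(20:2000, 1)
    x1 <- sample(0:min(60, l1), 1); x2 <- sample(0:min(60, l2), 1)
    expect_equal(count_test(x1, l1, x2, l2), fisher_enum(x1, l1, x2, l2),
                 tolerance = 1e-12)
    expect_equal(count_test(x1, l1, x2, l2),
                 fisher.test(matrix(c(x1, l1 - x1, x2, l2 - x2), 2,
                                    byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
  expect_error(count_test(1, 0, 1, 10), "library sizes")
})

test_that("binomial approximation converges to the exact test for large libraries", {
  p_f <- count_test(8, 1e6, 1, 1e6, method = "exact_fisher")
  p_b <- count_test(8, 1e6, 1, 1e6, method = "binomial_approx")
  expect_lt(abs(p_f - p_b), 1e-3)
  # equal counts, equal libraries: p = 1 for both methods
  expect_equal(count_test(4, 1e6, 4, 1e6, method = "binomial_approx"), 1)
})

test_that("Bonferroni correction and boundary-inclusive significance calls", {
  rec <- data.frame(mirna = c("a", "b", "c", "d"),
                    M = c(0.96, 0.51, 0.75, 0.80),
                    A = c(6, 7, 5, 4.9),
                    p = c(1e-5, 1e-9, 4e-5, 1e-9))
  out <- correct_and_call(rec, m_tests = 965)
  expect_equal(out$p_corr, pmin(1, 965 * rec$p))
  expect_true(out$significant[1])          # strong M, abundant, significant
  expect_false(out$significant[2])         # M below threshold whatever p
  expect_true(out$significant[3])          # M and A boundaries inclusive
  expect_false(out$significant[4])         # A below threshold
  expect_equal(correct_and_call(data.frame(mirna = "x", M = 1, A = 6,
                                           p = 0.001),
                                m_tests = 965)$p_corr, 0.965)
})

test_that("treat/ctrl swap negates M, preserves A and the two-sided p", {
  set.seed(14)
  m <- cbind(t0 = runif(20, 1, 500), t4 = runif(20, 1, 500))
  rownames(m) <- sprintf("g%d", 1:20)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(normalized = m))
  fwd <- compute_ma(se, "t4", "t0")
  rev <- compute_ma(se, "t0", "t4")
  expect_equal(fwd$M, -rev$M)
  expect_equal(fwd$A, rev$A)

  x <- matrix(sample(0:50, 20, TRUE), 10)
  p1 <- count_test(x[, 1], 4000, x[, 2], 5000)
  p2 <- count_test(x[, 2], 5000, x[, 1], 4000)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the diffexpr driver flags a spiked miRNA and not its null peers", {
  # the spike is kept a small library fraction: total-count scaling is
  # composition-sensitive when a single feature dominates the library
  base <- c(100, rep(c(40, 80, 200, 400), 6))
  fold <- matrix(1, length(base), 3)
  fold[1, 2:3] <- 4                        # 4-fold induced at 4 h and 24 h
  tab <- tiny_count_table(base, fold, seed = 6)
  de <- run_diffexpr(tab)
  expect_equal(attr(de, "method"), "exact_fisher")
  spiked <- de[de$mirna == "m001", ]
  expect_true(all(spiked$significant))
  expect_true(all(abs(spiked$M - 2) < 0.6))
  nulls <- de[de$mirna != "m001", ]
  expect_lt(mean(nulls$significant), 0.02)
})
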