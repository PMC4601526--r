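#' Normalize a raw miRNA count table
#'
#' Three fixed steps, in this order: (1) every zero cell is replaced by
#' `pseudocount`; (2) miRNAs whose aggregate raw count across all samples is
#' below `aggregate_min` are dropped (strict: an aggregate exactly equal to
#' `aggregate_min` is retained); (3) each column is scaled so that its
#' miRNA-mapped total (the raw library size) matches the scale target —
#' by default the mean raw library size across samples, which preserves the
#' equivalence between an average abundance of A = 5 and roughly 32 reads.
#'
#' @param raw a raw count table from [count_table()].
#' @param pseudocount value replacing zero cells, default 1.
#' @param aggregate_min minimum aggregate raw count, default 100.
#' @param scale_target `"mean_library"` (default) or `"fixed_per_million"`
#'   (columns scaled to 1e6).
#' @return a `SummarizedExperiment` with assay `"normalized"`; the dropped
#'   miRNA ids are in `metadata(x)$dropped`, and `colData` keeps the raw
#'   library sizes.
#' @export
normalize_counts <- function(raw, pseudocount = 1, aggregate_min = 100,
                             scale_target = c("mean_library",
                                              "fixed_per_million")) {
  scale_target <- match.arg(scale_target)
  m <- SummarizedExperiment::assay(raw, "counts")
  if (any(colSums(m) == 0)) stop("degenerate library: all-zero column")
  if (pseudocount < 0 || aggregate_min < 0)
    stop("pseudocount and aggregate_min must be >= 0")
  lib <- SummarizedExperiment::colData(raw)$library_size

  x <- m
  x[x == 0] <- pseudocount                         # (1)
  keep <- rowSums(m) >= aggregate_min              # (2) on raw aggregates
  dropped <- rownames(m)[!keep]
  x <- x[keep, , drop = FALSE]
  target <- if (scale_target == "mean_library") mean(lib) else 1e6
  x <- sweep(x, 2L, target / lib, `*`)             # (3)

  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(normalized = x),
    colData = SummarizedExperiment::colData(raw))
  S4Vectors::metadata(out)$dropped <- dropped
  S4Vectors::metadata(out)$scale_target <- target
  out
}

#' Merge technical replicates
#'
#' Sums columns that share `(cell_line, genotype, time_h)`; the merged
#' library size is the sum of the member library sizes. Intended for raw
#' count tables before testing.
#'
#' @param x a count table.
#' @return a count table with one column per condition, named
#'   `<cell_line>_<genotype>_<time_h>h` and `replicate = 1`.
#' @export
merge_replicates <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  need <- c("cell_line", "genotype", "time_h")
  if (any(is.na(as.data.frame(cd)[, need])))
    stop("missing replicate metadata")
  key <- paste(cd$cell_line, cd$genotype, paste0(cd$time_h, "h"), sep = "_")
  m <- SummarizedExperiment::assay(x, 1L)
  groups <- split(seq_len(ncol(m)), key)
  groups <- groups[unique(key)]                    # keep first-seen order
  merged <- vapply(groups, function(j) rowSums(m[, j, drop = FALSE]),
                   numeric(nrow(m)))
  if (nrow(m) == 1L) merged <- matrix(merged, nrow = 1L,
                                      dimnames = list(rownames(m),
                                                      names(groups)))
  lib <- vapply(groups, function(j) sum(cd$library_size[j]), numeric(1))
  first <- vapply(groups, `[`, integer(1), 1L)
  meta <- data.frame(cell_line = cd$cell_line[first],
                     genotype = cd$genotype[first],
                     time_h = cd$time_h[first],
                     replicate = 1L)
  count_table(merged, meta, library_sizes = lib)
}

#' Per-miRNA M and A values for one comparison
#'
#' M is the log2 fold change of treatment over control and A the log2 of
#' their mean, both on normalized counts (strictly positive after the
#' pseudocount step). With mean-library scaling, A = 5 corresponds to an
#' average of 32 reads and the default significance threshold M = 0.75 to a
#' 2^0.75 = 1.68-fold change.
#'
#' @param normalized a normalized count table ([normalize_counts()]).
#' @param treat,ctrl column names of the treatment and control samples.
#' @return data.frame with columns `mirna`, `M`, `A`.
#' @export
compute_ma <- function(normalized, treat, ctrl) {
  m <- SummarizedExperiment::assay(normalized, 1L)
  if (!all(c(treat, ctrl) %in% colnames(m)))
    stop("treat/ctrl column not found")
  nt <- m[, treat]; nc <- m[, ctrl]
  if (any(nt <= 0 | nc <= 0)) stop("normalized counts must be positive")
  data.frame(mirna = rownames(m), M = log2(nt / nc),
             A = log2((nt + nc) / 2), row.names = NULL,
             stringsAsFactors = FALSE)
}

# two-sided exact p for a 2x2 table [[x_t, L_t-x_t], [x_c, L_c-x_c]]:
# the sum of hypergeometric point probabilities <= that of the observed
# table (with the customary 1+1e-7 relative slack against floating-point
# ties). dhyper is unimodal in the table cell, so {d <= p_obs} is a left
# and a right tail whose boundaries are found by binary search; the tails
# are then summed with phyper. Exact, and O(log support) per table.
.fisher_exact_2x2 <- function(x_treat, lib_treat, x_ctrl, lib_ctrl) {
  k <- x_treat + x_ctrl
  lo <- max(0, k - lib_ctrl)
  hi <- min(k, lib_treat)
  if (lo == hi) return(1)
  d <- function(j) stats::dhyper(j, lib_treat, lib_ctrl, k)
  p_cut <- d(x_treat) * (1 + 1e-7)
  mode <- floor((k + 1) * (lib_treat + 1) / (lib_treat + lib_ctrl + 2))
  mode <- min(max(mode, lo), hi)
  if (d(mode) <= p_cut) return(1)

  # largest j in [lo, mode] with d(j) <= p_cut (d non-decreasing there)
  k_lo <- if (d(lo) > p_cut) lo - 1 else {
    a <- lo; b <- mode        # invariant: d(a) <= p_cut < d(b)
    while (b - a > 1) {
      m <- floor((a + b) / 2)
      if (d(m) <= p_cut) a <- m else b <- m
    }
    a
  }
  # smallest j in [mode, hi] with d(j) <= p_cut (d non-increasing there)
  k_hi <- if (d(hi) > p_cut) hi + 1 else {
    a <- mode; b <- hi        # invariant: d(a) > p_cut >= d(b)
    while (b - a > 1) {
      m <- floor((a + b) / 2)
      if (d(m) <= p_cut) b <- m else a <- m
    }
    b
  }
  p <- 0
  if (k_lo >= lo) p <- p + stats::phyper(k_lo, lib_treat, lib_ctrl, k)
  if (k_hi <= hi) p <- p + stats::phyper(k_hi - 1, lib_treat, lib_ctrl, k,
                                         lower.tail = FALSE)
  min(1, p)
}

#' Count-based test for differential expression of one miRNA
#'
#' Tests whether the read count of a miRNA differs between two libraries,
#' given the library sizes (miRNA-mapped totals). `exact_fisher` is the
#' two-sided exact test on the 2x2 table
#' `[[x_treat, lib_treat - x_treat], [x_ctrl, lib_ctrl - x_ctrl]]`,
#' computed by summing hypergeometric point probabilities no larger than
#' that of the observed table. `binomial_approx` tests
#' `x_treat ~ Binomial(x_treat + x_ctrl, lib_treat/(lib_treat + lib_ctrl))`
#' two-sided; the two agree as library sizes grow with the counts fixed.
#'
#' @param x_treat,x_ctrl miRNA read counts (integers).
#' @param lib_treat,lib_ctrl library sizes, positive integers with
#'   `0 <= x <= lib`.
#' @param method `"exact_fisher"` (default) or `"binomial_approx"`.
#' @return two-sided p-value(s); vectorised over the count/library
#'   arguments.
#' @export
count_test <- function(x_treat, lib_treat, x_ctrl, lib_ctrl,
                       method = c("exact_fisher", "binomial_approx")) {
  method <- match.arg(method)
  n <- max(length(x_treat), length(x_ctrl))
  x_treat <- rep_len(as.numeric(x_treat), n)
  x_ctrl <- rep_len(as.numeric(x_ctrl), n)
  lib_treat <- rep_len(as.numeric(lib_treat), n)
  lib_ctrl <- rep_len(as.numeric(lib_ctrl), n)
  if (any(lib_treat <= 0 | lib_ctrl <= 0)) stop("library sizes must be > 0")
  if (any(x_treat < 0 | x_ctrl < 0 | x_treat > lib_treat |
            x_ctrl > lib_ctrl))
    stop("counts must satisfy 0 <= x <= lib")
  if (method == "exact_fisher") {
    vapply(seq_len(n), function(i)
      .fisher_exact_2x2(x_treat[i], lib_treat[i], x_ctrl[i], lib_ctrl[i]),
      numeric(1))
  } else {
    vapply(seq_len(n), function(i) {
      k <- x_treat[i] + x_ctrl[i]
      if (k == 0) return(1)
      stats::binom.test(x_treat[i], k,
                        lib_treat[i] / (lib_treat[i] + lib_ctrl[i]))$p.value
    }, numeric(1))
  }
}

#' Multiple-testing correction and significance calls
#'
#' Applies the Bonferroni correction `p_corr = min(1, m_tests * p)` and
#' flags a record significant when `|M| >= m_thresh`, `A >= a_thresh`
#' (both boundaries inclusive) and `p_corr < alpha` (strict).
#'
#' @param records data.frame with columns `mirna`, `M`, `A`, `p` (one
#'   comparison).
#' @param m_thresh,a_thresh,alpha thresholds; defaults 0.75 log2 units,
#'   5 log2 units and 0.05. The more permissive variant used for candidate
#'   novel miRNAs is `(0.5, 4, 0.001)`.
#' @param m_tests number of tests corrected for; default `nrow(records)`.
#' @return `records` with columns `p_corr` and `significant` added.
#' @export
correct_and_call <- function(records, m_thresh = 0.75, a_thresh = 5,
                             alpha = 0.05, m_tests = nrow(records)) {
  if (m_tests < nrow(records))
    stop("m_tests must be at least the number of records")
  records$p_corr <- pmin(1, m_tests * records$p)
  records$significant <- abs(records$M) >= m_thresh &
    records$A >= a_thresh & records$p_corr < alpha
  records
}

#' Differential expression of miRNAs against the 0 h control
#'
#' End-to-end driver: merges technical replicates, normalizes (pseudocount,
#' aggregate filter, library-size scaling), and for every
#' `(cell_line, genotype, time_h)` condition with `time_h > 0` compares it
#' to the matching 0 h control. M and A are computed on normalized merged
#' counts; the count test runs on raw merged counts with raw library sizes
#' (exact tests need integers); the Bonferroni factor is the number of
#' miRNAs tested, applied per comparison.
#'
#' @param raw a raw count table with technical replicates.
#' @param method test passed to [count_test()].
#' @param m_thresh,a_thresh,alpha see [correct_and_call()].
#' @param pseudocount,aggregate_min see [normalize_counts()].
#' @return data.frame with one row per miRNA and comparison: `mirna`,
#'   `cell_line`, `genotype`, `time_h`, `M`, `A`, `p`, `p_corr`,
#'   `significant`. The attribute `"m_tests"` records the correction
#'   factor; correction is per comparison.
#' @export
run_diffexpr <- function(raw, method = "exact_fisher", m_thresh = 0.75,
                         a_thresh = 5, alpha = 0.05, pseudocount = 1,
                         aggregate_min = 100) {
  merged <- merge_replicates(raw)
  norm <- normalize_counts(merged, pseudocount = pseudocount,
                           aggregate_min = aggregate_min)
  cd <- as.data.frame(SummarizedExperiment::colData(merged))
  rawm <- SummarizedExperiment::assay(merged, "counts")
  rawm <- rawm[rownames(norm), , drop = FALSE]
  out <- list()
  for (i in which(cd$time_h != 0)) {
    j <- which(cd$cell_line == cd$cell_line[i] &
                 cd$genotype == cd$genotype[i] & cd$time_h == 0)
    if (length(j) != 1L) next
    ma <- compute_ma(norm, colnames(rawm)[i], colnames(rawm)[j])
    ma$p <- count_test(rawm[, i], cd$library_size[i],
                       rawm[, j], cd$library_size[j], method = method)
    ma <- correct_and_call(ma, m_thresh, a_thresh, alpha)
    ma$cell_line <- cd$cell_line[i]
    ma$genotype <- cd$genotype[i]
    ma$time_h <- cd$time_h[i]
    out[[length(out) + 1L]] <- ma
  }
  res <- do.call(rbind, out)
  res <- res[, c("mirna", "cell_line", "genotype", "time_h",
                 "M", "A", "p", "p_corr", "significant")]
  attr(res, "m_tests") <- nrow(rawm)
  attr(res, "method") <- method
  attr(res, "correction") <- "bonferroni_per_comparison"
  rownames(res) <- NULL
  res
}
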