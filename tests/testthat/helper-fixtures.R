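# shared fixtures and independent oracles, built in code at test time

ADAPTER <- "TCGTATGCCGTCTTCTGCTTG"

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# small mature-miRNA reference with unique sequences
tiny_reference <- function(n = 6, len = 22, seed = 42) {
  set.seed(seed)
  repeat {
    seqs <- vapply(seq_len(n), function(i) random_seq(len), character(1))
    if (!anyDuplicated(seqs)) break
  }
  data.frame(id = sprintf("miR-t%02d", seq_len(n)), sequence = seqs,
             stemloop_id = sprintf("miR-t%02d", seq_len(n)),
             arm = "unknown", stringsAsFactors = FALSE)
}

# brute-force two-sided Fisher p by full hypergeometric enumeration
fisher_enum <- function(x1, l1, x2, l2) {
  k <- x1 + x2
  lo <- max(0, k - l2); hi <- min(k, l1)
  d <- dhyper(lo:hi, l1, l2, k)
  sum(d[d <= d[x1 - lo + 1] * (1 + 1e-7)])
}

# naive per-position PWM log2-odds scan (forward strand)
naive_scan <- function(seq, pwm, bg = rep(0.25, 4)) {
  L <- ncol(pwm); n <- nchar(seq)
  vapply(seq_len(n - L + 1), function(i) {
    s <- 0
    for (j in seq_len(L)) {
      b <- substr(seq, i + j - 1, i + j - 1)
      ix <- match(b, c("A", "C", "G", "T"))
      if (is.na(ix)) return(-Inf)
      s <- s + log2(pwm[ix, j] / bg[ix])
    }
    s
  }, numeric(1))
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# small random PWM, column-normalized
random_pwm <- function(L = 8, seed = 7) {
  set.seed(seed)
  m <- matrix(runif(4 * L, 0.05, 1), 4, L,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  sweep(m, 2, colSums(m), `/`)
}

p53_pwm <- function() {
  read_jaspar_pfm(system.file("extdata", "p53_synthetic.pfm",
                              package = "mirddr"))
}

# small raw count table: 1 cell line x {0,4,24} h x 2 replicates
tiny_count_table <- function(counts0, fold = NULL, seed = 5) {
  set.seed(seed)
  n <- length(counts0)
  ids <- sprintf("m%03d", seq_len(n))
  if (is.null(fold)) fold <- matrix(1, n, 3)
  cols <- list(); meta <- list()
  for (ti in seq_along(c(0, 4, 24))) {
    t <- c(0, 4, 24)[ti]
    for (r in 1:2) {
      key <- sprintf("CL_WT_%dh_r%d", t, r)
      cols[[key]] <- rpois(n, counts0 * fold[, ti])
      meta[[key]] <- data.frame(cell_line = "CL", genotype = "WT",
                                time_h = t, replicate = r)
    }
  }
  m <- do.call(cbind, cols); rownames(m) <- ids
  count_table(m, do.call(rbind, meta))
}
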