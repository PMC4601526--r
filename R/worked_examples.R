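#' Published worked examples bundled with the package
#'
#' Three small reference tables used to validate the pipeline against
#' published results on the DNA-damage miRNA response:
#'
#' * `ddr_example_gsea()` — the 20 DDR-induced miRNAs with their 0-based
#'   rank in the genome-wide p53-motif ranking, their rank-metric score,
#'   and the published running enrichment score at each hit. The attribute
#'   `"n_total"` (1531) is the ranked-list length consistent with all 20
#'   running-score values.
#' * `ddr_example_flags()` — per-cell-line M values at 4 h and 24 h and
#'   the published differential-expression flags (1 = satisfied the
#'   M > 0.75, A > 5, corrected p < 0.05 criteria) for the 20 consolidated
#'   DDR miRNAs in MCF10A and HCT116.
#' * `ddr_example_candidates()` — the 23 induced candidates before
#'   redundancy resolution (the 20 above plus the miR-139/miR-486 star
#'   arms and miR-365b-3p). Mature sequences and read coverages in this
#'   file are synthetic stand-ins that preserve the published redundancy
#'   structure: the -5p arms out-cover their -3p stars, and
#'   miR-365a-3p/miR-365b-3p share an identical mature sequence.
#'
#' @return a data.frame (see above).
#' @name worked_examples
NULL

#' @rdname worked_examples
#' @export
ddr_example_gsea <- function() {
  df <- utils::read.delim(system.file("extdata", "gsea_worked_example.tsv",
                                      package = "mirddr"),
                          stringsAsFactors = FALSE)
  attr(df, "n_total") <- 1531L
  df
}

#' @rdname worked_examples
#' @export
ddr_example_flags <- function() {
  utils::read.delim(system.file("extdata", "ddr_flags.tsv",
                                package = "mirddr"),
                    stringsAsFactors = FALSE)
}

#' @rdname worked_examples
#' @export
ddr_example_candidates <- function() {
  utils::read.delim(system.file("extdata", "ddr_candidates_synthetic.tsv",
                                package = "mirddr"),
                    stringsAsFactors = FALSE)
}

#' Embed the GSEA worked example in a full ranked list
#'
#' Reconstructs a complete ranked list of `n_total` features in which the
#' worked-example miRNAs sit at exactly their published ranks with their
#' published rank-metric scores; filler features receive interpolated
#' scores that keep the list non-increasing. With hit weight p = 1 the
#' running enrichment score depends only on the member scores and the list
#' length, so the filler values are immaterial to [running_es()].
#'
#' @return list with `ids` and `scores` (length 1531, best first) and
#'   `set` (the 20 member ids).
#' @export
ddr_example_ranked_list <- function() {
  ex <- ddr_example_gsea()
  N <- attr(ex, "n_total")
  scores <- numeric(N)
  ids <- sprintf("filler-%04d", seq_len(N))
  pos <- ex$rank + 1L
  ids[pos] <- ex$name
  scores[pos] <- ex$score
  anchors <- unique(c(1L, pos, N))
  vals <- c(max(ex$score), ex$score, 0)[match(anchors, c(1L, pos, N))]
  fill <- stats::approx(anchors, vals, xout = seq_len(N))$y
  scores[-pos] <- fill[-pos]
  scores <- cummin(scores)     # guard monotonicity at the anchors
  list(ids = ids, scores = scores, set = ex$name)
}
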