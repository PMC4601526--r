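#' Robust filter for DNA-damage-responsive miRNAs
#'
#' Applies the three-part robustness cascade to per-miRNA expression
#' records at 4 h and 24 h: (1) the fold change must show the same trend
#' (same sign of M, zero fails) at 4 h and 24 h within a cell line; (2) the
#' change must be significant (corrected p < alpha) at 4 h or 24 h in that
#' cell line; (3) the miRNA must be significant in at least two cell lines
#' and/or two replicates. A miRNA is a candidate when some cell line passes
#' (1)+(2) in the requested direction and (3) holds overall.
#'
#' @param records data.frame as from [run_diffexpr()] (columns `mirna`,
#'   `cell_line`, `time_h`, `M`, `p_corr`, `significant`), WT samples only.
#' @param direction `"induced"` (M > 0) or `"repressed"` (M < 0).
#' @param replicate_significance optional data.frame with columns `mirna`,
#'   `cell_line`, `replicate`, `significant` carrying per-replicate calls;
#'   when absent, criterion (3) reduces to two cell lines.
#' @return character vector of candidate miRNA ids, with a `trace`
#'   attribute: a per-miRNA list recording which criteria passed where
#'   (miRNAs missing a time point are skipped with a trace note).
#' @export
robust_filter <- function(records, direction = c("induced", "repressed"),
                          replicate_significance = NULL) {
  direction <- match.arg(direction)
  sgn <- if (direction == "induced") 1 else -1
  trace <- list()
  flags <- list()   # per-mirna named logical over cell lines
  for (id in unique(records$mirna)) {
    rec <- records[records$mirna == id, ]
    per_cl <- logical(0)
    notes <- character(0)
    for (cl in unique(rec$cell_line)) {
      r4 <- rec[rec$cell_line == cl & rec$time_h == 4, ]
      r24 <- rec[rec$cell_line == cl & rec$time_h == 24, ]
      if (nrow(r4) != 1L || nrow(r24) != 1L) {
        notes <- c(notes, sprintf("%s: missing time point, skipped", cl))
        next
      }
      if (is.na(r4$M) || is.na(r24$M)) {
        notes <- c(notes, sprintf("%s: missing M, skipped", cl))
        next
      }
      trend <- sign(r4$M) == sgn && sign(r24$M) == sgn
      signif <- isTRUE(r4$significant) || isTRUE(r24$significant)
      per_cl[cl] <- trend && signif
      notes <- c(notes, sprintf("%s: trend=%s significant=%s", cl,
                                trend, signif))
    }
    flags[[id]] <- per_cl
    trace[[id]] <- list(cell_line_flags = per_cl, notes = notes)
  }
  candidates <- character(0)
  for (id in names(flags)) {
    n_cl <- sum(flags[[id]])
    n_rep <- 0L
    if (!is.null(replicate_significance)) {
      rs <- replicate_significance[replicate_significance$mirna == id &
                                     replicate_significance$significant, ]
      if (nrow(rs)) n_rep <- max(table(rs$cell_line))
    }
    pass3 <- n_cl >= 2L || n_rep >= 2L
    trace[[id]]$criterion3 <- pass3
    if (n_cl >= 1L && pass3) candidates <- c(candidates, id)
  }
  structure(candidates, trace = trace)
}

#' Resolve redundant miRNA candidates
#'
#' Two consolidation rules, applied in order: (1) when both arms (-5p and
#' -3p) of the same stem-loop are candidates, keep the arm with the higher
#' read coverage (the presumed functional species) and discard the star
#' sequence; (2) when several candidates have identical mature sequences,
#' keep a single representative (the lexicographically smallest id).
#'
#' @param candidates character vector of candidate miRNA ids.
#' @param reference data.frame with columns `id`, `sequence`, `stemloop_id`
#'   covering all candidates.
#' @param coverage named numeric vector of total read coverage per
#'   candidate.
#' @return character vector of surviving ids, with attribute `removed`:
#'   a data.frame of removed ids and the rule (`"arm_coverage"` or
#'   `"identical_sequence"`) that removed each.
#' @export
resolve_redundancy <- function(candidates, reference, coverage) {
  if (!all(candidates %in% reference$id))
    stop("reference does not cover all candidates")
  if (!all(candidates %in% names(coverage)))
    stop("coverage missing for some candidates")
  ref <- reference[match(candidates, reference$id), ]
  removed <- data.frame(id = character(0), rule = character(0),
                        stringsAsFactors = FALSE)
  keep <- candidates

  # rule 1: both arms of one stem-loop -> higher coverage wins
  for (sl in unique(ref$stemloop_id)) {
    arms <- ref$id[ref$stemloop_id == sl]
    arms <- intersect(arms, keep)
    if (length(arms) > 1L) {
      best <- arms[which.max(coverage[arms])]
      drop <- setdiff(arms, best)
      keep <- setdiff(keep, drop)
      removed <- rbind(removed, data.frame(id = drop, rule = "arm_coverage",
                                           stringsAsFactors = FALSE))
    }
  }
  # rule 2: identical mature sequences -> one representative
  ref2 <- ref[ref$id %in% keep, ]
  for (s in unique(ref2$sequence[duplicated(ref2$sequence)])) {
    ids <- sort(ref2$id[ref2$sequence == s])
    drop <- ids[-1L]
    keep <- setdiff(keep, drop)
    removed <- rbind(removed, data.frame(id = drop,
                                         rule = "identical_sequence",
                                         stringsAsFactors = FALSE))
  }
  structure(keep, removed = removed)
}

#' Kinetic cluster label presets
#'
#' Maps the four cluster labels A-D to (direction, peak time) pairs. The
#' two published conventions differ: in the `"mcf10a"` preset A is
#' early-peak induced (4 h) and B late-peak induced (24 h); in the
#' `"hct116"` preset A is late-peak induced and B early-peak induced.
#' C and D are the early- and late-peak repressed clusters respectively in
#' both presets.
#'
#' @param preset `"mcf10a"` or `"hct116"`.
#' @return data.frame with columns `label`, `direction`, `peak_time`.
#' @export
cluster_presets <- function(preset = c("mcf10a", "hct116")) {
  preset <- match.arg(preset)
  if (preset == "mcf10a") {
    data.frame(label = c("A", "B", "C", "D"),
               direction = c("induced", "induced", "repressed", "repressed"),
               peak_time = c(4, 24, 4, 24), stringsAsFactors = FALSE)
  } else {
    data.frame(label = c("A", "B", "C", "D"),
               direction = c("induced", "induced", "repressed", "repressed"),
               peak_time = c(24, 4, 4, 24), stringsAsFactors = FALSE)
  }
}

#' Assign DDR miRNAs to kinetic clusters
#'
#' Deterministic rule: the direction of a miRNA is the sign of M at the
#' time of its largest |M|, and the peak time is that time; ties on |M| go
#' to 24 h (the later peak) and are trace-noted. The (direction, peak)
#' pair is then mapped to a label through a [cluster_presets()] convention.
#'
#' @param records data.frame with columns `mirna`, `M4`, `M24` (M at 4 h
#'   and 24 h for one cell line).
#' @param preset label convention, see [cluster_presets()].
#' @return data.frame with columns `mirna`, `direction`, `peak_time`,
#'   `label`, `tie` (logical).
#' @export
assign_kinetic_clusters <- function(records, preset = "mcf10a") {
  map <- cluster_presets(preset)
  tie <- abs(records$M4) == abs(records$M24)
  peak <- ifelse(abs(records$M4) > abs(records$M24), 4, 24)
  mpeak <- ifelse(peak == 4, records$M4, records$M24)
  direction <- ifelse(mpeak >= 0, "induced", "repressed")
  label <- map$label[match(paste(direction, peak),
                           paste(map$direction, map$peak_time))]
  data.frame(mirna = records$mirna, direction = direction,
             peak_time = peak, label = label, tie = tie,
             stringsAsFactors = FALSE)
}

#' Compare DDR sets across cell lines
#'
#' @param sets named list of character vectors (one per cell line),
#'   at least two.
#' @return list with `sizes` (per set), `union_size`, `intersections`
#'   (named pairwise intersection sizes), `shared` (members of every set).
#' @export
compare_ddr_sets <- function(sets) {
  if (length(sets) < 2L) stop("need at least two cell lines")
  nm <- names(sets)
  pairs <- utils::combn(nm, 2L)
  inter <- apply(pairs, 2L, function(p)
    length(intersect(sets[[p[1]]], sets[[p[2]]])))
  names(inter) <- apply(pairs, 2L, paste, collapse = "&")
  list(sizes = vapply(sets, length, integer(1)),
       union_size = length(Reduce(union, sets)),
       intersections = inter,
       shared = Reduce(intersect, sets))
}

#' Chi-square test on a 2x2 cell-line by peak-time table
#'
#' Pearson chi-square with df = 1, without continuity correction by
#' default (togglable).
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param correct apply the Yates continuity correction? Default `FALSE`.
#' @return list with `statistic` and `p`.
#' @export
timing_chisq <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2")
  if (any(tab < 0)) stop("counts must be >= 0")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Call p53 dependence of DDR miRNAs
#'
#' A miRNA is `p53_dependent` when it is significant in the wild-type
#' background but in the TP53-null background is not significant and shows
#' |M| below `m_thresh / 2` at its wild-type peak time; `p53_independent`
#' when significant (same sign) in both; otherwise `indeterminate`
#' (including miRNAs with missing knockout data).
#'
#' @param wt_records,ko_records data.frames with columns `mirna`, `time_h`,
#'   `M`, `significant` for the wild-type and knockout backgrounds of the
#'   same cell line.
#' @param m_thresh the significance fold-change threshold (log2), default
#'   0.75; the knockout residual-effect bound is half of it.
#' @return data.frame with columns `mirna`, `call`, `M_wt`, `M_ko`,
#'   `peak_time`.
#' @export
p53_dependence <- function(wt_records, ko_records, m_thresh = 0.75) {
  out <- list()
  for (id in unique(wt_records$mirna)) {
    wt <- wt_records[wt_records$mirna == id, ]
    if (!nrow(wt)) next
    peak <- wt$time_h[which.max(abs(wt$M))]
    wt_peak <- wt[wt$time_h == peak, ][1L, ]
    ko <- ko_records[ko_records$mirna == id & ko_records$time_h == peak, ]
    if (!nrow(ko)) {
      out[[id]] <- data.frame(mirna = id, call = "indeterminate",
                              M_wt = wt_peak$M, M_ko = NA_real_,
                              peak_time = peak, stringsAsFactors = FALSE)
      next
    }
    ko <- ko[1L, ]
    wt_sig <- isTRUE(wt_peak$significant)
    ko_sig <- isTRUE(ko$significant)
    call <- if (wt_sig && !ko_sig && abs(ko$M) < m_thresh / 2) {
      "p53_dependent"
    } else if (wt_sig && ko_sig && sign(wt_peak$M) == sign(ko$M)) {
      "p53_independent"
    } else {
      "indeterminate"
    }
    out[[id]] <- data.frame(mirna = id, call = call, M_wt = wt_peak$M,
                            M_ko = ko$M, peak_time = peak,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
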