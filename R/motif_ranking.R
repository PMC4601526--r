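#' Read position frequency matrices in JASPAR text format
#'
#' Parses records of the form `>ID name` followed by four lines
#' `A [ 1 2 ... ]` etc., and converts counts to column-normalized
#' probabilities after adding `pseudo` to every cell.
#'
#' @param path PFM text file (one or more records).
#' @param pseudo pseudocount mass added per cell before normalization,
#'   default 0.01.
#' @return named list of PWMs: 4 x L probability matrices with rownames
#'   `A,C,G,T`; every column sums to 1.
#' @export
read_jaspar_pfm <- function(path, pseudo = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no PFM records found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    id <- strsplit(sub("^>\\s*", "", block[1L]), "\\s+")[[1L]][1L]
    rows <- block[-1L]
    if (length(rows) != 4L)
      stop("PFM record '", id, "' must have 4 base rows")
    m <- t(vapply(rows, function(l) {
      nums <- regmatches(l, gregexpr("[0-9.eE+-]+", l))[[1L]]
      base <- sub("^\\s*([ACGT]).*", "\\1", l)
      as.numeric(nums)
    }, numeric(length(regmatches(rows[1L],
      gregexpr("[0-9.eE+-]+", rows[1L]))[[1L]]))))
    bases <- sub("^\\s*([ACGT]).*", "\\1", rows)
    if (!setequal(bases, c("A", "C", "G", "T")))
      stop("PFM record '", id, "' rows must be labelled A, C, G, T")
    rownames(m) <- bases
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    m <- m + pseudo
    m <- sweep(m, 2L, colSums(m), `/`)
    out[[id]] <- m
  }
  out
}

#' Delineate a miRNA regulatory region
#'
#' Window rules relative to the anchor coordinate, on the plus strand:
#' intergenic miRNA/cluster starts get `[anchor - 5000, anchor + 500)`,
#' host-gene transcription start sites `[TSS - 4000, TSS + 2000)`, and
#' intragenic miRNA/cluster starts `[anchor - 3500, anchor - 500)`.
#' On the minus strand the window is mirrored (upstream = larger
#' coordinates). Windows are clipped at contig bounds with a warning.
#' Intragenic miRNAs get two regions (host TSS and intragenic anchor);
#' their feature score is later the maximum over both.
#'
#' @param anchor 0-based anchor coordinate (miRNA/cluster start or host
#'   TSS).
#' @param kind `"intergenic_anchor"`, `"host_tss"` or `"intragenic_anchor"`.
#' @param strand `"+"` or `"-"`.
#' @param contig_length contig length in bp for bounds clipping.
#' @return integer vector `c(start, end)`, 0-based half-open.
#' @export
delineate_promoter <- function(anchor,
                               kind = c("intergenic_anchor", "host_tss",
                                        "intragenic_anchor"),
                               strand = c("+", "-"),
                               contig_length = Inf) {
  kind <- match.arg(kind)
  strand <- match.arg(strand)
  if (anchor < 0 || anchor > contig_length)
    stop("anchor beyond contig bounds")
  win <- switch(kind,
                intergenic_anchor = c(-5000, 500),
                host_tss = c(-4000, 2000),
                intragenic_anchor = c(-3500, -500))
  if (strand == "+") {
    start <- anchor + win[1L]; end <- anchor + win[2L]
  } else {
    start <- anchor - win[2L]; end <- anchor - win[1L]
  }
  if (start < 0 || end > contig_length) {
    warning("window clipped at contig bounds")
    start <- max(0, start); end <- min(contig_length, end)
  }
  c(start = as.integer(start), end = as.integer(end))
}

# sequence string -> integer codes A=1 C=2 G=3 T=4, NA otherwise
.seq_codes <- function(seq) {
  match(strsplit(toupper(seq), "")[[1L]], c("A", "C", "G", "T"))
}

.revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(seq)), "")[[1L]]),
        collapse = "")
}

#' Scan a sequence with a PWM
#'
#' Computes the log2-odds score
#' `score(i) = sum_j log2(pwm[base_{i+j-1}, j] / background[base])`
#' at every start position on both strands; the reverse strand scans the
#' reverse complement (scores reported at forward-strand start positions
#' of the site). Windows containing `N` score `-Inf`.
#'
#' @param seq nucleotide string over `{A,C,G,T,N}`.
#' @param pwm 4 x L probability matrix (rownames `A,C,G,T`).
#' @param background length-4 base probability vector (A,C,G,T), default
#'   uniform.
#' @return list with numeric vectors `forward` and `reverse` of length
#'   `nchar(seq) - L + 1`.
#' @export
scan_pwm <- function(seq, pwm, background = rep(0.25, 4)) {
  .check_alphabet(seq, "sequence")
  L <- ncol(pwm)
  n <- nchar(seq)
  if (n < L) stop("sequence shorter than the motif")
  if (abs(sum(background) - 1) > 1e-6)
    stop("background must sum to 1")
  lo <- log2(pwm / background)          # 4 x L
  scan1 <- function(codes) {
    np <- length(codes) - L + 1L
    s <- numeric(np)
    for (j in seq_len(L)) {
      col <- lo[, j]
      v <- unname(col[codes[j:(j + np - 1L)]])
      v[is.na(v)] <- -Inf               # N never matches
      s <- s + v
    }
    s
  }
  fwd <- scan1(.seq_codes(seq))
  rev_scores <- scan1(.seq_codes(.revcomp(seq)))
  # reverse-strand site starting at forward position i covers
  # [i, i+L-1]; in the reverse complement it starts at n-L+2-i
  list(forward = fwd, reverse = rev(rev_scores))
}

#' Homotypic CRM score of a regulatory region
#'
#' Finds all motif hits (any PWM, either strand) with log2-odds score
#' above `hit_floor`, then, within every sliding window of `window` bp,
#' greedily selects the best non-overlapping hits and sums their scores.
#' The region score is the maximum over windows, floored at 0, so every
#' region returns a score (the zero-cluster-threshold convention).
#'
#' @param seq region sequence.
#' @param pwms named list of PWMs (see [read_jaspar_pfm()]).
#' @param background length-4 base probabilities, default uniform; see
#'   [background_from_regions()].
#' @param window homotypic-cluster window in bp, default 500.
#' @param hit_floor minimum log2-odds for a hit to count, default 0.
#' @return single numeric score (>= 0); attribute `"hits"` holds the
#'   selected hit table of the best window.
#' @export
crm_score <- function(seq, pwms, background = rep(0.25, 4), window = 500L,
                      hit_floor = 0) {
  if (!length(pwms)) stop("empty PWM list")
  n <- nchar(seq)
  hits <- list()
  for (id in names(pwms)) {
    L <- ncol(pwms[[id]])
    if (n < L) next
    sc <- scan_pwm(seq, pwms[[id]], background)
    for (strand in c("forward", "reverse")) {
      pos <- which(sc[[strand]] > hit_floor)
      if (length(pos))
        hits[[length(hits) + 1L]] <- data.frame(
          start = pos, end = pos + L - 1L, score = sc[[strand]][pos],
          pwm = id, strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(structure(0, hits = NULL))
  h <- do.call(rbind, hits)
  h <- h[order(-h$score, h$start), ]

  greedy <- function(sub) {
    # best-first non-overlapping selection
    sel <- logical(nrow(sub))
    occ_end <- integer(0); occ_start <- integer(0)
    total <- 0
    for (i in seq_len(nrow(sub))) {
      if (!any(sub$start[i] <= occ_end & sub$end[i] >= occ_start)) {
        sel[i] <- TRUE
        occ_start <- c(occ_start, sub$start[i])
        occ_end <- c(occ_end, sub$end[i])
        total <- total + sub$score[i]
      }
    }
    list(total = total, hits = sub[sel, , drop = FALSE])
  }

  window <- min(window, n)
  # the max over sliding windows is attained when the window is flush
  # with a hit boundary; evaluate those candidate offsets only
  cand <- unique(pmax(1L, pmin(c(h$start, h$end - window + 1L),
                               n - window + 1L)))
  best <- list(total = 0, hits = NULL)
  for (w in cand) {
    sub <- h[h$start >= w & h$end <= w + window - 1L, , drop = FALSE]
    if (!nrow(sub)) next
    if (sum(sub$score) <= best$total) next   # upper bound prune
    g <- greedy(sub)
    if (g$total > best$total) best <- g
  }
  structure(max(0, best$total), hits = best$hits)
}

#' Zero-order background model from a region set
#'
#' Base frequencies pooled over the given sequences with a pseudocount,
#' for use as the [scan_pwm()]/[crm_score()] background.
#'
#' @param seqs character vector of sequences.
#' @param pseudo pseudocount per base, default 0.01.
#' @return length-4 probability vector (A, C, G, T).
#' @export
background_from_regions <- function(seqs, pseudo = 0.01) {
  counts <- stats::setNames(numeric(4), c("A", "C", "G", "T"))
  for (b in names(counts))
    counts[b] <- sum(nchar(seqs) - nchar(gsub(b, "", seqs, fixed = TRUE)))
  p <- counts + pseudo
  p / sum(p)
}

#' Rank features by score within one species
#'
#' Ranks descending by score; the normalized rank of the best of `N`
#' features is `1/N` and ties share the mean of their positions.
#'
#' @param scores named numeric vector (feature id -> CRM score), length
#'   >= 2.
#' @return named numeric vector of normalized ranks in `(0, 1]`.
#' @export
rank_species <- function(scores) {
  if (length(scores) < 2L) stop("need at least two features")
  r <- rank(-scores, ties.method = "average") / length(scores)
  stats::setNames(r, names(scores))
}

#' Aggregate per-species ranks by order statistics
#'
#' Computes `q = P(U_(1) <= r_(1), ..., U_(n) <= r_(n))`, the probability
#' that the order statistics of `n` independent uniform(0,1) variables are
#' jointly bounded by the sorted observed normalized ranks, through the
#' stable recursion
#' `V_k = sum_{i=1..k} (-1)^(i-1) V_{k-i} r_{n-k+1}^i / i!` over ranks
#' sorted ascending, with `q = n! V_n`. Missing species are treated as
#' rank 1.0. The final score is `-log(q)` (natural log).
#'
#' @param ranks numeric vector of normalized ranks in `(0, 1]`; `NA`
#'   entries count as 1.0.
#' @return list with `q` and `final_score`.
#' @export
aggregate_order_statistics <- function(ranks) {
  ranks[is.na(ranks)] <- 1
  if (!length(ranks)) stop("need at least one rank")
  if (any(ranks <= 0 | ranks > 1)) stop("ranks must lie in (0, 1]")
  r <- sort(ranks)
  n <- length(r)
  v <- numeric(n + 1L)
  v[1L] <- 1                                   # V_0
  for (k in seq_len(n)) {
    i <- seq_len(k)
    v[k + 1L] <- sum((-1)^(i - 1) * v[k - i + 1L] *
                       r[n - k + 1L]^i / factorial(i))
  }
  q <- min(1, max(0, factorial(n) * v[n + 1L]))
  list(q = q, final_score = if (q > 0) -log(q) else Inf)
}

#' Calibrate aggregated rank probabilities against their null distribution
#'
#' The aggregated `q` of [aggregate_order_statistics()] is a joint
#' cumulative probability; for more than one species a joint CDF evaluated
#' at a random rank vector is not itself uniformly distributed, so raw `q`
#' values are poorly calibrated as significance measures. This function
#' maps observed `q` values through the Monte-Carlo null CDF of the Q
#' statistic (rank vectors of `n_species` independent uniforms): by the
#' probability integral transform the result is uniform under the null.
#' The transform is monotone, so feature order is unchanged.
#'
#' @param q numeric vector of aggregated probabilities.
#' @param n_species number of aggregated rankings.
#' @param n_null null sample size, default 20000.
#' @param seed seed for the null sample, default 1.
#' @return numeric vector of calibrated probabilities in (0, 1).
#' @export
calibrate_rank_aggregation <- function(q, n_species, n_null = 20000L,
                                       seed = 1L) {
  set.seed(seed)
  null_q <- vapply(seq_len(n_null), function(i)
    aggregate_order_statistics(stats::runif(n_species))$q, numeric(1))
  vapply(q, function(x) (sum(null_q <= x) + 1) / (n_null + 1), numeric(1))
}

#' Cross-species motif ranking of regulatory features
#'
#' Scores every feature in every species with [crm_score()] (a feature
#' with several candidate regions takes the maximum), ranks features
#' within each species, aggregates the per-species ranks with
#' [aggregate_order_statistics()], and orders features by the final
#' `-log(q)` score (descending; ties broken lexicographically by id).
#'
#' @param regions named list (species -> named character vector of region
#'   sequences; several entries may share a feature id, e.g. host-TSS and
#'   intragenic windows of one miRNA).
#' @param pwms named list of PWMs.
#' @param window,hit_floor passed to [crm_score()].
#' @param background `"regions"` (zero-order model fit per species,
#'   default) or a length-4 probability vector.
#' @return data.frame sorted by `final_score` descending with columns
#'   `feature`, `q`, `final_score`, `rank` (dense, best = 0) and one
#'   `score.<species>` column per species.
#' @export
rank_motif_features <- function(regions, pwms, window = 500L,
                                hit_floor = 0, background = "regions") {
  species <- names(regions)
  features <- sort(unique(unlist(lapply(regions, names))))
  score_mat <- matrix(NA_real_, length(features), length(species),
                      dimnames = list(features, species))
  rank_mat <- score_mat
  for (sp in species) {
    seqs <- regions[[sp]]
    bg <- if (identical(background, "regions"))
      background_from_regions(seqs) else background
    sc <- vapply(seqs, crm_score, numeric(1), pwms = pwms,
                 background = bg, window = window, hit_floor = hit_floor)
    per_feature <- tapply(sc, names(seqs), max)   # max over regions
    score_mat[names(per_feature), sp] <- as.numeric(per_feature)
    present <- !is.na(score_mat[, sp])
    if (sum(present) >= 2L)
      rank_mat[present, sp] <- rank_species(score_mat[present, sp])
  }
  agg <- apply(rank_mat, 1L, function(r) {
    a <- aggregate_order_statistics(r)
    c(a$q, a$final_score)
  })
  out <- data.frame(feature = features, q = agg[1L, ],
                    final_score = agg[2L, ], stringsAsFactors = FALSE)
  sc_df <- as.data.frame(score_mat)
  names(sc_df) <- paste0("score.", species)
  out <- cbind(out, sc_df)
  out <- out[order(-out$final_score, out$feature), ]
  out$rank <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  out
}
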