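#' Running enrichment score over a ranked list
#'
#' Walks down a ranked list (best first): a set member ("hit") at rank `i`
#' increments the running score by `|score_i|^p / sum_set |score|^p`, a
#' non-member decrements it by `1/(N - N_hits)`. The enrichment score (ES)
#' is the running value furthest from zero (earliest position on ties) and
#' the leading edge contains the set members at or before the peak (for a
#' positive ES; at or after it for a negative ES). By construction the
#' running score returns to zero after the last position.
#'
#' @param ids character vector of the ranked feature ids, best first.
#' @param scores rank-metric values aligned with `ids`, non-increasing.
#' @param gene_set character vector of set member ids (subset of `ids`,
#'   non-empty, proper subset).
#' @param p hit weight exponent, default 1 (the standard weighted scheme).
#' @return list with `running` (length N), `ES`, `peak` (0-based rank of
#'   the peak), `hits` (0-based ranks of the members, sorted) and
#'   `leading_edge` (member ids).
#' @export
running_es <- function(ids, scores, gene_set, p = 1) {
  N <- length(ids)
  if (length(scores) != N) stop("ids and scores must align")
  if (is.unsorted(rev(scores))) stop("scores must be non-increasing")
  hit <- ids %in% gene_set
  nh <- sum(hit)
  if (nh == 0L || nh == N)
    stop("gene_set must be a non-empty proper subset of ids")
  w <- abs(scores)^p
  denom <- sum(w[hit])
  if (denom == 0) stop("all set members have zero rank-metric score")
  step <- ifelse(hit, w / denom, -1 / (N - nh))
  running <- cumsum(step)
  peak <- which.max(abs(running))          # earliest on ties
  ES <- running[peak]
  hits0 <- which(hit) - 1L
  leading <- if (ES >= 0) ids[hit & seq_len(N) <= peak]
             else ids[hit & seq_len(N) >= peak]
  list(running = running, ES = ES, peak = peak - 1L,
       hits = hits0, leading_edge = leading)
}

#' Core-enrichment flags for set members
#'
#' @param result a [running_es()] result.
#' @return named character vector over the set members (ordered by rank):
#'   `"Yes"` for leading-edge (core) members, `"No"` otherwise.
#' @export
core_enrichment_flags <- function(result) {
  member_ranks <- result$hits
  flags <- if (result$ES >= 0) {
    ifelse(member_ranks <= result$peak, "Yes", "No")
  } else {
    ifelse(member_ranks >= result$peak, "Yes", "No")
  }
  stats::setNames(flags, paste0("rank_", member_ranks))
}

#' Preranked GSEA with a gene-set permutation null
#'
#' For each gene set, the observed ES is compared with the ES of `n_perm`
#' random same-size sets drawn without replacement from the ranked ids
#' (seeded). NES = ES / mean(null ES of matching sign) — the "mean div"
#' normalization — and the nominal p is the fraction of same-sign null ES
#' at least as extreme as the observed. FDR q follows the standard
#' pooled-null procedure: for a set with NES*, the fraction of all
#' (sign-matched, normalized) null NES beyond NES* divided by the fraction
#' of observed NES beyond NES*, clipped to [0, 1].
#'
#' @param ids,scores ranked list as in [running_es()].
#' @param gene_sets named list of character vectors.
#' @param n_perm number of permutations, >= 100; default 1000.
#' @param seed integer seed; identical seeds give identical results.
#' @param p hit weight exponent, default 1.
#' @return data.frame with one row per set: `set_id`, `size`, `ES`, `NES`,
#'   `p_nominal`, `fdr_q`, `peak`, `leading_edge` (comma-separated),
#'   `n_perm`, `seed`; the attribute `"detail"` keeps each set's full
#'   [running_es()] result and null ES vector.
#' @export
gsea_preranked <- function(ids, scores, gene_sets, n_perm = 1000L,
                           seed = 1L, p = 1) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (is.null(names(gene_sets)))
    names(gene_sets) <- paste0("set", seq_along(gene_sets))
  obs <- lapply(gene_sets, function(gs)
    running_es(ids, scores, intersect(gs, ids), p = p))
  sizes <- vapply(gene_sets, function(gs) length(intersect(gs, ids)),
                  integer(1))

  null_es <- list()
  set.seed(seed)
  for (k in seq_along(gene_sets)) {
    n <- sizes[k]
    null_es[[k]] <- vapply(seq_len(n_perm), function(i)
      running_es(ids, scores, sample(ids, n), p = p)$ES, numeric(1))
  }

  nes_of <- function(es, null) {
    same <- null[sign(null) == sign(es)]
    if (!length(same) || mean(abs(same)) == 0) return(NA_real_)
    es / mean(abs(same))
  }
  ES <- vapply(obs, `[[`, numeric(1), "ES")
  NES <- vapply(seq_along(obs), function(k) nes_of(ES[k], null_es[[k]]),
                numeric(1))
  if (all(is.na(NES))) stop("degenerate permutation null")
  p_nom <- vapply(seq_along(obs), function(k) {
    same <- null_es[[k]][sign(null_es[[k]]) == sign(ES[k])]
    if (!length(same)) return(0)
    sum(abs(same) >= abs(ES[k])) / length(same)
  }, numeric(1))

  # pooled normalized null for FDR
  null_nes <- unlist(lapply(seq_along(obs), function(k) {
    null <- null_es[[k]]
    pos <- null[null >= 0]; neg <- null[null < 0]
    c(if (length(pos) && mean(pos) > 0) pos / mean(pos),
      if (length(neg) && mean(abs(neg)) > 0) neg / mean(abs(neg)))
  }))
  fdr_q <- vapply(seq_along(obs), function(k) {
    nes <- NES[k]
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- mean(null_nes >= nes)
      den <- mean(NES[!is.na(NES)] >= nes)
    } else {
      num <- mean(null_nes <= nes)
      den <- mean(NES[!is.na(NES)] <= nes)
    }
    if (den == 0) return(0)
    min(1, max(0, num / den))
  }, numeric(1))

  res <- data.frame(
    set_id = names(gene_sets), size = sizes, ES = ES, NES = NES,
    p_nominal = p_nom, fdr_q = fdr_q,
    peak = vapply(obs, `[[`, numeric(1), "peak"),
    leading_edge = vapply(obs, function(o)
      paste(o$leading_edge, collapse = ","), character(1)),
    n_perm = n_perm, seed = seed, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "detail") <- list(observed = obs, null_es = null_es)
  res
}

#' Read and write GMT gene-set files
#'
#' GMT: one set per line, tab-separated `name`, `description`, members.
#'
#' @param path GMT file.
#' @param sets named list of character vectors (for writing).
#' @param description per-set description, recycled.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(out) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1L)
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(k)
    paste(c(names(sets)[k], description[k], sets[[k]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ranked list TSV (id, score)
#'
#' @param path two-column TSV with a header.
#' @return data.frame with columns `id`, `score`, sorted by score
#'   descending (ties by id).
#' @export
read_ranked_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("id", "score")
  df <- df[order(-df$score, df$id), ]
  rownames(df) <- NULL
  df
}
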