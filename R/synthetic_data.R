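#' Simulation configuration
#'
#' Defaults emulate the study design: 3 cell lines (MCF10A, HCT116 and its
#' TP53-null derivative) sampled at 0, 4 and 24 h after damage with 2
#' technical replicates each; 965 miRNAs (the number surviving the
#' aggregate-count filter); libraries of about 12 million miRNA-mapped
#' reads with 15% coefficient of variation; near-Poisson dispersion
#' (technical replication only); spiked archetypes A-D sized as the
#' MCF10A kinetic clusters (23/24/4/31) with a 4-fold peak effect and 75%
#' of induced spikes p53-dependent.
#'
#' @param seed integer seed; all generator outputs are deterministic in it.
#' @param n_mirnas number of miRNAs.
#' @param n_species number of pseudo-species for promoter simulation.
#' @param library_size_mean,library_size_cv library-size model.
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param spike_sets named list `A,B,C,D`, each
#'   `list(n =, effect =, p53_dependent_frac =)`; `effect` is the peak
#'   log2 fold change (positive for A/B, negative for C/D), the off-peak
#'   effect is a third of it (same sign). Archetypes A/C peak at 4 h,
#'   B/D at 24 h.
#' @param cluster_geometry named counts of loci categories:
#'   `intragenic_single`, `intragenic_clustered`, `intergenic_single`,
#'   `intergenic_clustered` (clustered counts are split into clusters of
#'   2-4 loci). Defaults follow the observed genome-wide proportions.
#' @param motif_plant `list(n_features =, sites_per_feature =,
#'   species_coverage =)` for promoter planting.
#' @param region_length simulated regulatory-region length in bp.
#' @param gc background GC content of simulated regions.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_mirnas = 965L, n_species = 10L,
                       library_size_mean = 12e6, library_size_cv = 0.15,
                       dispersion = 0.001,
                       spike_sets = list(
                         A = list(n = 23L, effect = 2, p53_dependent_frac = 0.75),
                         B = list(n = 24L, effect = 2, p53_dependent_frac = 0.75),
                         C = list(n = 4L, effect = -2, p53_dependent_frac = 0),
                         D = list(n = 31L, effect = -2, p53_dependent_frac = 0)),
                       cluster_geometry = NULL,
                       motif_plant = list(n_features = 20L,
                                          sites_per_feature = 3L,
                                          species_coverage = 0.6),
                       region_length = 1000L, gc = 0.41) {
  if (is.null(cluster_geometry)) {
    n <- n_mirnas
    ic <- round(0.21 * n); is_ <- round(0.50 * n); gc_ <- round(0.06 * n)
    cluster_geometry <- c(intragenic_single = is_,
                          intragenic_clustered = ic,
                          intergenic_clustered = gc_,
                          intergenic_single = n - ic - is_ - gc_)
  }
  if (sum(cluster_geometry) != n_mirnas)
    stop("cluster_geometry must sum to n_mirnas")
  structure(list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
                 n_species = as.integer(n_species),
                 library_size_mean = library_size_mean,
                 library_size_cv = library_size_cv,
                 dispersion = dispersion, spike_sets = spike_sets,
                 cluster_geometry = cluster_geometry,
                 motif_plant = motif_plant,
                 region_length = as.integer(region_length), gc = gc),
            class = "sim_config")
}

# effect (log2) of a miRNA at a time point given archetype bookkeeping
.archetype_effect <- function(label, effect, time_h) {
  peak <- switch(label, A = 4, B = 24, C = 4, D = 24)
  if (time_h == 0) 0 else if (time_h == peak) effect else effect / 3
}

#' Simulate a raw miRNA count table with planted DDR structure
#'
#' Baseline relative abundances are log-normal; per condition one
#' "biological" negative-binomial draw is made per miRNA and the two
#' technical replicates are independent binomial thinnings of it, with
#' thinning fractions carrying the library-size variation. Spiked miRNAs
#' follow the archetype kinetics (A/C peak at 4 h, B/D at 24 h; off-peak
#' effect = a third of the peak effect); effects flagged p53-dependent
#' are zeroed in the TP53-null cell line.
#'
#' @param cfg a [sim_config()].
#' @return list with `table` (raw count table, 18 columns by default) and
#'   `truth` (data.frame with per-miRNA `mirna`, `archetype` (`"null"` or
#'   A-D), `effect`, `p53_dependent`, `baseline_prop` and expected
#'   baseline count `expected_count`).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_mirnas
  ids <- sprintf("miR-sim-%04d", seq_len(n))
  prop <- rlnorm(n, meanlog = 0, sdlog = 2)
  prop <- prop / sum(prop)

  arch <- rep("null", n)
  p53dep <- rep(FALSE, n)
  effect <- rep(0, n)
  free <- seq_len(n)
  for (lab in names(cfg$spike_sets)) {
    ss <- cfg$spike_sets[[lab]]
    if (ss$n == 0L) next
    pick <- sample(free, ss$n)
    free <- setdiff(free, pick)
    arch[pick] <- lab
    effect[pick] <- ss$effect
    ndep <- round(ss$p53_dependent_frac * ss$n)
    if (ndep > 0L) p53dep[pick[seq_len(ndep)]] <- TRUE
  }

  cell_lines <- data.frame(
    cell_line = c("MCF10A", "HCT116", "HCT116"),
    genotype = c("WT", "WT", "TP53KO"), stringsAsFactors = FALSE)
  times <- c(0, 4, 24)
  cols <- list(); meta <- list()
  for (ci in seq_len(nrow(cell_lines))) {
    for (t in times) {
      mult <- vapply(seq_len(n), function(i) {
        e <- if (arch[i] == "null") 0 else
          .archetype_effect(arch[i], effect[i], t)
        if (cell_lines$genotype[ci] == "TP53KO" && p53dep[i]) e <- 0
        2^e
      }, numeric(1))
      mu <- 2 * cfg$library_size_mean * prop * mult   # both reps pooled
      bio <- if (cfg$dispersion > 0) {
        rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
      } else {
        rpois(n, mu)
      }
      for (rep_i in 1:2) {
        thin <- 0.5 * exp(rnorm(1, 0, cfg$library_size_cv))
        thin <- min(thin, 1)
        cnt <- rbinom(n, size = bio, prob = thin)
        key <- sprintf("%s_%s_%dh_r%d", cell_lines$cell_line[ci],
                       cell_lines$genotype[ci], t, rep_i)
        cols[[key]] <- cnt
        meta[[key]] <- data.frame(cell_line = cell_lines$cell_line[ci],
                                  genotype = cell_lines$genotype[ci],
                                  time_h = t, replicate = rep_i,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- ids
  tab <- count_table(m, do.call(rbind, meta))
  # expected baseline count in a merged (two-replicate) library
  truth <- data.frame(mirna = ids, archetype = arch, effect = effect,
                      p53_dependent = p53dep, baseline_prop = prop,
                      expected_count = 2 * cfg$library_size_mean * prop,
                      stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

#' Simulate small-RNA reads from a count table
#'
#' Each count emits that many reads equal to the mature sequence with the
#' adapter appended; an optional contaminant fraction adds poly(A) and
#' too-short reads (which [filter_reads()] removes). With no contaminants,
#' trimming + [quantify_exact()] reproduces the table exactly.
#'
#' @param table a raw count table (small! one read per count is emitted).
#' @param reference data.frame `id`, `sequence` covering the table rows.
#' @param adapter adapter sequence appended to every read.
#' @param seed integer seed (orders reads and draws contaminants).
#' @param contaminant_frac fraction of additional contaminant reads,
#'   default 0.
#' @return named list (sample id -> character vector of reads).
#' @export
simulate_reads <- function(table, reference, adapter, seed = 1L,
                           contaminant_frac = 0) {
  set.seed(seed)
  m <- SummarizedExperiment::assay(table, 1L)
  if (!all(rownames(m) %in% reference$id))
    stop("reference does not cover the table")
  seqs <- reference$sequence[match(rownames(m), reference$id)]
  out <- list()
  for (j in seq_len(ncol(m))) {
    reads <- rep(paste0(seqs, adapter), times = m[, j])
    if (contaminant_frac > 0 && length(reads)) {
      n_cont <- round(contaminant_frac * length(reads))
      polyA <- strrep("A", sample(18:25, n_cont, replace = TRUE))
      reads <- c(reads, paste0(polyA, adapter))
    }
    out[[colnames(m)[j]]] <- if (length(reads)) sample(reads) else character(0)
  }
  out
}

#' Simulate miRNA locus and transcript annotation
#'
#' Lays the configured categories along one chromosome: clusters have
#' intra-cluster gaps below 10 kb, all other inter-locus gaps are at least
#' 20 kb, and intragenic loci sit strictly inside a same-strand transcript.
#' Applying [classify_location()] and [classify_grouping()] to the output
#' recovers the ground-truth labels exactly.
#'
#' @param cfg a [sim_config()].
#' @return list with `loci` (`GRanges`), `transcripts` (`GRanges`) and
#'   `truth` (data.frame `mirna`, `location`, `grouping`).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  geom <- cfg$cluster_geometry
  n <- cfg$n_mirnas
  ids <- sprintf("miR-sim-%04d", seq_len(n))

  # category per miRNA, in id order
  cats <- c(rep("intragenic_single", geom["intragenic_single"]),
            rep("intragenic_clustered", geom["intragenic_clustered"]),
            rep("intergenic_single", geom["intergenic_single"]),
            rep("intergenic_clustered", geom["intergenic_clustered"]))
  if (length(cats) != n) stop("infeasible geometry")

  pos <- 50000L          # running coordinate (1-based)
  starts <- integer(n); ends <- integer(n); strands <- character(n)
  tx <- list()
  i <- 1L
  place_cluster <- function(k) {
    # returns matrix of k (start,end) with gaps < 10 kb
    s <- integer(k); e <- integer(k)
    for (q in seq_len(k)) {
      s[q] <- pos; e[q] <- pos + 79L           # 80 bp stem-loops
      gap <- if (q < k) sample(200:5000, 1L) else 0L
      pos <<- e[q] + 1L + gap
    }
    cbind(s, e)
  }
  idx_by_cat <- split(seq_len(n), cats)
  order_cats <- c("intragenic_single", "intragenic_clustered",
                  "intergenic_single", "intergenic_clustered")
  for (cc in order_cats) {
    idx <- idx_by_cat[[cc]]
    if (is.null(idx)) next
    intragenic <- grepl("intragenic", cc)
    clustered <- grepl("clustered", cc)
    while (length(idx)) {
      k <- if (clustered) min(sample(2:4, 1L), length(idx)) else 1L
      if (clustered && length(idx) - k == 1L) k <- k + 1L  # no orphan
      take <- idx[seq_len(k)]; idx <- idx[-seq_len(k)]
      strand <- sample(c("+", "-"), 1L)
      se <- place_cluster(k)
      starts[take] <- se[, 1L]; ends[take] <- se[, 2L]
      strands[take] <- strand
      if (intragenic) {
        tx[[length(tx) + 1L]] <- c(max(1L, se[1L, 1L] - 2000L),
                                   se[k, 2L] + 2000L)
        attr(tx[[length(tx)]], "strand") <- strand
      }
      pos <- pos + 20000L + sample(0:5000, 1L)   # >= 20 kb to next entity
    }
  }
  loci <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(starts, ends),
                                 strand = strands)
  names(loci) <- ids
  txg <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(vapply(tx, `[`, numeric(1), 1L),
                     vapply(tx, `[`, numeric(1), 2L)),
    strand = vapply(tx, attr, character(1), "strand"))
  names(txg) <- sprintf("HOST%04d", seq_along(txg))
  truth <- data.frame(mirna = ids,
                      location = ifelse(grepl("intragenic", cats),
                                        "intragenic", "intergenic"),
                      grouping = ifelse(grepl("clustered", cats),
                                        "clustered", "single"),
                      stringsAsFactors = FALSE)
  list(loci = loci, transcripts = txg, truth = truth)
}

# sample one site sequence from a PWM (per-column categorical draw)
.sample_site <- function(pwm) {
  paste(apply(pwm, 2L, function(p) sample(c("A", "C", "G", "T"), 1L,
                                          prob = p)), collapse = "")
}

.random_seq <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Simulate multi-species regulatory regions with planted motif clusters
#'
#' Background sequence is i.i.d. with the configured GC content. The first
#' `n_features` features (by the returned `planted` flag) receive
#' `sites_per_feature` non-overlapping sites sampled from the first PWM,
#' in a `species_coverage` fraction of the pseudo-species; site positions
#' are recorded.
#'
#' @param cfg a [sim_config()] (`motif_plant`, `region_length`, `gc`,
#'   `n_species` are used).
#' @param pwms named list of PWMs; sites are sampled from the first.
#' @param n_features total number of features; default
#'   `cfg$motif_plant$n_features * 25` (planted features are a small
#'   minority).
#' @param feature_ids optional explicit feature ids (length `n_features`
#'   is then taken from them).
#' @param planted_ids optional ids of the features to plant (must be a
#'   subset of `feature_ids`); overrides `cfg$motif_plant$n_features`.
#' @return list with `regions` (named list: species -> named character
#'   vector of sequences), `truth` (data.frame `feature`, `planted`) and
#'   `sites` (data.frame of planted site positions).
#' @export
simulate_promoters <- function(cfg, pwms, n_features = NULL,
                               feature_ids = NULL, planted_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  mp <- cfg$motif_plant
  if (!is.null(feature_ids)) n_features <- length(feature_ids)
  if (is.null(n_features)) n_features <- mp$n_features * 25L
  feats <- if (!is.null(feature_ids)) feature_ids
           else sprintf("feature-%04d", seq_len(n_features))
  planted <- if (!is.null(planted_ids)) {
    if (!all(planted_ids %in% feats))
      stop("planted_ids must be a subset of feature_ids")
    match(planted_ids, feats)
  } else {
    seq_len(mp$n_features)
  }
  if (length(planted) > n_features)
    stop("more planted features than features")
  pwm <- pwms[[1L]]
  L <- ncol(pwm)
  if (L > cfg$region_length) stop("site longer than region")
  species <- sprintf("species%02d", seq_len(cfg$n_species))
  n_cov <- max(1L, round(mp$species_coverage * cfg$n_species))
  regions <- list(); sites <- list()
  for (sp in species) regions[[sp]] <- character(0)
  cover <- lapply(planted, function(i) sample(species, n_cov))
  for (sp in species) {
    seqs <- vapply(seq_len(n_features), function(i)
      .random_seq(cfg$region_length, cfg$gc), character(1))
    for (j in seq_along(planted)) {
      i <- planted[j]
      if (!(sp %in% cover[[j]]) || mp$sites_per_feature == 0L) next
      # non-overlapping slots
      slot_w <- cfg$region_length %/% mp$sites_per_feature
      if (slot_w < L) stop("site longer than region slot")
      s <- seqs[i]
      for (q in seq_len(mp$sites_per_feature)) {
        off <- (q - 1L) * slot_w + sample(seq_len(slot_w - L + 1L), 1L)
        site <- .sample_site(pwm)
        substr(s, off, off + L - 1L) <- site
        sites[[length(sites) + 1L]] <- data.frame(
          feature = feats[i], species = sp, start = off, site = site,
          stringsAsFactors = FALSE)
      }
      seqs[i] <- s
    }
    names(seqs) <- feats
    regions[[sp]] <- seqs
  }
  truth <- data.frame(feature = feats,
                      planted = seq_len(n_features) %in% planted,
                      stringsAsFactors = FALSE)
  list(regions = regions, truth = truth,
       sites = if (length(sites)) do.call(rbind, sites) else NULL)
}

#' Write simulated regions as per-species FASTA
#'
#' @param regions named list as returned by [simulate_promoters()].
#' @param dir output directory (created if needed); one
#'   `<species>.fasta` per species, headers = feature ids.
#' @return invisibly, the written paths.
#' @export
write_region_fasta <- function(regions, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (sp in names(regions)) {
    p <- file.path(dir, paste0(sp, ".fasta"))
    x <- Biostrings::DNAStringSet(regions[[sp]])
    Biostrings::writeXStringSet(x, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
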