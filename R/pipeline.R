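#' Pipeline configuration
#'
#' Bundles the stage thresholds (defaults are the standard analysis
#' parameters used throughout the package), the simulation configuration
#' and the random seed.
#'
#' @param sim a [sim_config()] (its seed drives all randomness).
#' @param m_thresh,a_thresh,alpha significance thresholds, defaults 0.75,
#'   5 and 0.05.
#' @param max_gap clustering distance for genomic grouping, default 10000.
#' @param window,hit_floor CRM scoring parameters, defaults 500 and 0.
#' @param gsea_n_perm GSEA permutations, default 1000.
#' @param preset kinetic-cluster label convention, `"mcf10a"`,
#'   `"hct116"` or `"custom"`.
#' @param method count test, default `"exact_fisher"`.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), m_thresh = 0.75,
                            a_thresh = 5, alpha = 0.05, max_gap = 10000L,
                            window = 500L, hit_floor = 0,
                            gsea_n_perm = 1000L, preset = "mcf10a",
                            method = "exact_fisher") {
  structure(list(sim = sim, m_thresh = m_thresh, a_thresh = a_thresh,
                 alpha = alpha, max_gap = max_gap, window = window,
                 hit_floor = hit_floor, gsea_n_perm = gsea_n_perm,
                 preset = preset, method = method),
            class = "pipeline_config")
}

#' Run the full synthetic-data pipeline
#'
#' End-to-end driver on simulated inputs: simulates a count table, calls
#' differential expression against the 0 h controls, extracts per-cell-line
#' DDR sets and their overlap, applies the robustness filter, assigns
#' kinetic clusters, classifies genomic context and tests category
#' enrichment, simulates multi-species regulatory regions with motif
#' clusters planted at the p53-dependent induced miRNAs, ranks all miRNAs
#' by aggregated motif score, runs preranked GSEA of the induced DDR set
#' on that ranking, and summarises p53 dependence against the TP53-null
#' samples. Fully deterministic under the configured seed.
#'
#' @param config a [pipeline_config()].
#' @param pwms named list of PWMs for the motif stage; default: the
#'   bundled synthetic p53-like matrix.
#' @param out_dir optional directory; when given, the report tables are
#'   written as TSV/JSON.
#' @return named list of stage outputs: `truth`, `diffexpr`, `ddr_sets`,
#'   `venn`, `robust_induced`, `clusters`, `context`, `enrichment`,
#'   `motif_ranking`, `gsea`, `p53_dependence`, `log` (stage record
#'   counts).
#' @export
run_pipeline <- function(config = pipeline_config(), pwms = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(pwms))
    pwms <- read_jaspar_pfm(system.file("extdata", "p53_synthetic.pfm",
                                        package = "mirddr"))
  log <- list()
  sim <- simulate_counts(config$sim)
  log$simulated <- c(mirnas = nrow(sim$truth),
                     samples = ncol(SummarizedExperiment::assay(sim$table)))

  de <- run_diffexpr(sim$table, method = config$method,
                     m_thresh = config$m_thresh, a_thresh = config$a_thresh,
                     alpha = config$alpha)
  wt <- de[de$genotype == "WT", ]
  ko <- de[de$genotype == "TP53KO", ]
  log$diffexpr <- c(records = nrow(de), m_tests = attr(de, "m_tests"))

  # per-cell-line DDR sets (significant at any time point, WT)
  ddr_sets <- lapply(split(wt, wt$cell_line), function(d)
    sort(unique(d$mirna[d$significant])))
  venn <- compare_ddr_sets(ddr_sets)
  log$ddr <- c(union = venn$union_size, venn$sizes)

  robust_ind <- robust_filter(wt, "induced")
  robust_rep <- robust_filter(wt, "repressed")
  log$robust <- c(induced = length(robust_ind),
                  repressed = length(robust_rep))

  # kinetic clusters per cell line over that line's DDR miRNAs
  clusters <- lapply(names(ddr_sets), function(cl) {
    d <- wt[wt$cell_line == cl & wt$mirna %in% ddr_sets[[cl]], ]
    m4 <- d[d$time_h == 4, c("mirna", "M")]
    m24 <- d[d$time_h == 24, c("mirna", "M")]
    rec <- merge(m4, m24, by = "mirna", suffixes = c("4", "24"))
    if (!nrow(rec)) return(NULL)
    assign_kinetic_clusters(rec, preset = if (config$preset == "custom")
      "mcf10a" else config$preset)
  })
  names(clusters) <- names(ddr_sets)

  ann <- simulate_annotation(config$sim)
  labels <- merge(classify_location(ann$loci, ann$transcripts),
                  classify_grouping(ann$loci, config$max_gap), by = "mirna")
  ddr_union <- sort(unique(unlist(ddr_sets)))
  enrichment <- if (length(ddr_union))
    category_enrichment(ddr_union, sim$truth$mirna, labels) else NULL

  planted <- sim$truth$mirna[sim$truth$p53_dependent & sim$truth$effect > 0]
  prom <- simulate_promoters(config$sim, pwms,
                             feature_ids = sim$truth$mirna,
                             planted_ids = planted)
  ranking <- rank_motif_features(prom$regions, pwms,
                                 window = config$window,
                                 hit_floor = config$hit_floor)
  log$motif <- c(features = nrow(ranking), planted = length(planted))

  gsea <- if (length(robust_ind) >= 2) {
    gsea_preranked(ranking$feature, ranking$final_score,
                   list(ddr_induced = as.character(robust_ind)),
                   n_perm = config$gsea_n_perm, seed = config$sim$seed)
  } else NULL

  dep <- p53_dependence(
    wt[wt$cell_line == "HCT116", c("mirna", "time_h", "M", "significant")],
    ko[, c("mirna", "time_h", "M", "significant")],
    m_thresh = config$m_thresh)
  dep_ddr <- dep[dep$mirna %in% ddr_sets[["HCT116"]], ]
  log$p53 <- c(dependent = sum(dep_ddr$call == "p53_dependent"),
               assessed = nrow(dep_ddr))

  out <- list(truth = sim$truth, diffexpr = de, ddr_sets = ddr_sets,
              venn = venn, robust_induced = as.character(robust_ind),
              robust_repressed = as.character(robust_rep),
              clusters = clusters, context = labels,
              enrichment = enrichment, motif_ranking = ranking,
              gsea = gsea, p53_dependence = dep_ddr, log = log)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(de, file.path(out_dir, "diffexpr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ranking, file.path(out_dir, "motif_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$gsea))
      utils::write.table(out$gsea, file.path(out_dir, "gsea.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(lapply(log, as.list),
                         file.path(out_dir, "log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
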