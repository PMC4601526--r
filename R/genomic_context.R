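#' Classify miRNA loci as intragenic or intergenic
#'
#' A locus is intragenic when its interval is fully contained in at least
#' one annotated transcript on the same strand; the host gene is the
#' containing transcript with the smallest span (deterministic for nested
#' transcripts). Containment in an opposite-strand transcript does not
#' count.
#'
#' @param loci [GenomicRanges::GRanges] of miRNA loci (names = miRNA ids).
#' @param transcripts `GRanges` of annotated transcripts; names (or a
#'   `gene_id`/`ID` metadata column) identify the host.
#' @return data.frame with columns `mirna`, `location` (`"intragenic"` or
#'   `"intergenic"`) and `host_gene` (`NA` for intergenic loci).
#' @export
classify_location <- function(loci, transcripts) {
  if (!all(as.character(GenomicRanges::seqnames(loci)) %in%
             unique(as.character(GenomicRanges::seqnames(transcripts)))))
    stop("locus on a chromosome absent from the transcript annotation")
  tx_id <- names(transcripts)
  if (is.null(tx_id)) {
    mc <- S4Vectors::mcols(transcripts)
    tx_id <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id)
             else if ("ID" %in% names(mc)) as.character(mc$ID)
             else as.character(seq_along(transcripts))
  }
  ov <- GenomicRanges::findOverlaps(loci, transcripts, type = "within",
                                    ignore.strand = FALSE)
  location <- rep("intergenic", length(loci))
  host <- rep(NA_character_, length(loci))
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(transcripts)[sh]
    for (q in unique(qh)) {
      cand <- sh[qh == q]
      best <- cand[which.min(GenomicRanges::width(transcripts)[cand])]
      location[q] <- "intragenic"
      host[q] <- tx_id[best]
    }
  }
  ids <- names(loci)
  if (is.null(ids)) ids <- as.character(seq_along(loci))
  data.frame(mirna = ids, location = location, host_gene = host,
             stringsAsFactors = FALSE)
}

#' Classify miRNA loci as clustered or single
#'
#' Single-linkage chaining on each chromosome, strand-agnostic: two loci
#' are linked when the gap between their intervals is strictly below
#' `max_gap` (default 10 kb; a gap of exactly 10,000 bp does not link).
#' Connected components of size >= 2 are clusters.
#'
#' @param loci `GRanges` of miRNA loci (names = miRNA ids).
#' @param max_gap linking distance in bp, strict, default 10000.
#' @return data.frame with columns `mirna`, `grouping` (`"clustered"` or
#'   `"single"`) and `cluster_id` (`NA` for singles).
#' @export
classify_grouping <- function(loci, max_gap = 10000L) {
  # reduce() with min.gapwidth = max_gap merges ranges whose gap is
  # < max_gap, which is exactly the strict rule
  red <- GenomicRanges::reduce(loci, min.gapwidth = max_gap,
                               ignore.strand = TRUE,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  grouping <- rep("single", length(loci))
  cluster_id <- rep(NA_character_, length(loci))
  k <- 0L
  for (i in seq_along(red)) {
    members <- revmap[[i]]
    if (length(members) >= 2L) {
      k <- k + 1L
      grouping[members] <- "clustered"
      cluster_id[members] <- sprintf("cluster_%03d", k)
    }
  }
  ids <- names(loci)
  if (is.null(ids)) ids <- as.character(seq_along(loci))
  data.frame(mirna = ids, grouping = grouping, cluster_id = cluster_id,
             stringsAsFactors = FALSE)
}

#' Genomic-category enrichment of DDR miRNAs
#'
#' For every location x grouping category, builds the 2x2 table
#' `[[DDR in category, DDR outside], [non-DDR in category, non-DDR
#' outside]]` and computes the two-sided exact test of [count_test()].
#' Loci without a context label are reported as unassigned and excluded
#' from the tables.
#'
#' @param ddr character vector of DDR miRNA ids (subset of `all_mirnas`).
#' @param all_mirnas character vector of all miRNA ids considered.
#' @param labels data.frame with columns `mirna`, `location`, `grouping`
#'   (as from [classify_location()] + [classify_grouping()]).
#' @return data.frame with one row per category: counts, fractions and the
#'   exact two-sided `p`; the attribute `"unassigned"` lists ids without a
#'   label.
#' @export
category_enrichment <- function(ddr, all_mirnas, labels) {
  if (!length(ddr)) stop("empty DDR set")
  if (!all(ddr %in% all_mirnas)) stop("ddr must be a subset of all_mirnas")
  lab <- labels[match(all_mirnas, labels$mirna), ]
  unassigned <- all_mirnas[is.na(lab$location) | is.na(lab$grouping)]
  keep <- !(all_mirnas %in% unassigned)
  ids <- all_mirnas[keep]
  lab <- lab[keep, ]
  cat <- paste(lab$location, lab$grouping, sep = "_")
  is_ddr <- ids %in% ddr
  out <- lapply(sort(unique(cat)), function(cc) {
    a <- sum(is_ddr & cat == cc)
    b <- sum(is_ddr & cat != cc)
    c_ <- sum(!is_ddr & cat == cc)
    d <- sum(!is_ddr & cat != cc)
    data.frame(category = cc, ddr_in = a, ddr_out = b,
               nonddr_in = c_, nonddr_out = d,
               ddr_frac = a / (a + b), nonddr_frac = c_ / (c_ + d),
               p = count_test(a, a + b, c_, c_ + d,
                              method = "exact_fisher"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "unassigned") <- unassigned
  res
}

#' Read miRNA loci or transcripts from GFF3/BED
#'
#' Wraps [rtracklayer::import()]; GFF3 1-based closed coordinates and BED
#' 0-based half-open coordinates are both returned as `GRanges` (1-based
#' internally, as is conventional). Names are taken from the `Name`/`ID`
#' attribute (GFF3) or the name column (BED).
#'
#' @param path GFF3 or BED file.
#' @return a named `GRanges`.
#' @export
read_loci <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  nm <- if ("Name" %in% names(mc) && !all(is.na(mc$Name))) {
    as.character(mc$Name)
  } else if ("ID" %in% names(mc)) {
    as.character(mc$ID)
  } else if ("name" %in% names(mc)) {
    as.character(mc$name)
  } else {
    as.character(seq_along(gr))
  }
  names(gr) <- nm
  gr
}
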