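#' Build a miRNA count table
#'
#' Wraps a miRNA x sample count matrix and its per-sample metadata in a
#' [SummarizedExperiment::SummarizedExperiment] with assay `"counts"`.
#' Library sizes are defined as the per-sample totals of miRNA-mapped reads
#' and stored in `colData(x)$library_size`; for a raw table they equal the
#' column sums.
#'
#' @param counts numeric matrix, miRNAs in rows (rownames = miRNA ids),
#'   samples in columns (colnames = sample ids). Raw tables are integral and
#'   non-negative.
#' @param sample_meta data.frame with one row per column of `counts` and
#'   columns `cell_line` (character), `genotype` (`"WT"` or `"TP53KO"`),
#'   `time_h` (0, 4 or 24) and `replicate` (integer). Row order must match
#'   the column order of `counts`.
#' @param library_sizes optional per-sample positive totals; default:
#'   column sums of `counts`.
#'
#' @return a `SummarizedExperiment` with assay `"counts"` and the metadata
#'   columns above.
#' @export
count_table <- function(counts, sample_meta, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' needs rownames (miRNA ids) and colnames (sample ids)")
  if (any(counts < 0)) stop("counts must be non-negative")
  need <- c("cell_line", "genotype", "time_h", "replicate")
  miss <- setdiff(need, names(sample_meta))
  if (length(miss))
    stop("sample_meta is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(sample_meta) != ncol(counts))
    stop("sample_meta must have one row per sample column")
  if (!all(sample_meta$genotype %in% c("WT", "TP53KO")))
    stop("genotype must be 'WT' or 'TP53KO'")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  cd <- S4Vectors::DataFrame(sample_meta, library_size = unname(library_sizes),
                             row.names = colnames(counts))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
}

#' Read / write a count table as TSV
#'
#' The on-disk format is a plain tab-delimited table: first column `mirna`,
#' one column per sample, raw or normalized counts in the cells. The sample
#' sheet (TSV with columns `sample`, `cell_line`, `genotype`, `time_h`,
#' `replicate`) supplies the metadata on read.
#'
#' @param x a count table (`SummarizedExperiment`) for writing.
#' @param path TSV file path.
#' @param sample_sheet path to a sample-sheet TSV for reading.
#' @return `read_count_table()` returns a `SummarizedExperiment`;
#'   `write_count_table()` returns `path` invisibly.
#' @export
write_count_table <- function(x, path) {
  m <- SummarizedExperiment::assay(x, 1L)
  df <- data.frame(mirna = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path, sample_sheet) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  sm <- read_sample_sheet(sample_sheet)
  if (!all(colnames(m) %in% sm$sample))
    stop("sample sheet is missing samples: ",
         paste(setdiff(colnames(m), sm$sample), collapse = ", "))
  sm <- sm[match(colnames(m), sm$sample), , drop = FALSE]
  count_table(m, sm[, c("cell_line", "genotype", "time_h", "replicate")])
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample`, `cell_line`, `genotype`, `time_h`,
#'   `replicate`.
#' @return data.frame, one row per sample. The number of samples is always
#'   taken from this sheet, never assumed.
#' @export
read_sample_sheet <- function(path) {
  sm <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "cell_line", "genotype", "time_h", "replicate")
  miss <- setdiff(need, names(sm))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  sm
}
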