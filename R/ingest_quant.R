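#' Trim a 3' sequencing adapter from small-RNA reads
#'
#' Removes everything from the left-most occurrence of the adapter onwards.
#' A full adapter match anywhere in the read counts; otherwise a terminal
#' overlap (suffix of the read equal to a prefix of the adapter) of at least
#' `min_overlap` bases counts as adapter evidence. Reads with no evidence
#' are returned unchanged; reads whose insert (the prefix before the
#' adapter) is empty are rejected.
#'
#' @param reads character vector of read sequences over `{A,C,G,T,N}`.
#' @param adapter adapter sequence (non-empty, same alphabet).
#' @param min_overlap minimum terminal overlap, default 6.
#' @return data.frame with columns `read` (input), `trimmed` (insert
#'   sequence, `NA` for rejected reads) and `status` (`"trimmed"`,
#'   `"untrimmed"` or `"rejected"`).
#' @examples
#' trim_adapter(c("ACGTACGTTCGTATGCC", "ACGTACGT"), adapter = "TCGTATGCC")
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L) {
  .check_alphabet(reads, "read")
  .check_alphabet(adapter, "adapter")
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L) stop("min_overlap must be >= 1")

  trimmed <- reads
  status <- rep("untrimmed", length(reads))
  full <- regexpr(adapter, reads, fixed = TRUE)
  hit <- full > 0L
  trimmed[hit] <- substr(reads[hit], 1L, full[hit] - 1L)
  status[hit] <- "trimmed"

  # terminal overlap for reads without a full internal match: longest
  # adapter prefix (>= min_overlap) equal to a read suffix, i.e. the
  # left-most adapter start position
  no <- which(!hit)
  if (length(no)) {
    max_ov <- min(nchar(adapter) - 1L, max(nchar(reads[no]), 0L))
    if (max_ov >= min_overlap) {
      for (ov in seq(max_ov, min_overlap)) {      # longest first = left-most
        pre <- substr(adapter, 1L, ov)
        cand <- no[status[no] == "untrimmed"]
        if (!length(cand)) break
        m <- substr(reads[cand], nchar(reads[cand]) - ov + 1L,
                    nchar(reads[cand])) == pre & nchar(reads[cand]) >= ov
        sel <- cand[m]
        trimmed[sel] <- substr(reads[sel], 1L, nchar(reads[sel]) - ov)
        status[sel] <- "trimmed"
      }
    }
  }
  rej <- status == "trimmed" & !nzchar(trimmed)
  trimmed[rej] <- NA_character_
  status[rej] <- "rejected"
  data.frame(read = reads, trimmed = trimmed, status = status,
             stringsAsFactors = FALSE)
}

#' Filter reads by length and complexity
#'
#' Retains reads with `min_len <= length <= max_len` whose mono-nucleotide
#' fraction is at most `max_mono_frac` and whose longest homopolymer run is
#' shorter than `max_homopolymer` (the polyN rule). Rejected reads are
#' counted by the first failing rule, in the order length then complexity.
#'
#' @param reads character vector of read sequences.
#' @param min_len,max_len retained length range, defaults 18 and 30 nt.
#' @param max_mono_frac maximum fraction of the read made of a single base,
#'   default 0.8.
#' @param max_homopolymer shortest homopolymer run that rejects a read,
#'   default 15 nt.
#' @return list with `retained` (character vector) and `rejected`
#'   (named integer vector with entries `length` and `complexity`).
#' @export
filter_reads <- function(reads, min_len = 18L, max_len = 30L,
                         max_mono_frac = 0.8, max_homopolymer = 15L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (!length(reads))
    return(list(retained = character(0),
                rejected = c(length = 0L, complexity = 0L)))
  .check_alphabet(reads, "read")
  len <- nchar(reads)
  bad_len <- len < min_len | len > max_len
  mono <- vapply(strsplit(reads, ""), function(b) {
    max(tabulate(factor(b, levels = .VALID_BASES))) / length(b)
  }, numeric(1))
  runs <- vapply(reads, function(s) {
    r <- rle(strsplit(s, "")[[1]])
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
  bad_cplx <- mono > max_mono_frac | runs >= max_homopolymer
  keep <- !bad_len & !bad_cplx
  list(retained = reads[keep],
       rejected = c(length = sum(bad_len),
                    complexity = sum(bad_cplx & !bad_len)))
}

#' Quantify reads against a mature-miRNA reference by exact identity
#'
#' A read increments a reference entry if and only if its sequence is
#' identical to the mature sequence (default), or — with
#' `end_tolerance > 0` — is a sub- or super-string of it with at most
#' `end_tolerance` extra/missing bases at the ends. A read whose sequence
#' matches several reference entries with identical mature sequences
#' increments all of them and is logged as ambiguous. `N` bases never
#' match. The column library size is the number of matched reads.
#'
#' @param reads character vector of (trimmed, filtered) read sequences.
#' @param reference data.frame with columns `id`, `sequence` and optionally
#'   `stemloop_id`, `arm` (see [read_mirna_reference()]); ids must be unique.
#' @param sample_id label for the quantified column.
#' @param end_tolerance allowed end slack in bases; 0 = strict full-sequence
#'   identity (default).
#' @return list with `counts` (named integer vector over reference ids),
#'   `library_size` (matched reads), `unmatched` (count) and `ambiguous`
#'   (ids of multi-matching sequences).
#' @export
quantify_exact <- function(reads, reference, sample_id = "sample",
                           end_tolerance = 0L) {
  if (!nrow(reference)) stop("reference must be non-empty")
  if (anyDuplicated(reference$id)) stop("reference ids must be unique")
  .check_alphabet(reference$sequence, "reference sequence")
  if (length(reads)) .check_alphabet(reads, "read")

  counts <- stats::setNames(integer(nrow(reference)), reference$id)
  ambiguous <- character(0)
  clean <- reads[!grepl("N", reads, fixed = TRUE)]   # N never matches
  n_reads <- length(reads)
  matched <- 0L
  if (length(clean)) {
    if (end_tolerance == 0L) {
      tab <- table(clean)
      seq_to_ids <- split(reference$id, reference$sequence)
      hit <- names(tab)[names(tab) %in% names(seq_to_ids)]
      for (s in hit) {
        ids <- seq_to_ids[[s]]
        counts[ids] <- counts[ids] + as.integer(tab[[s]])
        matched <- matched + as.integer(tab[[s]])
        if (length(ids) > 1L) ambiguous <- union(ambiguous, ids)
      }
    } else {
      for (r in clean) {
        nr <- nchar(r)
        d <- nchar(reference$sequence) - nr
        ok <- (d == 0L & reference$sequence == r) |
          (d > 0L & d <= end_tolerance &
             vapply(reference$sequence, function(s) grepl(r, s, fixed = TRUE),
                    logical(1))) |
          (d < 0L & -d <= end_tolerance &
             vapply(reference$sequence, function(s) grepl(s, r, fixed = TRUE),
                    logical(1)))
        if (any(ok)) {
          counts[ok] <- counts[ok] + 1L
          matched <- matched + 1L
          if (sum(ok) > 1L) ambiguous <- union(ambiguous, reference$id[ok])
        }
      }
    }
  }
  list(counts = counts, library_size = matched,
       unmatched = n_reads - matched, ambiguous = ambiguous,
       sample_id = sample_id)
}

#' Classify reads into small-RNA annotation classes
#'
#' Assigns each read to the first class (in the given priority order) whose
#' sequence set contains it exactly, mirroring the matching rule of
#' [quantify_exact()]; unassigned reads fall into `unannotated`. Class
#' names are restricted to the small non-coding RNA taxonomy used in
#' small-RNA profiling.
#'
#' @param reads character vector of read sequences.
#' @param classes named list of character vectors of class sequences; names
#'   drawn from `miRNA, rRNA, scRNA, snRNA, snoRNA, tRNA, misc_RNA,
#'   predicted`.
#' @return named numeric vector of read fractions over
#'   `c(names(classes), "unannotated")`; sums to 1.
#' @export
classify_rna_classes <- function(reads, classes) {
  valid <- c("miRNA", "rRNA", "scRNA", "snRNA", "snoRNA", "tRNA",
             "misc_RNA", "predicted")
  if (!all(names(classes) %in% valid))
    stop("invalid class name(s): ",
         paste(setdiff(names(classes), valid), collapse = ", "))
  n <- length(reads)
  res <- stats::setNames(numeric(length(classes) + 1L),
                         c(names(classes), "unannotated"))
  if (n == 0L) { res["unannotated"] <- 1; return(res) }
  assigned <- rep(FALSE, n)
  clean <- !grepl("N", reads, fixed = TRUE)
  for (cl in names(classes)) {
    hit <- !assigned & clean & reads %in% classes[[cl]]
    res[cl] <- sum(hit) / n
    assigned <- assigned | hit
  }
  res["unannotated"] <- sum(!assigned) / n
  res
}

#' Read small-RNA reads or a mature-miRNA reference from FASTA/FASTQ
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()]. Uracil is converted
#' to thymine so RNA-alphabet references quantify directly against DNA-space
#' reads; Phred qualities are ignored.
#'
#' @param path FASTA or FASTQ file.
#' @param format `"fasta"` or `"fastq"`; guessed from the extension by
#'   default.
#' @return `read_small_rna()`: character vector of sequences named by read
#'   id. `read_mirna_reference()`: data.frame with columns `id`, `sequence`,
#'   `stemloop_id`, `arm`; the stem-loop id is the mature id with a trailing
#'   `-5p`/`-3p` stripped, and `arm` is that suffix (or `"unknown"`).
#' @export
read_small_rna <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = format)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_small_rna
#' @export
read_mirna_reference <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(chartr("U", "T", as.character(x)))
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) stop("reference ids must be unique")
  arm <- ifelse(grepl("-5p$", ids), "5p",
                ifelse(grepl("-3p$", ids), "3p", "unknown"))
  data.frame(id = ids, sequence = unname(seqs),
             stemloop_id = sub("-[35]p$", "", ids), arm = arm,
             stringsAsFactors = FALSE)
}
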