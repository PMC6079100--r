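#' Screen count matrix
#'
#' Container for a guide x sample matrix of non-negative integer read
#' counts, together with the per-sample raw totals used as normalization
#' denominators.
#'
#' @param counts Integer matrix, guides in rows (rownames = guide ids),
#'   samples in columns (colnames = sample names).
#'
#' @return A list of class `screen_counts` with elements `counts`,
#'   `samples`, `totals`.
#' @export
screen_counts <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("`counts` must be a matrix with guide rownames and sample colnames")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers with no missing cells")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 samples = colnames(counts),
                 totals = colSums(counts)),
            class = "screen_counts")
}

as_screen_counts <- function(x) {
  if (inherits(x, "screen_counts")) x else screen_counts(x)
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("screen_counts: %d guides x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", x$samples, x$totals), collapse = ", ")))
  invisible(x)
}

split_tsv_lines <- function(lines, n_fields, what, path = "<stream>") {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  if (length(bad))
    stopf("%s: malformed row at line %d of %s (expected %d tab-separated fields, got %d)",
          what, bad[1], path, n_fields, lengths(parts)[bad[1]])
  parts
}

#' Read a guide library from a TSV file
#'
#' Expects a header with at least `guide_id`, `gene_id`, `sequence`
#' (optionally `is_control`). Duplicate guide ids and inconsistent sequence
#' lengths are rejected.
#'
#' @param path File path (plain or gzipped TSV).
#' @return A `guide_library` data frame.
#' @export
read_guide_library <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stopf("guide library %s is empty", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  needed <- c("guide_id", "gene_id", "sequence")
  if (!all(needed %in% header))
    stopf("guide library header must contain %s", paste(needed, collapse = ", "))
  parts <- split_tsv_lines(lines[-1], length(header), "guide library", path)
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- header
  if (!"is_control" %in% names(df)) df$is_control <- "FALSE"
  df$is_control <- as.logical(df$is_control)
  if (any(is.na(df$is_control)))
    stopf("is_control column must be TRUE/FALSE")
  validate_guide_library(df[c("guide_id", "gene_id", "sequence", "is_control")])
}

#' Write a guide library to TSV
#' @param library A `guide_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guide_library <- function(library, path) {
  library <- validate_guide_library(library)
  write.table(as.data.frame(library), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write FASTQ lines to a file
#'
#' @param lines Character vector of FASTQ lines (4 per record), as produced
#'   by [counts_to_fastq()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(lines, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

fastq_records <- function(fastq) {
  lines <- if (length(fastq) == 1 && file.exists(fastq)) readLines(fastq) else fastq
  if (length(lines) %% 4 != 0)
    stopf("truncated FASTQ: %d lines is not a multiple of 4", length(lines))
  if (!length(lines)) return(character(0))
  heads <- lines[seq(1, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  if (any(substr(heads, 1, 1) != "@") || any(substr(plus, 1, 1) != "+"))
    stopf("malformed FASTQ record structure ('@'/'+' lines out of place)")
  lines[seq(2, length(lines), by = 4)]
}

#' Count guide-matching reads in a FASTQ stream
#'
#' Each read is trimmed to its first `trim_length` bases and exact-matched
#' (forward orientation, zero mismatches) against the library sequences.
#' Reads that do not match any guide, including reads shorter than
#' `trim_length`, are tallied as unassigned.
#'
#' @param fastq A file path (plain or gzipped) or a character vector of
#'   FASTQ lines.
#' @param library A `guide_library`.
#' @param trim_length Prefix length to match; must equal the library's
#'   guide length (default 20).
#'
#' @return List with `counts` (named integer vector over all library
#'   guides) and `n_unassigned`.
#' @export
count_reads <- function(fastq, library, trim_length = 20) {
  library <- validate_guide_library(library)
  trim_length <- assert_count(trim_length, "trim_length")
  glen <- if (nrow(library)) nchar(library$sequence[1]) else trim_length
  if (trim_length != glen)
    stopf("trim_length (%d) must equal the library guide length (%d)",
          trim_length, glen)
  seqs <- fastq_records(fastq)
  counts <- setNames(integer(nrow(library)), library$guide_id)
  if (!length(seqs)) return(list(counts = counts, n_unassigned = 0L))
  long_enough <- nchar(seqs) >= trim_length
  idx <- match(substr(seqs[long_enough], 1, trim_length), library$sequence)
  hit <- tabulate(idx[!is.na(idx)], nrow(library))
  counts[] <- hit
  n_unassigned <- length(seqs) - sum(hit)
  list(counts = counts, n_unassigned = as.integer(n_unassigned))
}

#' Read / write screen count tables
#'
#' TSV with a `guide_id` column followed by one integer column per sample.
#' `write_count_table()` followed by `read_count_table()` is the identity.
#'
#' @param path File path.
#' @return `read_count_table()`: a [screen_counts()] object.
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stopf("count table %s is empty", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "guide_id" || length(header) < 2)
    stopf("count table header must be guide_id followed by sample names")
  parts <- split_tsv_lines(lines[-1], length(header), "count table", path)
  m <- do.call(rbind, parts)
  vals <- suppressWarnings(matrix(as.numeric(m[, -1, drop = FALSE]),
                                  nrow = nrow(m)))
  if (any(is.na(vals)))
    stopf("count table contains missing or non-numeric cells")
  dimnames(vals) <- list(m[, 1], header[-1])
  screen_counts(vals)
}

#' @rdname read_count_table
#' @param counts A [screen_counts()] object (or guide x sample matrix).
#' @export
write_count_table <- function(counts, path) {
  counts <- as_screen_counts(counts)
  df <- data.frame(guide_id = rownames(counts$counts), counts$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
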