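#' Reserved gene id for positive-control guides
#'
#' Control guides (e.g. guides targeting an epitope tag on the sorted
#' reporter construct) are grouped under a single reserved gene id so that
#' gene-level statistics treat them as one redundant set.
#'
#' @return A length-1 character string.
#' @export
control_gene_id <- function() "CTRL"

random_kmers <- function(n, k) {
  if (n == 0) return(character(0))
  draw <- function(m) {
    apply(matrix(sample(c("A", "C", "G", "T"), m * k, replace = TRUE), nrow = m),
          1, paste0, collapse = "")
  }
  seqs <- draw(n)
  # collisions are vanishingly rare for k = 20 but must not occur at all
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- draw(length(dup))
  }
  seqs
}

new_guide_library <- function(df) {
  structure(df, class = c("guide_library", "data.frame"))
}

validate_guide_library <- function(df) {
  needed <- c("guide_id", "gene_id", "sequence", "is_control")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stopf("guide library is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$guide_id))
    stopf("duplicate guide_id(s): %s",
          paste(unique(df$guide_id[duplicated(df$guide_id)]), collapse = ", "))
  len <- unique(nchar(df$sequence))
  if (length(len) > 1)
    stopf("guide sequences have inconsistent lengths: %s",
          paste(len, collapse = ", "))
  if (nrow(df) && any(grepl("[^ACGT]", df$sequence)))
    stopf("guide sequences must use the alphabet {A,C,G,T}")
  new_guide_library(df)
}

#' Generate a synthetic sgRNA library
#'
#' Builds a guide library with `guides_per_gene` independent 20-nt guides per
#' gene plus `n_control_guides` positive-control guides mapped to the
#' reserved gene id [control_gene_id()]. Sequences are unique random 20-mers;
#' the same arguments always produce the same library.
#'
#' @param n_genes Number of target genes (>= 1).
#' @param guides_per_gene Guides designed per gene (default 6, the redundancy
#'   of a genome-wide knockout library).
#' @param n_control_guides Guides targeting the reporter construct itself
#'   (default 3); they share the reserved control gene id.
#' @param seed Integer seed; the call is a pure function of its arguments.
#' @param guide_length Guide length in nucleotides (default 20).
#'
#' @return A `guide_library` data frame with columns `guide_id`, `gene_id`,
#'   `sequence`, `is_control`.
#' @export
make_guide_library <- function(n_genes, guides_per_gene = 6,
                               n_control_guides = 3, seed = 1,
                               guide_length = 20) {
  n_genes <- assert_count(n_genes, "n_genes")
  guides_per_gene <- assert_count(guides_per_gene, "guides_per_gene")
  n_control_guides <- assert_count(n_control_guides, "n_control_guides", min = 0)
  guide_length <- assert_count(guide_length, "guide_length")
  seeded(seed, {
    gene_ids <- sprintf("gene%05d", seq_len(n_genes))
    gene_col <- rep(gene_ids, each = guides_per_gene)
    guide_col <- paste0(gene_col, "_g", rep(seq_len(guides_per_gene), n_genes))
    if (n_control_guides > 0) {
      gene_col <- c(gene_col, rep(control_gene_id(), n_control_guides))
      guide_col <- c(guide_col,
                     paste0(control_gene_id(), "_g", seq_len(n_control_guides)))
    }
    df <- data.frame(
      guide_id = guide_col,
      gene_id = gene_col,
      sequence = random_kmers(length(guide_col), guide_length),
      is_control = gene_col == control_gene_id(),
      stringsAsFactors = FALSE
    )
    validate_guide_library(df)
  })
}
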