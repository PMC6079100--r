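#' Pseudocount normalization of screen counts
#'
#' Per sample s and guide g, the normalized value is
#' `(c_gs + 1) / T_s`, where `T_s` is the sum of raw counts in the sample.
#' The pseudocount keeps downstream enrichment ratios finite for guides
#' that drop out of a sorted population.
#'
#' @param counts A [screen_counts()] object (or guide x sample matrix).
#' @return Numeric matrix of normalized values (same dimnames as counts).
#' @export
normalize_counts <- function(counts) {
  counts <- as_screen_counts(counts)
  if (any(counts$totals == 0))
    stopf("sample(s) with zero total reads: %s",
          paste(counts$samples[counts$totals == 0], collapse = ", "))
  sweep(counts$counts + 1, 2, counts$totals, "/")
}

#' Per-guide enrichment between a sorted and a reference sample
#'
#' `e_g = n_g,sorted / n_g,reference` on pseudocount-normalized values;
#' both populations are compared against the unsorted pool by default.
#'
#' @param normalized Matrix from [normalize_counts()].
#' @param sorted_sample Name of the sorted sample column (e.g. `"high"`).
#' @param reference_sample Name of the reference column (default
#'   `"unsorted"`).
#' @return Named numeric vector of per-guide enrichment ratios (> 0).
#' @export
guide_enrichment <- function(normalized, sorted_sample,
                             reference_sample = "unsorted") {
  for (s in c(sorted_sample, reference_sample))
    if (!s %in% colnames(normalized))
      stopf("sample '%s' not present (have: %s)", s,
            paste(colnames(normalized), collapse = ", "))
  normalized[, sorted_sample] / normalized[, reference_sample]
}

rsa_gene_pvalues <- function(ranks, n_total) {
  r <- sort(ranks)
  n <- length(r)
  # P(X >= i) for X ~ Hypergeom(N = n_total, marked = n, drawn = r_i)
  p <- phyper(seq_len(n) - 1L, n, n_total - n, r, lower.tail = FALSE)
  list(p = p, p_min = min(p), best_rank = r[which.min(p)])
}

#' Gene-level RSA statistics from guide enrichments
#'
#' The redundant sgRNA activity (RSA) statistic: all N guides are ranked by
#' enrichment, most-enriched first (ties receive the worst, i.e. largest,
#' rank). For a gene with guides at ranks r_1 < ... < r_n,
#' `p_i = P(X >= i)` under `X ~ Hypergeometric(N, n, r_i)` — the chance
#' that a random top-r_i set contains at least i of the gene's n guides —
#' and the gene score is `p_min = min_i p_i`, reported with
#' `logP = log10(p_min)`.
#'
#' `direction` labels which sorted population the enrichment vector
#' compares against the unsorted pool; in either case a hit is a gene whose
#' guides are jointly over-represented in that population (positive-control
#' guides that silence the reporter, for example, are hits in the "low"
#' direction because they accumulate in the low-fluorescence gate). Set
#' `decreasing = FALSE` to instead score joint depletion.
#'
#' @param enrichment Named numeric vector of per-guide enrichments
#'   (names = guide ids).
#' @param guide_to_gene Named character vector mapping guide id to gene id,
#'   or a `guide_library`.
#' @param direction Label for the sorted population: `"high"` or `"low"`.
#' @param decreasing Rank largest enrichment first (default `TRUE`).
#'
#' @return Data frame with one row per gene: `gene_id`, `direction`,
#'   `n_guides`, `best_rank`, `p_min`, `logP`.
#' @export
rsa_scores <- function(enrichment, guide_to_gene,
                       direction = c("high", "low"), decreasing = TRUE) {
  direction <- match.arg(direction)
  if (!length(enrichment)) stopf("empty enrichment vector")
  if (inherits(guide_to_gene, "guide_library") || is.data.frame(guide_to_gene))
    guide_to_gene <- setNames(guide_to_gene$gene_id, guide_to_gene$guide_id)
  genes <- guide_to_gene[names(enrichment)]
  if (any(is.na(genes)))
    stopf("guide(s) without a gene mapping: %s",
          paste(head(names(enrichment)[is.na(genes)], 3), collapse = ", "))
  n_total <- length(enrichment)
  key <- if (decreasing) -enrichment else enrichment
  ranks <- rank(key, ties.method = "max")
  by_gene <- split(ranks, genes)
  res <- lapply(by_gene, rsa_gene_pvalues, n_total = n_total)
  data.frame(
    gene_id = names(by_gene),
    direction = direction,
    n_guides = lengths(by_gene),
    best_rank = vapply(res, `[[`, numeric(1), "best_rank"),
    p_min = vapply(res, `[[`, numeric(1), "p_min"),
    logP = log10(vapply(res, `[[`, numeric(1), "p_min")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Call screen hits from RSA results
#'
#' Genes with `p_min` strictly below `alpha` (default 0.01), sorted by
#' ascending `p_min`.
#'
#' @param rsa Data frame from [rsa_scores()].
#' @param alpha Significance cutoff in (0, 1].
#' @return The subset of `rsa` rows that are hits, ordered by `p_min`.
#' @export
call_hits <- function(rsa, alpha = 0.01) {
  assert_fraction(alpha, "alpha", lo = 0, hi = 1, lo_open = TRUE)
  hits <- rsa[rsa$p_min < alpha, , drop = FALSE]
  hits[order(hits$p_min), , drop = FALSE]
}

#' Remove unexpressed genes from a hit list
#'
#' Drops hits whose expression (e.g. RPKM in the screened cell line) is
#' below `threshold`; genes absent from the expression map are treated as
#' unexpressed and dropped with a message.
#'
#' @param hits Character vector of gene ids.
#' @param expression Named numeric vector, gene id -> expression level.
#' @param threshold Minimum expression to keep a hit (default 1).
#' @return Filtered character vector of gene ids.
#' @export
expression_filter <- function(hits, expression, threshold = 1) {
  if (!length(hits)) return(character(0))
  expr <- expression[hits]
  missing <- is.na(expr)
  if (any(missing))
    message(sprintf("expression_filter: %d gene(s) absent from the expression map, removed: %s",
                    sum(missing), paste(head(hits[missing], 5), collapse = ", ")))
  hits[!missing & expr >= threshold]
}

#' Derive a gene signature from differential-expression statistics
#'
#' Genes with `log2fc` strictly above `lfc_threshold` and `fdr` strictly
#' below `fdr_threshold` (defaults log2FC > 1, FDR < 0.05).
#'
#' @param stats Data frame with columns `gene_id`, `log2fc`, `fdr`.
#' @param lfc_threshold log2 fold-change cutoff (exclusive).
#' @param fdr_threshold FDR cutoff (exclusive).
#' @return Character vector of signature gene ids.
#' @export
signature_from_de <- function(stats, lfc_threshold = 1, fdr_threshold = 0.05) {
  needed <- c("gene_id", "log2fc", "fdr")
  miss <- setdiff(needed, names(stats))
  if (length(miss))
    stopf("`stats` is missing column(s): %s", paste(miss, collapse = ", "))
  stats$gene_id[stats$log2fc > lfc_threshold & stats$fdr < fdr_threshold]
}

#' @importFrom utils head
NULL
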