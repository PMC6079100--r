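signed_ks <- function(ranks_in_set, n_genes) {
  r <- sort(ranks_in_set)
  m <- length(r)
  i <- seq_len(m)
  d_pos <- max(i / m - (r - 1) / n_genes)
  d_neg <- max(r / n_genes - (i - 1) / m)
  if (d_pos >= d_neg) d_pos else -d_neg
}

rank_genes_in_sample <- function(z_col) {
  # descending by z; ties broken by gene (row) order
  ord <- order(-z_col, seq_along(z_col))
  ranks <- integer(length(z_col))
  ranks[ord] <- seq_along(z_col)
  ranks
}

#' Per-sample signature activity score (signed KS statistic)
#'
#' Single-sample gene-set scoring in the GSEA family: each gene is z-scored
#' across the cohort, genes are ranked within the sample by descending
#' z-score (ties broken by gene order), and the signed Kolmogorov-Smirnov
#' statistic between the set's rank distribution and uniformity is
#' returned. Scores lie in `[-1, 1]`; positive means the set is enriched
#' among the sample's most highly expressed genes.
#'
#' With `zscore = TRUE` (default) the score is invariant under per-gene
#' affine rescaling (gene-specific units cancel); with `zscore = FALSE`
#' genes are ranked by raw expression within the sample, making the score
#' invariant under any strictly monotone transform of that sample's values.
#'
#' @param expression Gene x sample numeric matrix (>= 2 samples, so the
#'   cohort z-score is defined).
#' @param gene_set Character vector of gene ids; must intersect the matrix.
#' @param samples Optional subset of sample names (default: all).
#' @param zscore Z-score each gene across the cohort before ranking
#'   (default `TRUE`).
#' @return Named numeric vector of scores, one per sample.
#' @export
signature_scores <- function(expression, gene_set,
                             samples = colnames(expression), zscore = TRUE) {
  set_idx <- which(rownames(expression) %in% gene_set)
  if (!length(set_idx))
    stopf("gene_set has empty intersection with the expression matrix")
  if (zscore) {
    mu <- rowMeans(expression)
    sd_ <- apply(expression, 1, sd)
    sd_[sd_ == 0] <- 1  # constant genes carry no ranking information
    z <- (expression - mu) / sd_
  } else {
    z <- expression
  }
  n_genes <- nrow(expression)
  vapply(samples, function(s) {
    ranks <- rank_genes_in_sample(z[, s])
    signed_ks(ranks[set_idx], n_genes)
  }, numeric(1))
}

#' @rdname signature_scores
#' @param sample A single sample name.
#' @export
sample_signature_score <- function(expression, gene_set, sample,
                                   zscore = TRUE) {
  signature_scores(expression, gene_set, samples = sample, zscore = zscore)[[1]]
}

#' Per-sample repressor and coactivator activities
#'
#' Converts signature scores into activity scores with the repressor sign
#' convention: a repressor's activity is LOW when its repressed genes are
#' highly expressed, so `trps1_activity = -score(repressed set)`; a
#' coactivator's activity is high when its induced genes are highly
#' expressed, so `yap_activity = +score(induced set)`.
#'
#' @param expression Gene x sample matrix.
#' @param trps1_repressed_set Genes upregulated upon repressor depletion.
#' @param yap_induced_set Genes induced by the coactivator.
#' @return Data frame `sample_id`, `trps1_activity`, `yap_activity`.
#' @export
activity_scores <- function(expression, trps1_repressed_set, yap_induced_set) {
  d_rep <- signature_scores(expression, trps1_repressed_set)
  d_yap <- signature_scores(expression, yap_induced_set)
  data.frame(sample_id = colnames(expression),
             trps1_activity = -unname(d_rep),
             yap_activity = unname(d_yap),
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-approximation `t = rho * sqrt((n-2) / (1-rho^2))` with `n - 2` df.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho` and `p` (two-sided).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stopf("x and y must have equal length >= 3")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stopf("Spearman correlation is undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2))
}

#' Stratify a cohort at the third quartile
#'
#' `"high"` = strictly above Q3 (linear-interpolation quantile, the
#' standard type-7 convention); `"low"` = the remaining patients.
#'
#' @param values Numeric vector, length >= 4.
#' @param type Quantile algorithm passed to [stats::quantile()] (default 7).
#' @return Factor with levels `low`, `high`.
#' @export
quartile_stratify <- function(values, type = 7) {
  if (length(values) < 4) stopf("need at least 4 values to form quartiles")
  q3 <- quantile(values, 0.75, type = type, names = FALSE)
  factor(ifelse(values > q3, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and log-rank comparison of two groups
#'
#' Product-limit survival estimates per group and the log-rank test
#' (a 1-df chi-square) comparing them.
#'
#' @param time Follow-up times (>= 0).
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Two-level grouping factor.
#' @return List of class `survival_comparison`: `km` (data frame `group`,
#'   `time`, `n_risk`, `n_event`, `surv`), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2)
    stopf("exactly two non-empty groups are required (got %d)", nlevels(group))
  if (any(time < 0) || !all(event %in% c(0, 1)))
    stopf("times must be >= 0 and event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(fit$strata), fit$strata)
  km <- data.frame(group = sub("^group=", "", strata), time = fit$time,
                   n_risk = fit$n.risk, n_event = fit$n.event,
                   surv = fit$surv, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd$chisq)
  structure(list(km = km, chisq = chisq, df = 1,
                 p = pchisq(chisq, df = 1, lower.tail = FALSE)),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("log-rank chi-square = %.4g (1 df), p = %.4g\n", x$chisq, x$p))
  invisible(x)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact enumeration when the smaller sample has at most `exact_max`
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity corrections.
#'
#' @param a,b Numeric samples (non-empty).
#' @param two_sided Two-sided test (default); otherwise the alternative
#'   that `a` is stochastically greater than `b`.
#' @param exact_max Largest min-sample size for the exact path (default 8).
#' @return The p-value.
#' @export
wilcoxon_rank_sum <- function(a, b, two_sided = TRUE, exact_max = 8) {
  if (!length(a) || !length(b)) stopf("both samples must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) return(1)  # fully tied: no evidence
  ties <- anyDuplicated(pooled) > 0
  exact <- min(length(a), length(b)) <= exact_max && !ties
  alternative <- if (two_sided) "two.sided" else "greater"
  stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                     correct = TRUE)$p.value
}

#' @importFrom stats sd setNames
NULL
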