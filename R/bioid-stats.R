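group_obs_counts <- function(x, groups) {
  obs <- !is.na(x)
  vapply(levels(groups), function(g)
    rowSums(obs[, groups == g, drop = FALSE]), numeric(nrow(x)))
}

check_two_groups <- function(x, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stopf("exactly two sample groups are required (got %d)", nlevels(groups))
  if (length(groups) != ncol(x))
    stopf("`groups` length (%d) must match the number of samples (%d)",
          length(groups), ncol(x))
  if (any(table(groups) < 2)) stopf("each group needs >= 2 samples")
  groups
}

#' Filter protein groups with insufficient observations
#'
#' A protein is filtered out when it has fewer than two observed values in
#' group 1 AND fewer than two in group 2 — too little information in either
#' group for a robust comparison. A protein with >= 2 values in at least
#' one group is kept.
#'
#' @param x Log2 intensity matrix (proteins x samples), `NA` = missing.
#' @param groups Factor of length `ncol(x)` with two levels.
#' @return Named logical vector, `TRUE` = kept.
#' @export
filter_protein_groups <- function(x, groups) {
  groups <- check_two_groups(x, groups)
  cnt <- group_obs_counts(x, groups)
  kept <- cnt[, 1] >= 2 | cnt[, 2] >= 2
  setNames(kept, rownames(x))
}

#' Label missing cells as MNAR or MAR
#'
#' A missing cell is labelled MNAR (missing not at random, i.e. consistent
#' with intensity-dependent dropout of a protein absent from one condition)
#' when its group is missing 2 or 3 of 3 replicates while the other group
#' is fully observed. Every other missing cell of a kept protein — e.g. one
#' missing replicate per group, or partial missingness in both groups — is
#' labelled MAR. The matrix must already have passed
#' [filter_protein_groups()]; proteins failing the filter are rejected.
#'
#' @inheritParams filter_protein_groups
#' @return Character matrix, same shape as `x`, with `"MNAR"`/`"MAR"` at
#'   missing cells and `NA` elsewhere.
#' @export
classify_missingness <- function(x, groups) {
  groups <- check_two_groups(x, groups)
  kept <- filter_protein_groups(x, groups)
  if (!all(kept))
    stopf("matrix contains %d protein(s) failing the two-value filter; run filter_protein_groups() first",
          sum(!kept))
  sizes <- table(groups)
  cnt <- group_obs_counts(x, groups)
  miss <- sweep(-cnt, 2, as.numeric(sizes), "+")  # missing counts per group
  labels <- matrix(NA_character_, nrow(x), ncol(x), dimnames = dimnames(x))
  for (gi in 1:2) {
    g <- levels(groups)[gi]
    other <- 3 - gi
    mnar_protein <- miss[, gi] >= 2 & miss[, other] == 0
    in_group <- groups == g
    cells <- is.na(x[, in_group, drop = FALSE])
    lab <- ifelse(mnar_protein, "MNAR", "MAR")
    labels[, in_group][cells] <-
      matrix(lab, nrow(x), sum(in_group))[cells]
  }
  labels
}

#' Impute missing LFQ intensities by mechanism
#'
#' MNAR cells are replaced by the minimum observed value of their sample
#' column (MinDet: a left-censored value is at the detection floor). MAR
#' cells are imputed by k-nearest-neighbour averaging: distances between
#' proteins are Euclidean over mutually observed samples, the `k` nearest
#' proteins observed at the target sample are selected (ties broken by row
#' order), and their mean intensity at that sample is used.
#'
#' @param x Log2 intensity matrix with `NA` at missing cells.
#' @param labels Label matrix from [classify_missingness()].
#' @param k Number of neighbours for MAR imputation (default 10).
#' @return Completed numeric matrix (no `NA`).
#' @export
impute_lfq <- function(x, labels, k = 10) {
  k <- assert_count(k, "k")
  if (!identical(dim(x), dim(labels)))
    stopf("`labels` must have the same shape as `x`")
  nobs_col <- colSums(!is.na(x))
  if (any(nobs_col == 0))
    stopf("sample column(s) with zero observed values: %s",
          paste(colnames(x)[nobs_col == 0], collapse = ", "))
  mislab <- !is.na(labels)
  if (any(is.na(x) != mislab))
    stopf("labels must cover exactly the missing cells")
  if (!any(mislab)) return(x)
  out <- x
  col_min <- apply(x, 2, min, na.rm = TRUE)
  mnar <- which(labels == "MNAR", arr.ind = TRUE)
  if (nrow(mnar)) out[mnar] <- col_min[mnar[, 2]]
  mar <- which(labels == "MAR", arr.ind = TRUE)
  for (idx in seq_len(nrow(mar))) {
    i <- mar[idx, 1]; j <- mar[idx, 2]
    candidates <- which(!is.na(x[, j]))
    candidates <- candidates[candidates != i]
    if (!length(candidates))
      stopf("no observed neighbour available in column %s", colnames(x)[j])
    d <- vapply(candidates, function(o) {
      shared <- !is.na(x[i, ]) & !is.na(x[o, ])
      if (!any(shared)) return(Inf)
      sqrt(sum((x[i, shared] - x[o, shared])^2))
    }, numeric(1))
    nn <- candidates[order(d, candidates)][seq_len(min(k, length(candidates)))]
    out[i, j] <- mean(x[nn, j])
  }
  out
}

#' Quantile normalization
#'
#' Forces every sample column to the same empirical distribution — the
#' vector of row-wise means of the sorted columns — while preserving
#' within-column ranks (ties resolved by row order, so the defining
#' property that all sorted columns are identical holds exactly).
#'
#' @param x Complete numeric matrix (no `NA`).
#' @return Normalized matrix, same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  if (any(is.na(x))) stopf("quantile_normalize requires a complete matrix")
  target <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) out[order(x[, j]), j] <- target
  out
}

trigamma_inverse <- function(y) {
  # Newton iteration on x -> trigamma(x), as used for empirical-Bayes
  # degrees-of-freedom estimation.
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (it in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Estimate empirical-Bayes variance prior by the method of moments
#'
#' Fits a scaled inverse chi-square prior `s0^2, d0` to the per-protein
#' sample variances `s_g^2` (each with `d_g` degrees of freedom) through the
#' moments of `log s_g^2`, following the classical moderated-t derivation:
#' `e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2)` has mean
#' `log s0^2 + digamma(d0/2) - log(d0/2)` and variance
#' `trigamma(d_g/2) + trigamma(d0/2)`.
#'
#' @param s2 Numeric vector of sample variances (zeros are excluded from
#'   the fit).
#' @param df Residual degrees of freedom (scalar or vector).
#' @return List with `d0` (possibly `Inf`) and `s0_2`.
#' @export
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) stopf("need at least two positive variances to fit a prior")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  ebar <- mean(e)
  ev <- var(e) - mean(trigamma(df[ok] / 2))
  if (ev <= 0) {
    # no excess spread beyond chi-square sampling noise: variances are
    # exchangeable and the prior scale is their plain mean
    d0 <- Inf
    s0_2 <- mean(s2[ok])
  } else {
    d0 <- 2 * trigamma_inverse(ev)
    s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated two-sample t-test with empirical-Bayes variance shrinkage
#'
#' For each protein the two-sample difference `delta = mean(group2) -
#' mean(group1)` is tested with a pooled residual variance `s_g^2` (with
#' `d_g = n1 + n2 - 2` df) shrunk towards an empirical-Bayes prior:
#' `s~^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, moderated
#' `t = delta / (s~ sqrt(1/n1 + 1/n2))` with `d0 + d_g` degrees of freedom.
#' The prior `(d0, s0^2)` is estimated by [fit_variance_prior()] unless
#' supplied; `d0 = 0` reduces to the ordinary pooled t-test and
#' `d0 = Inf` replaces every variance by `s0^2`.
#'
#' @param x Complete (imputed, normalized) log2 intensity matrix.
#' @param groups Two-level factor over columns; `delta` is second level
#'   minus first level.
#' @param d0,s0_2 Optional prior overrides (both must be given together).
#' @return Data frame with one row per protein: `protein_id`, `logFC`,
#'   `s2`, `s2_post`, `t`, `df_total`, `p`; the fitted prior is attached as
#'   attributes `d0` and `s0_2`.
#' @export
moderated_t_test <- function(x, groups, d0 = NULL, s0_2 = NULL) {
  groups <- check_two_groups(x, groups)
  if (any(is.na(x))) stopf("moderated_t_test requires a complete matrix")
  g1 <- groups == levels(groups)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  delta <- m2 - m1
  ss1 <- rowSums((x[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, g2, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / dg
  if (is.null(d0) != is.null(s0_2))
    stopf("supply both `d0` and `s0_2`, or neither")
  if (is.null(d0)) {
    if (all(s2 <= 0)) {
      warnf("all within-group variances are zero; falling back to the ordinary t-test")
      d0 <- 0; s0_2 <- 0
    } else {
      prior <- fit_variance_prior(s2, dg)
      d0 <- prior$d0; s0_2 <- prior$s0_2
    }
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2))
             else if (d0 == 0) s2
             else (d0 * s0_2 + dg * s2) / (d0 + dg)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- delta / se
  df_total <- d0 + dg
  p <- 2 * pt(-abs(tstat), df = df_total)
  res <- data.frame(protein_id = rownames(x), logFC = delta, s2 = s2,
                    s2_post = s2_post, t = tstat, df_total = df_total,
                    p = p, row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s0_2") <- s0_2
  res
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up adjusted p-values by default; any method of
#' [stats::p.adjust()] is accepted.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method Adjustment method (default `"BH"`).
#' @return Adjusted p-values.
#' @export
adjust_fdr <- function(p, method = "BH") {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = method)
}

#' Full BioID differential-abundance pipeline
#'
#' Applies, in order: the two-value filter, MNAR/MAR classification,
#' mechanism-specific imputation (MinDet / kNN), quantile normalization,
#' the moderated t-test and BH adjustment.
#'
#' @param x Log2 LFQ intensity matrix with `NA` at missing cells.
#' @param groups Two-level factor over columns (reference level first).
#' @param k Neighbours for kNN imputation (default 10).
#' @param fdr_method Adjustment method for [adjust_fdr()].
#' @return Data frame per kept protein (`protein_id`, `logFC`, `t`, `p`,
#'   `fdr`, `n_obs_<group>` and imputation counts), with the label matrix
#'   attached as attribute `labels` and filtered ids as `filtered`.
#' @export
bioid_differential <- function(x, groups, k = 10, fdr_method = "BH") {
  groups <- check_two_groups(x, groups)
  kept <- filter_protein_groups(x, groups)
  xk <- x[kept, , drop = FALSE]
  labels <- classify_missingness(xk, groups)
  completed <- impute_lfq(xk, labels, k = k)
  normalized <- quantile_normalize(completed)
  res <- moderated_t_test(normalized, groups)
  res$fdr <- adjust_fdr(res$p, method = fdr_method)
  cnt <- group_obs_counts(xk, groups)
  res[[paste0("n_obs_", levels(groups)[1])]] <- cnt[, 1]
  res[[paste0("n_obs_", levels(groups)[2])]] <- cnt[, 2]
  res$n_mnar <- rowSums(labels == "MNAR", na.rm = TRUE)
  res$n_mar <- rowSums(labels == "MAR", na.rm = TRUE)
  attr(res, "labels") <- labels
  attr(res, "filtered") <- rownames(x)[!kept]
  res
}
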