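# Small in-code fixtures shared across the suite.

tiny_library <- function(n_genes = 3, guides_per_gene = 2, n_controls = 1,
                         seed = 42) {
  make_guide_library(n_genes, guides_per_gene, n_controls, seed = seed)
}

# A 10-guide enrichment vector with a prescribed rank order: guide gN gets
# rank N (enrichment decreasing in N) for the most-enriched-first ranking.
ranked_enrichment <- function(n = 10) {
  setNames(rev(seq_len(n)), paste0("g", seq_len(n)))
}

# Exhaustive hypergeometric oracle: P(X >= i) where X counts marked
# positions among a uniformly random size-r subset of N positions, with n
# marked. Enumerates all choose(N, r) subsets.
brute_force_tail <- function(i, n_marked, r, N) {
  marked <- seq_len(n_marked)
  sets <- utils::combn(N, r)
  mean(colSums(matrix(sets %in% marked, nrow = r)) >= i)
}

# Oracle RSA p_min for one gene via exhaustive enumeration.
brute_force_rsa_pmin <- function(ranks, N) {
  r <- sort(ranks)
  min(vapply(seq_along(r), function(i)
    brute_force_tail(i, length(r), r[i], N), numeric(1)))
}

# Textbook log-rank statistic: sum over distinct event times of
# (O1 - E1), with E1 and hypergeometric variance from the risk sets.
oracle_logrank_chisq <- function(time, event, group) {
  group <- as.factor(group)
  g1 <- levels(group)[1]
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Straight-line reimplementation of the log-variance moment equations for
# the empirical-Bayes prior (independent of fit_variance_prior).
oracle_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- s2 > 0
  e <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  ev <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (ev <= 0) return(list(d0 = Inf, s0_2 = mean(s2[ok])))
  # invert trigamma by bisection on (1e-8, 1e8)
  lo <- 1e-8; hi <- 1e8
  for (it in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > ev) lo <- mid else hi <- mid
  }
  half_d0 <- sqrt(lo * hi)
  list(d0 = 2 * half_d0,
       s0_2 = exp(mean(e) + digamma(half_d0) - log(half_d0)))
}
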