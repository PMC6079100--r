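make_rank_matrix <- function(values_by_sample) {
  # builds a gene x sample matrix whose within-sample ordering is prescribed;
  # two samples with opposite trends keep per-gene z-scores informative
  n <- length(values_by_sample[[1]])
  m <- do.call(cbind, values_by_sample)
  rownames(m) <- paste0("g", seq_len(n))
  m
}

test_that("the signed KS score reproduces direct evaluations of its formula", {
  # N = 4 with the set at within-sample ranks {1, 2} of sample s1
  m <- make_rank_matrix(list(s1 = c(4, 3, 2, 1), s2 = c(1, 2, 3, 4)))
  d <- sample_signature_score(m, c("g1", "g2"), "s1")
  expect_equal(d, 0.75)  # max(1/2 - 0, 1 - 1/4)

  # the full gene universe as the set collapses to D = 1/N
  expect_equal(sample_signature_score(m, rownames(m), "s1"), 1 / 4)

  # bottom ranks mirror the top case with the sign flipped
  d_bottom <- sample_signature_score(m, c("g3", "g4"), "s1")
  expect_equal(d_bottom, -0.75)

  expect_error(sample_signature_score(m, c("nope"), "s1"), "empty intersection")
})

test_that("scores are invariant under per-gene affine maps, and under monotone
           single-sample maps when ranking raw values", {
  expr <- withr::with_seed(1, matrix(rnorm(300), nrow = 30,
                  dimnames = list(paste0("g", 1:30), paste0("s", 1:10))))
  set <- paste0("g", 1:6)
  base <- signature_scores(expr, set)
  gains <- withr::with_seed(2, runif(30, 0.5, 4))
  offsets <- withr::with_seed(3, rnorm(30))
  scaled <- expr * gains + offsets
  expect_equal(signature_scores(scaled, set), base)

  raw <- signature_scores(expr, set, zscore = FALSE)
  warped <- expr
  warped[, "s3"] <- exp(warped[, "s3"] / 2)  # strictly monotone
  expect_equal(signature_scores(warped, set, zscore = FALSE), raw)
})

test_that("activity scores use the repressor sign convention and recover
           the planted anti-correlation's sign", {
  co <- simulate_cohort(200, 400, 80, 80, latent_correlation = -0.7, seed = 8)
  act <- activity_scores(co$expression, co$gene_sets$trps1_repressed,
                         co$gene_sets$yap_induced)
  # samples with the repressed set on top have LOW repressor activity
  top_rep <- which.max(colMeans(co$expression[co$gene_sets$trps1_repressed, ]))
  expect_lt(act$trps1_activity[top_rep], 0)
  rho <- spearman_rho(act$trps1_activity, act$yap_activity)
  expect_lt(rho$rho, 0)
  expect_gt(cor(act$trps1_activity, co$truth$trps1_act), 0.8)
})

test_that("Spearman correlation matches hand-computed ranks", {
  expect_equal(spearman_rho(1:3, 3:1)$rho, -1)
  expect_equal(spearman_rho(1:5, 1:5)$rho, 1)
  x <- c(10, 40, 20, 50, 30)
  y <- c(1.2, 0.9, 2.5, 0.1, 1.1)
  expect_equal(spearman_rho(x, y)$rho, cor(rank(x), rank(y)))
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_rho(1:2, 1:2), "length")
})

test_that("quartile stratification splits strictly above the interpolated Q3", {
  g <- quartile_stratify(1:8)
  expect_identical(which(g == "high"), c(7L, 8L))  # Q3 = 6.25
  expect_true(all(quartile_stratify(rep(5, 10)) == "low"))
  v <- c(1, 2, 3, 100)
  expect_identical(as.character(quartile_stratify(v)[4]), "high")
  expect_error(quartile_stratify(1:3), "at least 4")
})

test_that("identical groups give a null log-rank and KM tracks the empirical
           survivor function without censoring", {
  time <- c(5, 8, 12, 20, 33)
  event <- c(1, 1, 0, 1, 1)
  res <- km_logrank(rep(time, 2), rep(event, 2),
                    rep(c("a", "b"), each = 5))
  expect_lt(res$chisq, 1e-10)
  expect_gt(res$p, 0.999)

  t2 <- c(1, 3, 4, 7, 9, 2, 5, 6, 8, 10)
  ev <- rep(1, 10)
  grp <- rep(c("a", "b"), each = 5)
  res2 <- km_logrank(t2, ev, grp)
  km_a <- res2$km[res2$km$group == "a", ]
  expect_equal(km_a$surv,
               vapply(km_a$time, function(t) mean(t2[grp == "a"] > t),
                      numeric(1)))
  expect_error(km_logrank(t2, ev, rep("a", 10)), "two")
})

test_that("the log-rank statistic matches the textbook observed-minus-expected
           oracle on a 10-subject fixture", {
  time <- c(3, 5, 7, 9, 14, 2, 4, 6, 8, 10)
  event <- c(1, 0, 1, 1, 1, 1, 1, 0, 1, 1)
  group <- rep(c("a", "b"), each = 5)
  res <- km_logrank(time, event, group)
  expect_equal(res$chisq, oracle_logrank_chisq(time, event, group),
               tolerance = 1e-8)
  expect_equal(res$p, pchisq(res$chisq, 1, lower.tail = FALSE))
})

test_that("rank-sum p-values are exact for small untied samples and the
           approximation agrees near the path boundary", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(wilcoxon_rank_sum(c(2, 7), c(2, 7)), 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
  # exact vs normal-approximation agreement at n = 8 per group
  for (s in 1:5) {
    a <- withr::with_seed(100 + s, rnorm(8))
    b <- withr::with_seed(200 + s, rnorm(8, 0.5))
    p_exact <- wilcoxon_rank_sum(a, b, exact_max = 8)
    p_approx <- wilcoxon_rank_sum(a, b, exact_max = 0)
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})
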