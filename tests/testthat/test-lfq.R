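test_that("LFQ simulator controls missingness by construction", {
  none <- simulate_lfq_experiment(100, 10, mnar_threshold_quantile = 0,
                                  mar_rate = 0, seed = 1)
  expect_false(any(is.na(none$intensities)))

  sim <- simulate_lfq_experiment(800, 0, mnar_threshold_quantile = 0.3,
                                 mar_rate = 0, seed = 2)
  obs <- sim$intensities
  miss <- is.na(obs)
  expect_true(all(sim$truth$mechanism[miss] == "MNAR"))
  expect_gt(mean(miss), 0.15)
  # dropout is intensity-dependent: low-abundance proteins lose far more
  # cells than high-abundance proteins
  prot_mean <- rowMeans(obs, na.rm = TRUE)
  lowest <- prot_mean <= quantile(prot_mean, 0.25, na.rm = TRUE)
  highest <- prot_mean >= quantile(prot_mean, 0.75, na.rm = TRUE)
  expect_gt(mean(miss[lowest, ], na.rm = TRUE),
            mean(miss[highest, ], na.rm = TRUE))

  expect_identical(simulate_lfq_experiment(50, 5, seed = 3),
                   simulate_lfq_experiment(50, 5, seed = 3))
  expect_error(simulate_lfq_experiment(10, 20), "n_enriched")
})

test_that("every missing cell carries exactly one generating mechanism", {
  sim <- simulate_lfq_experiment(600, 60, mnar_threshold_quantile = 0.2,
                                 mar_rate = 0.1, seed = 4)
  miss <- is.na(sim$intensities)
  mech <- sim$truth$mechanism
  expect_true(all(mech[miss] %in% c("MNAR", "MAR")))
  expect_true(all(mech[!miss] == "observed"))
})

test_that("the two-value filter keeps proteins informative in either group", {
  groups <- factor(rep(c("control", "bait"), each = 3),
                   levels = c("control", "bait"))
  x <- rbind(
    both_poor = c(5, NA, NA, 6, NA, NA),    # 1 + 1 observed -> filtered
    one_good = c(5, NA, NA, 6, 7, 8),       # 1 + 3 observed -> kept
    complete = c(5, 6, 7, 8, 9, 10)         # kept
  )
  colnames(x) <- paste0("s", 1:6)
  kept <- filter_protein_groups(x, groups)
  expect_identical(unname(kept), c(FALSE, TRUE, TRUE))
})

test_that("missingness labels follow the pattern rules with MAR fallback", {
  groups <- factor(rep(c("control", "bait"), each = 3),
                   levels = c("control", "bait"))
  x <- rbind(
    mnar3 = c(NA, NA, NA, 8, 9, 10),   # (3 missing, complete) -> MNAR
    mnar2 = c(5, NA, NA, 8, 9, 10),    # (2 missing, complete) -> MNAR
    mar11 = c(NA, 6, 7, NA, 9, 10),    # (1, 1) -> MAR
    mixed21 = c(NA, NA, 7, NA, 9, 10)  # (2, 1) -> ambiguous, all MAR
  )
  colnames(x) <- paste0("s", 1:6)
  lab <- classify_missingness(x, groups)
  expect_true(all(lab["mnar3", 1:3] == "MNAR"))
  expect_identical(unname(lab["mnar2", ]),
                   c(NA, "MNAR", "MNAR", NA, NA, NA))
  expect_identical(unname(lab["mar11", c(1, 4)]), c("MAR", "MAR"))
  expect_true(all(lab["mixed21", c(1, 2, 4)] == "MAR"))
  expect_true(all(is.na(lab[!is.na(x)])))

  unfiltered <- rbind(x, bad = c(5, NA, NA, 6, NA, NA))
  expect_error(classify_missingness(unfiltered, groups),
               "filter_protein_groups")
})

test_that("MinDet imputes the column minimum and kNN the neighbour mean", {
  groups <- factor(rep(c("control", "bait"), each = 3),
                   levels = c("control", "bait"))
  x <- rbind(
    p1 = c(NA, NA, NA, 8, 9, 10),        # MNAR in control columns
    p2 = c(5.1, 7.3, 8.0, 8, 9, 10),
    p3 = c(6.0, 7.0, 8.1, 8.1, 9.2, 10.3),
    p4 = c(5.9, NA, 8.05, 8.05, 9.1, 10.2)  # MAR at s2
  )
  colnames(x) <- paste0("s", 1:6)
  lab <- classify_missingness(x, groups)
  done <- impute_lfq(x, lab, k = 1)
  # MNAR cells take each column's observed minimum
  expect_equal(unname(done["p1", 1:3]), c(5.1, 7.0, 8.0))
  # p4's nearest neighbour on shared entries is p3 -> its value at s2
  expect_equal(done["p4", "s2"], 7.0)
  expect_false(any(is.na(done)))
  # a complete matrix passes through unchanged
  complete <- x[2:3, ]
  expect_identical(impute_lfq(complete, matrix(NA_character_, 2, 6,
                                               dimnames = dimnames(complete))),
                   complete)
  # MinDet never exceeds the column minimum of observed values
  sim <- simulate_lfq_experiment(300, 0, mnar_threshold_quantile = 0.25,
                                 mar_rate = 0.05, seed = 5)
  kept <- filter_protein_groups(sim$intensities, sim$groups)
  xk <- sim$intensities[kept, ]
  labk <- classify_missingness(xk, sim$groups)
  impk <- impute_lfq(xk, labk)
  mnar_cells <- which(labk == "MNAR", arr.ind = TRUE)
  col_min <- apply(xk, 2, min, na.rm = TRUE)
  expect_true(all(impk[mnar_cells] <= col_min[mnar_cells[, 2]] + 1e-12))
})

test_that("quantile normalization equalizes sorted columns exactly", {
  x <- cbind(a = c(1, 3), b = c(2, 8))
  qn <- quantile_normalize(x)
  expect_equal(unname(qn), cbind(c(1.5, 5.5), c(1.5, 5.5)),
               ignore_attr = TRUE)

  same <- cbind(a = c(4, 1, 9), b = c(4, 1, 9))
  expect_equal(quantile_normalize(same), same)

  y <- withr::with_seed(6, matrix(rnorm(600), ncol = 6))
  y[sample(length(y), 30)] <- y[1]  # inject ties
  qy <- quantile_normalize(y)
  sorted <- apply(qy, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  # within-column ranks preserved (ties resolved by row order)
  for (j in 1:6)
    expect_equal(order(qy[, j], seq_len(nrow(y))),
                 order(y[, j], seq_len(nrow(y))))
  expect_error(quantile_normalize(cbind(c(1, NA))), "complete")
})

test_that("moderated t reduces to the pooled t at d0 = 0 and to s0 at d0 = Inf", {
  groups <- factor(rep(c("control", "bait"), each = 3),
                   levels = c("control", "bait"))
  x <- withr::with_seed(7, matrix(rnorm(180, 20), ncol = 6,
                                  dimnames = list(sprintf("p%02d", 1:30),
                                                  paste0("s", 1:6))))
  r0 <- moderated_t_test(x, groups, d0 = 0, s0_2 = 1)
  for (i in c(1, 10, 30)) {
    tt <- t.test(x[i, 4:6], x[i, 1:3], var.equal = TRUE)
    expect_equal(r0$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r0$p[i], tt$p.value, tolerance = 1e-12)
  }
  rInf <- moderated_t_test(x, groups, d0 = Inf, s0_2 = 0.5)
  expect_true(all(rInf$s2_post == 0.5))
  expect_equal(rInf$t, rInf$logFC / sqrt(0.5 * (2 / 3)))
})

test_that("the moment-fitted prior matches an independent oracle and limma", {
  groups <- factor(rep(c("control", "bait"), each = 3),
                   levels = c("control", "bait"))
  # heteroscedastic proteins so the prior degrees of freedom are finite
  x <- withr::with_seed(8, {
    sd_g <- sqrt(8 / rchisq(200, df = 8))
    matrix(rnorm(200 * 6, mean = 20, sd = rep(sd_g, 6)), ncol = 6,
           dimnames = list(sprintf("p%03d", 1:200), paste0("s", 1:6)))
  })
  res <- moderated_t_test(x, groups)
  expect_true(is.finite(attr(res, "d0")))
  # independent straight-line oracle for the moment equations
  dg <- 4
  s2 <- res$s2
  oracle <- oracle_variance_prior(s2, dg)
  expect_equal(attr(res, "d0"), oracle$d0, tolerance = 1e-6)
  expect_equal(attr(res, "s0_2"), oracle$s0_2, tolerance = 1e-6)
  # cross-check the full statistic against limma's empirical Bayes
  design <- cbind(1, as.numeric(groups == "bait"))
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s0_2"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  p <- withr::with_seed(9, runif(50)^2)
  adj <- adjust_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(adjust_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("the full BioID pipeline returns labelled, adjusted results", {
  sim <- simulate_lfq_experiment(200, 30, effect_log2 = 6, seed = 10,
                                 mnar_threshold_quantile = 0.15,
                                 mar_rate = 0.05)
  res <- bioid_differential(sim$intensities, sim$groups)
  expect_true(all(c("logFC", "t", "p", "fdr", "n_mnar", "n_mar") %in% names(res)))
  expect_true(all(res$fdr >= res$p - 1e-15))
  labels <- attr(res, "labels")
  kept_ids <- res$protein_id
  miss <- is.na(sim$intensities[kept_ids, ])
  expect_true(all(!is.na(labels[miss])))     # every missing cell labelled
  expect_true(all(is.na(labels[!miss])))     # and only missing cells
  # strong bait-specific enrichment (64-fold) is overwhelmingly detected,
  # with positive fold changes (no FDP bound here: minimum-value imputation
  # of censored control values is known to admit false discoveries)
  enr <- names(which(sim$truth$enriched))
  hit <- res$protein_id[res$fdr < 0.05]
  expect_gt(mean(enr %in% hit), 0.7)
  expect_gt(median(res$logFC[res$protein_id %in% enr]), 2)
})
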