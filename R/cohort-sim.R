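#' Simulate an expression cohort with anti-correlated latent activities
#'
#' Each patient carries two latent activities — a repressor activity
#' (`trps1_act`) and a coactivator activity (`yap_act`) — drawn from a
#' standard bivariate normal with correlation `latent_correlation`
#' (default -0.85: high repressor activity accompanies low coactivator
#' activity). Signature genes load on the latents: repressor-target genes
#' rise when repressor activity is LOW (`expression = -loading * trps1_act
#' + noise`), coactivator-induced genes rise with coactivator activity
#' (`+loading * yap_act + noise`); all other genes are pure noise.
#' Survival is exponential with per-patient hazard
#' `baseline_hazard * hazard_ratio_per_sd ^ trps1_act`; an independent
#' censoring coin with probability `censor_rate` replaces the event time by
#' a uniform draw on (0, event time). A continuous copy-number score
#' (`cnv`) tracks the repressor latent with noise.
#'
#' @param n_patients,n_genes Cohort dimensions.
#' @param trps1_set_size,yap_set_size Sizes of the two disjoint signature
#'   sets (first genes of the matrix).
#' @param latent_correlation Correlation of the two latents, in (-1, 1).
#' @param hazard_ratio_per_sd Hazard ratio per SD of repressor activity
#'   (default 1: no survival effect).
#' @param censor_rate Probability a patient is censored (default 0.3).
#' @param seed Integer seed.
#' @param loading Signature-gene loading on its latent (default 1).
#' @param noise_sd Per-gene residual SD (default 1).
#' @param baseline_hazard Baseline exponential hazard (default 0.1 per
#'   time unit).
#'
#' @return A list with `expression` (gene x patient matrix), `clinical`
#'   (data frame `sample_id`, `time`, `event`, `subtype`, `cnv`),
#'   `gene_sets` (list `trps1_repressed`, `yap_induced`) and `truth`
#'   (data frame of latent activities).
#' @export
simulate_cohort <- function(n_patients, n_genes, trps1_set_size = 300,
                            yap_set_size = 300, latent_correlation = -0.85,
                            hazard_ratio_per_sd = 1, censor_rate = 0.3,
                            seed = 1, loading = 1, noise_sd = 1,
                            baseline_hazard = 0.1) {
  n_patients <- assert_count(n_patients, "n_patients")
  n_genes <- assert_count(n_genes, "n_genes")
  trps1_set_size <- assert_count(trps1_set_size, "trps1_set_size")
  yap_set_size <- assert_count(yap_set_size, "yap_set_size")
  rho <- assert_fraction(latent_correlation, "latent_correlation",
                         lo = -1, hi = 1, lo_open = TRUE, hi_open = TRUE)
  assert_fraction(censor_rate, "censor_rate", hi = 1, hi_open = TRUE)
  assert_number(hazard_ratio_per_sd, "hazard_ratio_per_sd", positive = TRUE)
  if (trps1_set_size + yap_set_size > n_genes)
    stopf("signature sets must be disjoint subsets of the %d genes", n_genes)
  seeded(seed, {
    z1 <- rnorm(n_patients)
    z2 <- rnorm(n_patients)
    trps1_act <- z1
    yap_act <- rho * z1 + sqrt(1 - rho^2) * z2
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    set_t <- gene_ids[seq_len(trps1_set_size)]
    set_y <- gene_ids[trps1_set_size + seq_len(yap_set_size)]
    expr <- matrix(rnorm(n_genes * n_patients, 0, noise_sd), n_genes,
                   dimnames = list(gene_ids,
                                   sprintf("pt%04d", seq_len(n_patients))))
    expr[set_t, ] <- expr[set_t, ] +
      matrix(-loading * trps1_act, trps1_set_size, n_patients, byrow = TRUE)
    expr[set_y, ] <- expr[set_y, ] +
      matrix(loading * yap_act, yap_set_size, n_patients, byrow = TRUE)
    hazard <- baseline_hazard * hazard_ratio_per_sd^trps1_act
    event_time <- rexp(n_patients, rate = hazard)
    censored <- runif(n_patients) < censor_rate
    time <- ifelse(censored, runif(n_patients, 0, event_time), event_time)
    clinical <- data.frame(
      sample_id = colnames(expr),
      time = time,
      event = as.integer(!censored),
      subtype = sample(c("LumA", "LumB", "Her2", "Basal"), n_patients,
                       replace = TRUE, prob = c(0.5, 0.2, 0.1, 0.2)),
      cnv = trps1_act + rnorm(n_patients, 0, 0.5),
      stringsAsFactors = FALSE
    )
    list(expression = expr, clinical = clinical,
         gene_sets = list(trps1_repressed = set_t, yap_induced = set_y),
         truth = data.frame(sample_id = colnames(expr),
                            trps1_act = trps1_act, yap_act = yap_act,
                            stringsAsFactors = FALSE))
  })
}

#' Write cohort tables to TSV
#'
#' @param cohort A [simulate_cohort()] result.
#' @param expression_path,clinical_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, expression_path, clinical_path) {
  expr_df <- data.frame(gene_id = rownames(cohort$expression),
                        cohort$expression, check.names = FALSE,
                        stringsAsFactors = FALSE)
  write.table(expr_df, expression_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$clinical, clinical_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(expression_path, clinical_path))
}

#' Read an expression matrix from TSV (first column = gene_id)
#' @param path File path.
#' @return Numeric gene x sample matrix.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
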