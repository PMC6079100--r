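#' Simulate a two-group label-free proteomics (LFQ) experiment
#'
#' Generates a log2 protein x sample intensity matrix for a control group
#' and a bait group (default 3 + 3 replicates), with `n_enriched` proteins
#' shifted by `effect_log2` in the bait group. Missingness combines two
#' mechanisms, applied in this order so every missing cell has exactly one
#' generating label: cells whose true intensity falls below the
#' `mnar_threshold_quantile` of all true intensities are dropped with
#' probability `mnar_prob` (intensity-dependent dropout, MNAR); remaining
#' observed cells are dropped uniformly at `mar_rate` (MAR).
#'
#' @param n_proteins Number of proteins.
#' @param n_enriched Number of bait-enriched proteins (first rows).
#' @param group_sizes Integer vector of length 2 (default `c(3, 3)`).
#' @param effect_log2 log2 enrichment of bait-group intensities (default 2).
#' @param mnar_threshold_quantile Quantile of true intensities below which
#'   intensity-dependent dropout applies (0 disables it).
#' @param mar_rate Uniform dropout rate on the remaining cells (0 disables).
#' @param seed Integer seed.
#' @param base_mean,base_sd Mean and SD of per-protein baseline log2
#'   intensity (defaults 25 and 3, typical of LFQ scales).
#' @param noise_sd Within-protein replicate SD (default 1).
#' @param mnar_prob Dropout probability below the intensity threshold
#'   (default 0.9).
#'
#' @return A list with `intensities` (matrix with `NA` at missing cells),
#'   `groups` (factor, levels `control`, `bait`) and `truth` (list with
#'   `enriched` logical vector and `mechanism` matrix with entries
#'   `"observed"`, `"MNAR"`, `"MAR"`).
#' @export
simulate_lfq_experiment <- function(n_proteins, n_enriched = 0,
                                    group_sizes = c(3, 3), effect_log2 = 2,
                                    mnar_threshold_quantile = 0.1,
                                    mar_rate = 0.05, seed = 1,
                                    base_mean = 25, base_sd = 3,
                                    noise_sd = 1, mnar_prob = 0.9) {
  n_proteins <- assert_count(n_proteins, "n_proteins")
  n_enriched <- assert_count(n_enriched, "n_enriched", min = 0)
  if (n_enriched > n_proteins) stopf("n_enriched must be <= n_proteins")
  if (length(group_sizes) != 2 || any(group_sizes < 2))
    stopf("group_sizes must be two integers >= 2")
  assert_fraction(mnar_threshold_quantile, "mnar_threshold_quantile",
                  hi = 1, hi_open = TRUE)
  assert_fraction(mar_rate, "mar_rate", hi = 1, hi_open = TRUE)
  n_samples <- sum(group_sizes)
  groups <- factor(rep(c("control", "bait"), group_sizes),
                   levels = c("control", "bait"))
  seeded(seed, {
    mu <- rnorm(n_proteins, base_mean, base_sd)
    enriched <- seq_len(n_proteins) <= n_enriched
    true <- matrix(mu, n_proteins, n_samples) +
      outer(ifelse(enriched, effect_log2, 0), as.numeric(groups == "bait")) +
      matrix(rnorm(n_proteins * n_samples, 0, noise_sd), n_proteins)
    dimnames(true) <- list(sprintf("prot%05d", seq_len(n_proteins)),
                           paste0(rep(c("ctrl", "bait"), group_sizes),
                                  c(seq_len(group_sizes[1]),
                                    seq_len(group_sizes[2]))))
    mechanism <- matrix("observed", n_proteins, n_samples,
                        dimnames = dimnames(true))
    if (mnar_threshold_quantile > 0) {
      thr <- quantile(true, mnar_threshold_quantile, names = FALSE)
      low <- true < thr
      drop_mnar <- low & matrix(runif(length(true)) < mnar_prob,
                                n_proteins, n_samples)
      mechanism[drop_mnar] <- "MNAR"
    }
    if (mar_rate > 0) {
      candidate <- mechanism == "observed"
      drop_mar <- candidate & matrix(runif(length(true)) < mar_rate,
                                     n_proteins, n_samples)
      mechanism[drop_mar] <- "MAR"
    }
    intensities <- true
    intensities[mechanism != "observed"] <- NA_real_
    list(intensities = intensities, groups = groups,
         truth = list(enriched = setNames(enriched, rownames(true)),
                      mechanism = mechanism))
  })
}

#' Read / write an LFQ intensity matrix
#'
#' TSV with a `protein_id` column and one numeric column per sample; an
#' empty cell encodes a missing intensity.
#'
#' @param path File path.
#' @return `read_lfq_matrix()`: numeric matrix with `NA` at missing cells.
#' @export
read_lfq_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  if (names(df)[1] != "protein_id")
    stopf("LFQ table must start with a protein_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$protein_id
  storage.mode(m) <- "double"
  m
}

#' @rdname read_lfq_matrix
#' @param x Numeric matrix (proteins x samples), `NA` = missing.
#' @export
write_lfq_matrix <- function(x, path) {
  df <- data.frame(protein_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
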