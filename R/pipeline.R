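pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = "results",
    alpha = 0.01,
    rpkm_threshold = 1,
    trim_length = 20L,
    tss_window = 50000L,
    fragment_cutoff = 146L,
    knn_k = 10L,
    quantile_type = 7L,
    lfc_threshold = 1,
    fdr_threshold = 0.05,
    n_genes = 100L,
    guides_per_gene = 6L,
    n_control_guides = 3L,
    cells_per_guide = 200L,
    sort_fraction = 0.01,
    sequencing_depth = 1e6,
    n_proteins = 500L,
    n_enriched = 50L,
    effect_log2 = 2,
    mnar_threshold_quantile = 0.1,
    mar_rate = 0.05,
    n_patients = 200L,
    cohort_genes = 2000L,
    trps1_set_size = 300L,
    yap_set_size = 300L,
    latent_correlation = -0.85,
    hazard_ratio_per_sd = 1,
    censor_rate = 0.3,
    paths = list()
  )
}

config_range_checks <- list(
  alpha = function(v) v > 0 && v < 1,
  sort_fraction = function(v) v > 0 && v < 0.5,
  mar_rate = function(v) v >= 0 && v < 1,
  mnar_threshold_quantile = function(v) v >= 0 && v < 1,
  censor_rate = function(v) v >= 0 && v < 1,
  latent_correlation = function(v) v > -1 && v < 1,
  fdr_threshold = function(v) v > 0 && v <= 1,
  trim_length = function(v) v >= 1,
  knn_k = function(v) v >= 1,
  tss_window = function(v) v >= 0,
  fragment_cutoff = function(v) v >= 1
)

#' Validate a pipeline configuration
#'
#' Parses a YAML config (text, file path, or an already-parsed list),
#' fills in defaults, rejects unknown keys (suggesting the closest known
#' key) and range-checks the thresholds.
#'
#' @param config YAML text, a path to a YAML file, a list, or `NULL`
#'   (all defaults).
#' @return A fully-defaulted list of class `pipeline_config`.
#' @export
validate_config <- function(config = NULL) {
  defaults <- pipeline_defaults()
  user <- if (is.null(config)) {
    list()
  } else if (is.list(config)) {
    config
  } else if (length(config) == 1 && file.exists(config)) {
    yaml::read_yaml(config)
  } else {
    yaml::yaml.load(paste(config, collapse = "\n"))
  }
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    key <- unknown[1]
    d <- utils::adist(key, names(defaults))
    hint <- names(defaults)[which.min(d)]
    stopf("unknown config key '%s'%s", key,
          if (min(d) <= 3) sprintf(" (did you mean '%s'?)", hint) else "")
  }
  cfg <- utils::modifyList(defaults, user)
  for (key in names(config_range_checks)) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !config_range_checks[[key]](v))
      stopf("config key '%s' is out of range (got %s)", key,
            paste(format(v), collapse = ","))
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

write_manifest <- function(outdir, subcommand, cfg, inputs, outputs,
                           status = "ok") {
  manifest <- list(
    subcommand = subcommand,
    status = status,
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "paths")],
    inputs = inputs,
    outputs = outputs,
    package = as.character(utils::packageVersion("sortscreen"))
  )
  path <- file.path(outdir, paste0("manifest_", subcommand, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

require_input <- function(cfg, key) {
  p <- cfg$paths[[key]]
  if (is.null(p)) stopf("config paths.%s is required for this subcommand", key)
  if (!file.exists(p)) stopf("input file not found: %s", p)
  p
}

#' Run a pipeline stage
#'
#' Dispatches one subcommand of the analysis pipeline, writes its output
#' tables under `config$outdir` and records a JSON manifest (inputs,
#' parameters, seed, outputs). Reruns with the same config are
#' deterministic.
#'
#' Subcommands: `simulate-screen`, `simulate-lfq`, `simulate-cohort`,
#' `count`, `screen-analyze`, `bioid-analyze`, `score-cohort`, `overlap`,
#' `assign-genes`, `stratify-fragments`.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @param subcommand One of the stage names above.
#' @return Invisibly, a character vector of written output paths.
#' @export
run_pipeline <- function(config, subcommand) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  subcommands <- c("simulate-screen", "simulate-lfq", "simulate-cohort",
                   "count", "screen-analyze", "bioid-analyze",
                   "score-cohort", "overlap", "assign-genes",
                   "stratify-fragments")
  subcommand <- match.arg(subcommand, subcommands)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(cfg$outdir, "")
  inputs <- list()
  outputs <- character(0)

  if (subcommand == "simulate-screen") {
    lib <- make_guide_library(cfg$n_genes, cfg$guides_per_gene,
                              cfg$n_control_guides, seed = cfg$seed)
    sim <- simulate_sort_screen(lib, params = screen_sim_params(
      cells_per_guide = cfg$cells_per_guide,
      sort_fraction = cfg$sort_fraction,
      sequencing_depth = cfg$sequencing_depth, seed = cfg$seed))
    outputs <- c(
      write_guide_library(lib, file.path(cfg$outdir, "guide_library.tsv")),
      write_count_table(sim$counts, file.path(cfg$outdir, "counts.tsv")))
    write.table(sim$truth, file.path(cfg$outdir, "screen_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, file.path(cfg$outdir, "screen_truth.tsv"))
  } else if (subcommand == "simulate-lfq") {
    sim <- simulate_lfq_experiment(cfg$n_proteins, cfg$n_enriched,
                                   effect_log2 = cfg$effect_log2,
                                   mnar_threshold_quantile = cfg$mnar_threshold_quantile,
                                   mar_rate = cfg$mar_rate, seed = cfg$seed)
    p <- file.path(cfg$outdir, "lfq_matrix.tsv")
    write_lfq_matrix(sim$intensities, p)
    g <- file.path(cfg$outdir, "lfq_groups.tsv")
    write.table(data.frame(sample = colnames(sim$intensities),
                           group = as.character(sim$groups)),
                g, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(p, g)
  } else if (subcommand == "simulate-cohort") {
    sim <- simulate_cohort(cfg$n_patients, cfg$cohort_genes,
                           cfg$trps1_set_size, cfg$yap_set_size,
                           latent_correlation = cfg$latent_correlation,
                           hazard_ratio_per_sd = cfg$hazard_ratio_per_sd,
                           censor_rate = cfg$censor_rate, seed = cfg$seed)
    ep <- file.path(cfg$outdir, "expression.tsv")
    cp <- file.path(cfg$outdir, "clinical.tsv")
    write_cohort(sim, ep, cp)
    for (nm in names(sim$gene_sets))
      writeLines(sim$gene_sets[[nm]],
                 file.path(cfg$outdir, paste0(nm, "_set.txt")))
    outputs <- c(ep, cp,
                 file.path(cfg$outdir, paste0(names(sim$gene_sets), "_set.txt")))
  } else if (subcommand == "count") {
    lib <- read_guide_library(inputs$library <- require_input(cfg, "library"))
    fq <- inputs$fastq <- require_input(cfg, "fastq")
    res <- count_reads(fq, lib, trim_length = cfg$trim_length)
    p <- file.path(cfg$outdir, "counts_single.tsv")
    write.table(data.frame(guide_id = names(res$counts),
                           count = as.integer(res$counts)),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("assigned %d reads, %d unassigned",
                    sum(res$counts), res$n_unassigned))
    outputs <- p
  } else if (subcommand == "screen-analyze") {
    lib <- read_guide_library(inputs$library <- require_input(cfg, "library"))
    counts <- read_count_table(inputs$counts <- require_input(cfg, "counts"))
    normalized <- normalize_counts(counts)
    tabs <- lapply(c(high = "high", low = "low"), function(s) {
      e <- guide_enrichment(normalized, s)
      rsa <- rsa_scores(e, lib, direction = s)
      rsa$hit <- rsa$p_min < cfg$alpha
      rsa
    })
    rsa_all <- do.call(rbind, tabs)
    p <- file.path(cfg$outdir, "rsa_results.tsv")
    write.table(rsa_all, p, sep = "\t", quote = FALSE, row.names = FALSE)
    e_tab <- data.frame(guide_id = rownames(normalized),
                        high = guide_enrichment(normalized, "high"),
                        low = guide_enrichment(normalized, "low"))
    pe <- file.path(cfg$outdir, "guide_enrichment.tsv")
    write.table(e_tab, pe, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(p, pe)
  } else if (subcommand == "bioid-analyze") {
    x <- read_lfq_matrix(inputs$lfq <- require_input(cfg, "lfq"))
    gt <- read.delim(inputs$groups <- require_input(cfg, "groups"),
                     stringsAsFactors = FALSE)
    groups <- factor(gt$group[match(colnames(x), gt$sample)],
                     levels = unique(gt$group))
    res <- bioid_differential(x, groups, k = cfg$knn_k)
    p <- file.path(cfg$outdir, "bioid_results.tsv")
    write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- p
  } else if (subcommand == "score-cohort") {
    expr <- read_expression_matrix(inputs$expression <- require_input(cfg, "expression"))
    clin <- read.delim(inputs$clinical <- require_input(cfg, "clinical"),
                       stringsAsFactors = FALSE)
    set_t <- readLines(inputs$trps1_set <- require_input(cfg, "trps1_set"))
    set_y <- readLines(inputs$yap_set <- require_input(cfg, "yap_set"))
    act <- activity_scores(expr, set_t, set_y)
    p <- file.path(cfg$outdir, "activities.tsv")
    write.table(act, p, sep = "\t", quote = FALSE, row.names = FALSE)
    rho <- spearman_rho(act$trps1_activity, act$yap_activity)
    strat <- quartile_stratify(clin$cnv, type = cfg$quantile_type)
    surv <- km_logrank(clin$time, clin$event, strat)
    report <- file.path(cfg$outdir, "cohort_report.json")
    jsonlite::write_json(list(spearman_rho = rho$rho, spearman_p = rho$p,
                              logrank_chisq = surv$chisq,
                              logrank_p = surv$p),
                         report, auto_unbox = TRUE, digits = NA)
    km <- file.path(cfg$outdir, "km_table.tsv")
    write.table(surv$km, km, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(p, report, km)
  } else if (subcommand == "overlap") {
    peaks_a <- read_bed(inputs$peaks_a <- require_input(cfg, "peaks_a"))
    peaks_b <- read_bed(inputs$peaks_b <- require_input(cfg, "peaks_b"))
    universe <- read_bed(inputs$universe <- require_input(cfg, "universe"))
    region_id <- seq_len(nrow(universe))
    bound_by <- function(pk) {
      pts <- interval_summits(pk)
      gr <- GenomicRanges::GRanges(pk$chrom,
                                   IRanges::IRanges(pts + 1L, pts + 1L))
      hits <- GenomicRanges::countOverlaps(as_iranges_halfopen(universe), gr)
      region_id[hits > 0]
    }
    ba <- bound_by(peaks_a); bb <- bound_by(peaks_b)
    venn <- pairwise_set_counts(ba, bb)
    pval <- overlap_enrichment_test(length(intersect(ba, bb)), length(bb),
                                    length(ba), nrow(universe))
    p <- file.path(cfg$outdir, "overlap_report.json")
    jsonlite::write_json(list(universe = nrow(universe),
                              bound_a = length(ba), bound_b = length(bb),
                              shared = length(intersect(ba, bb)),
                              venn = as.list(venn), p = pval),
                         p, auto_unbox = TRUE, digits = NA)
    outputs <- p
  } else if (subcommand == "assign-genes") {
    peaks <- read_bed(inputs$peaks <- require_input(cfg, "peaks"))
    tss <- read.delim(inputs$tss <- require_input(cfg, "tss"),
                      stringsAsFactors = FALSE)
    asg <- peaks_near_tss(peaks, tss, window = cfg$tss_window)
    p <- file.path(cfg$outdir, "gene_assignments.tsv")
    write.table(asg, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- p
  } else if (subcommand == "stratify-fragments") {
    frags <- read_bed(inputs$fragments <- require_input(cfg, "fragments"))
    strat <- stratify_fragments(frags, cutoff = cfg$fragment_cutoff)
    p1 <- file.path(cfg$outdir, "fragments_sub_nucleosomal.bed")
    p2 <- file.path(cfg$outdir, "fragments_nucleosomal.bed")
    write_bed(strat$sub_nucleosomal, p1)
    write_bed(strat$nucleosomal, p2)
    outputs <- c(p1, p2)
  }

  write_manifest(cfg$outdir, subcommand, cfg, inputs, outputs)
  invisible(outputs)
}
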