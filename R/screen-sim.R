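#' Parameters for the sorted-screen simulator
#'
#' Bundles the experimental design of a reporter-sorted pooled CRISPR screen:
#' every guide infects `cells_per_guide` cells on average (the library
#' redundancy), each cell's reporter fluorescence is Gaussian around the
#' gene-specific effect, and the `sort_fraction` least / most fluorescent
#' cells become the "low" / "high" subpopulations, which are then sequenced
#' to `sequencing_depth` reads alongside the unsorted pool.
#'
#' @param cells_per_guide Library redundancy (default 200 cells per guide).
#' @param sort_fraction Fraction of cells collected in each tail gate
#'   (default 0.01, i.e. the 1% extremes); must be in (0, 0.5).
#' @param reporter_sd Standard deviation of the per-cell reporter signal in
#'   effect units (default 1; gene effects are expressed in these SD units).
#' @param sequencing_depth Reads sequenced per sample (default 1e6).
#' @param control_effect Reporter shift applied to positive-control guides
#'   when the caller does not supply one (default -5 SD: knocking out the
#'   sorted reporter construct abolishes its signal).
#' @param abundance_sd_log SD of an optional log-normal jitter on pre-sort
#'   guide abundance (default 0: even representation).
#' @param seed Integer seed.
#'
#' @return A list of class `screen_sim_params`.
#' @export
screen_sim_params <- function(cells_per_guide = 200, sort_fraction = 0.01,
                              reporter_sd = 1, sequencing_depth = 1e6,
                              control_effect = -5, abundance_sd_log = 0,
                              seed = 1) {
  p <- list(
    cells_per_guide = assert_count(cells_per_guide, "cells_per_guide"),
    sort_fraction = assert_fraction(sort_fraction, "sort_fraction",
                                    lo = 0, hi = 0.5, lo_open = TRUE,
                                    hi_open = TRUE),
    reporter_sd = assert_number(reporter_sd, "reporter_sd", positive = TRUE),
    sequencing_depth = assert_count(sequencing_depth, "sequencing_depth"),
    control_effect = assert_number(control_effect, "control_effect"),
    abundance_sd_log = assert_number(abundance_sd_log, "abundance_sd_log"),
    seed = assert_count(seed, "seed", min = 0)
  )
  structure(p, class = "screen_sim_params")
}

#' Simulate a FACS-sorted pooled CRISPR screen
#'
#' Cells are assigned to guides by multinomial sampling over the library
#' (uniform abundance by default), each cell draws a reporter value
#' `Normal(effect(gene), reporter_sd)`, the bottom and top `sort_fraction`
#' of cells by reporter become the "low" and "high" samples, and each of the
#' three samples (unsorted, low, high) is sequenced by multinomial sampling
#' of `sequencing_depth` reads over its guide composition. Genes that shift
#' the reporter down deplete their guides from the "high" gate and enrich
#' them in the "low" gate, and vice versa.
#'
#' @param library A `guide_library`.
#' @param effects Named numeric vector of per-gene reporter shifts in
#'   reporter-SD units; genes not named default to 0. The control gene
#'   defaults to `params$control_effect` unless named explicitly.
#' @param params A [screen_sim_params()] object.
#'
#' @return A list with `counts` (a [screen_counts()] object with samples
#'   `unsorted`, `low`, `high`) and `truth` (data frame of per-gene effects).
#' @export
simulate_sort_screen <- function(library, effects = NULL,
                                 params = screen_sim_params()) {
  library <- validate_guide_library(library)
  stopifnot(inherits(params, "screen_sim_params"))
  if (params$sequencing_depth <= 0) stopf("sequencing_depth must be positive")
  genes <- unique(library$gene_id)
  eff <- setNames(numeric(length(genes)), genes)
  if (control_gene_id() %in% genes)
    eff[control_gene_id()] <- params$control_effect
  if (!is.null(effects)) {
    if (is.null(names(effects)) || !all(names(effects) %in% genes))
      stopf("`effects` must be named with gene ids present in the library")
    eff[names(effects)] <- effects
  }

  seeded(params$seed, {
    n_guides <- nrow(library)
    n_cells <- n_guides * params$cells_per_guide
    w <- if (params$abundance_sd_log > 0)
      exp(rnorm(n_guides, 0, params$abundance_sd_log)) else NULL
    cell_guide <- sample.int(n_guides, n_cells, replace = TRUE, prob = w)
    guide_eff <- eff[library$gene_id]
    reporter <- rnorm(n_cells, mean = guide_eff[cell_guide],
                      sd = params$reporter_sd)
    n_sort <- max(1L, floor(params$sort_fraction * n_cells))
    ord <- order(reporter)
    low_cells <- ord[seq_len(n_sort)]
    high_cells <- ord[seq.int(n_cells - n_sort + 1L, n_cells)]

    comp <- cbind(
      unsorted = tabulate(cell_guide, n_guides),
      low = tabulate(cell_guide[low_cells], n_guides),
      high = tabulate(cell_guide[high_cells], n_guides)
    )
    counts <- apply(comp, 2, function(p)
      as.integer(rmultinom(1, params$sequencing_depth, p)))
    dimnames(counts) <- list(library$guide_id, colnames(comp))
    list(
      counts = screen_counts(counts),
      truth = data.frame(gene_id = genes, effect = unname(eff),
                         stringsAsFactors = FALSE)
    )
  })
}

#' Render a count table as synthetic FASTQ reads
#'
#' Produces, per sample, a 4-line-record FASTQ character vector whose reads
#' carry the guide sequence in their first 20 (or `guide_length`) bases,
#' padded to `read_length` with random nucleotides. Guide occurrences match
#' the count table exactly; read order is shuffled.
#'
#' @param library A `guide_library`.
#' @param counts A [screen_counts()] object (or guide x sample matrix).
#' @param read_length Total read length (>= the guide length).
#' @param seed Integer seed for suffix bases and read order.
#'
#' @return Named list (one element per sample) of FASTQ line vectors; write
#'   them with [write_fastq()].
#' @export
counts_to_fastq <- function(library, counts, read_length = 20, seed = 1) {
  library <- validate_guide_library(library)
  counts <- as_screen_counts(counts)
  glen <- if (nrow(library)) nchar(library$sequence[1]) else 20L
  read_length <- assert_count(read_length, "read_length", min = glen)
  cmat <- counts$counts
  if (!setequal(rownames(cmat), library$guide_id))
    stopf("count table guides do not match the library")
  seqs <- setNames(library$sequence, library$guide_id)
  seeded(seed, {
    out <- lapply(colnames(cmat), function(s) {
      n_reads <- sum(cmat[, s])
      if (n_reads == 0) return(character(0))
      guide_of_read <- rep(rownames(cmat), cmat[, s])
      guide_of_read <- sample(guide_of_read)
      pad <- read_length - glen
      suffix <- if (pad > 0) random_suffixes(n_reads, pad) else ""
      reads <- paste0(seqs[guide_of_read], suffix)
      ids <- sprintf("@%s_read%07d", s, seq_len(n_reads))
      qual <- strrep("I", read_length)
      as.character(rbind(ids, reads, "+", qual))
    })
    names(out) <- colnames(cmat)
    out
  })
}

random_suffixes <- function(n, len) {
  apply(matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
               nrow = n), 1, paste0, collapse = "")
}
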