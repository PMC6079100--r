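#' Read a BED file into an interval data frame
#'
#' Accepts BED3 or BED6 (tab-separated, 0-based half-open coordinates).
#' Coordinates are validated per line; `name`, `score` and `strand` are
#' preserved verbatim so that [write_bed()] round-trips byte-faithfully.
#'
#' @param path File path.
#' @return Data frame with `chrom`, `start`, `end` and, for BED6, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- unique(lengths(parts))
  if (length(nf) != 1 || !nf %in% c(3, 6))
    stopf("BED must have uniformly 3 or 6 tab-separated fields (line %d has %d)",
          which(lengths(parts) != nf[1])[1], lengths(parts)[lengths(parts) != nf[1]][1])
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stopf("invalid BED interval at line %d: %s", bad[1], lines[bad[1]])
  df <- data.frame(chrom = m[, 1], start = start, end = end,
                   stringsAsFactors = FALSE)
  if (nf == 6) {
    df$name <- m[, 4]; df$score <- m[, 5]; df$strand <- m[, 6]
  }
  df
}

#' Write an interval data frame as BED
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (and optionally
#'   `name`, `score`, `strand` for BED6).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end")
  if (all(c("name", "score", "strand") %in% names(intervals)))
    cols <- c(cols, "name", "score", "strand")
  m <- intervals[cols]
  lines <- do.call(paste, c(lapply(m, as.character), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

interval_summits <- function(intervals) {
  if ("summit" %in% names(intervals))
    intervals$start + intervals$summit
  else
    (intervals$start + intervals$end) %/% 2
}

as_iranges_halfopen <- function(intervals) {
  # 0-based half-open [start, end) -> 1-based closed IRanges
  GenomicRanges::GRanges(intervals$chrom,
                         IRanges::IRanges(intervals$start + 1L, intervals$end))
}

summit_in_regions <- function(peaks, regions) {
  if (!nrow(peaks)) return(logical(0))
  if (!nrow(regions)) return(rep(FALSE, nrow(peaks)))
  s <- interval_summits(peaks)
  pts <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(s + 1L, s + 1L))
  GenomicRanges::countOverlaps(pts, as_iranges_halfopen(regions)) > 0
}

#' Classify peak summits as promoter, enhancer, or neither
#'
#' The summit (explicit `summit` offset column if present, else the
#' floored interval midpoint) is tested for containment in the half-open
#' promoter and enhancer intervals; a summit inside both is classified as
#' promoter (promoter precedence).
#'
#' @param peaks,promoters,enhancers Interval data frames (`chrom`,
#'   `start`, `end`; peaks may carry a `summit` offset column).
#' @return Character vector over peaks: `"promoter"`, `"enhancer"` or
#'   `"neither"`.
#' @export
classify_summits <- function(peaks, promoters, enhancers) {
  in_prom <- summit_in_regions(peaks, promoters)
  in_enh <- summit_in_regions(peaks, enhancers)
  ifelse(in_prom, "promoter", ifelse(in_enh, "enhancer", "neither"))
}

#' Hypergeometric overlap enrichment test
#'
#' Upper-tail probability of observing at least `k` of `n` tested peaks in
#' the `K` regions bound by a factor, out of a universe of `N` regions:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Observed overlap count.
#' @param n Number of peaks tested.
#' @param K Number of universe regions bound by the other factor.
#' @param N Universe size.
#' @return The upper-tail p-value in (0, 1].
#' @export
overlap_enrichment_test <- function(k, n, K, N) {
  k <- assert_count(k, "k", min = 0)
  n <- assert_count(n, "n", min = 0)
  K <- assert_count(K, "K", min = 0)
  N <- assert_count(N, "N")
  if (k > min(n, K) || n > N || K > N)
    stopf("inconsistent counts: need k <= min(n, K) and n, K <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Assign peaks to genes within a TSS window
#'
#' A gene receives a peak when the absolute distance between the peak
#' summit and the gene's transcription start site is at most `window`
#' (inclusive at the boundary; strand-agnostic).
#'
#' @param peaks Interval data frame (optionally with a `summit` column).
#' @param tss Data frame with `gene_id`, `chrom`, `pos`, or a named numeric
#'   vector of positions (single-chromosome shorthand).
#' @param window Maximum distance in bp (default 50000).
#' @return Data frame `gene_id`, `peak`, `distance` (one row per
#'   assignment).
#' @export
peaks_near_tss <- function(peaks, tss, window = 50000) {
  window <- assert_count(window, "window", min = 0)
  if (!is.data.frame(tss)) {
    tss <- data.frame(gene_id = names(tss),
                      chrom = if (nrow(peaks)) peaks$chrom[1] else "chr1",
                      pos = as.numeric(tss), stringsAsFactors = FALSE)
  }
  if (!nrow(peaks) || !nrow(tss))
    return(data.frame(gene_id = character(0), peak = integer(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  s <- interval_summits(peaks)
  out <- lapply(seq_len(nrow(tss)), function(i) {
    same <- peaks$chrom == tss$chrom[i]
    d <- abs(s - tss$pos[i])
    hit <- which(same & d <= window)
    if (!length(hit)) return(NULL)
    data.frame(gene_id = tss$gene_id[i], peak = hit, distance = d[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), peak = integer(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Partition fragments by insert size
#'
#' Splits fragment records at the mononucleosome length: insert sizes
#' strictly below `cutoff` (default 146 bp) are sub-nucleosomal
#' (nucleosome-free regions); sizes at or above it are nucleosomal.
#'
#' @param fragments Data frame with `chrom`, `start`, `end` (insert size =
#'   `end - start`).
#' @param cutoff Size threshold in bp (default 146).
#' @return List with `sub_nucleosomal` and `nucleosomal` data frames.
#' @export
stratify_fragments <- function(fragments, cutoff = 146) {
  size <- fragments$end - fragments$start
  if (nrow(fragments) && any(size <= 0)) stopf("fragments must have positive insert size")
  sub <- size < cutoff
  list(sub_nucleosomal = fragments[sub, , drop = FALSE],
       nucleosomal = fragments[!sub, , drop = FALSE])
}

#' Compare per-site signal changes between bound and unbound sites
#'
#' Computes per-site deltas `B - A`, then two-sided rank-sum tests: the
#' change within bound sites (condition B vs A), the change within unbound
#' sites, and whether bound sites change more than unbound sites (rank-sum
#' on the deltas).
#'
#' @param signal_a,signal_b Per-site signal under conditions A and B
#'   (equal length).
#' @param bound Logical vector partitioning the sites (no `NA`).
#' @return List with `delta`, `p_bound`, `p_unbound`, `p_bound_vs_unbound`.
#' @export
site_signal_compare <- function(signal_a, signal_b, bound) {
  n <- length(signal_a)
  if (length(signal_b) != n || length(bound) != n || any(is.na(bound)))
    stopf("`bound` must partition all %d sites (no NA)", n)
  if (!any(bound) || all(bound))
    stopf("both bound and unbound sites are required")
  delta <- signal_b - signal_a
  list(delta = delta,
       p_bound = wilcoxon_rank_sum(signal_b[bound], signal_a[bound]),
       p_unbound = wilcoxon_rank_sum(signal_b[!bound], signal_a[!bound]),
       p_bound_vs_unbound = wilcoxon_rank_sum(delta[bound], delta[!bound]))
}

#' Venn region counts over a shared region universe
#'
#' Given the subsets of a region universe bound by two or three factors,
#' counts every Venn region; the counts sum to the size of the union.
#'
#' @param setA,setB,setC Character (or integer) vectors of region ids;
#'   `setC` optional.
#' @return Named integer vector of Venn region counts (e.g. `A_only`,
#'   `B_only`, `AB` for two sets).
#' @export
pairwise_set_counts <- function(setA, setB, setC = NULL) {
  setA <- unique(setA); setB <- unique(setB)
  if (is.null(setC)) {
    u <- union(setA, setB)
    inA <- u %in% setA; inB <- u %in% setB
    c(A_only = sum(inA & !inB), B_only = sum(!inA & inB),
      AB = sum(inA & inB))
  } else {
    setC <- unique(setC)
    u <- Reduce(union, list(setA, setB, setC))
    inA <- u %in% setA; inB <- u %in% setB; inC <- u %in% setC
    c(A_only = sum(inA & !inB & !inC),
      B_only = sum(!inA & inB & !inC),
      C_only = sum(!inA & !inB & inC),
      AB = sum(inA & inB & !inC),
      AC = sum(inA & !inB & inC),
      BC = sum(!inA & inB & inC),
      ABC = sum(inA & inB & inC))
  }
}
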