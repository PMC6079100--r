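#' Simulate region and peak interval sets with a planted overlap fraction
#'
#' Places `n_regions` disjoint regions of width `region_width` on a linear
#' genome `[0, genome_length)`, then draws `n_peaks` peaks such that
#' exactly `round(planted_overlap_fraction * n_peaks)` peak summits fall
#' inside regions and the remainder fall strictly outside — the overlap
#' count is fixed by construction, making the pair a calibration fixture
#' for [overlap_enrichment_test()].
#'
#' @param genome_length Genome size in bp.
#' @param n_regions,n_peaks Numbers of regions and peaks.
#' @param planted_overlap_fraction Fraction of peak summits planted inside
#'   regions, in `[0, 1]`.
#' @param seed Integer seed.
#' @param region_width,peak_width Interval widths in bp (defaults 1000 and
#'   300; peaks are clipped to the genome and carry a `summit` offset).
#'
#' @return A list with `regions` and `peaks` (BED-like data frames; peaks
#'   include `summit` offsets) and `truth` (logical `planted` per peak).
#' @export
simulate_interval_sets <- function(genome_length, n_regions, n_peaks,
                                   planted_overlap_fraction, seed = 1,
                                   region_width = 1000, peak_width = 300) {
  genome_length <- assert_count(genome_length, "genome_length")
  n_regions <- assert_count(n_regions, "n_regions")
  n_peaks <- assert_count(n_peaks, "n_peaks")
  f <- assert_fraction(planted_overlap_fraction, "planted_overlap_fraction")
  region_width <- assert_count(region_width, "region_width")
  covered <- n_regions * region_width
  if (covered > genome_length)
    stopf("cannot pack %d regions of %d bp into a %d bp genome",
          n_regions, region_width, genome_length)
  n_in <- round(f * n_peaks)
  if (n_in < n_peaks && covered == genome_length)
    stopf("no genome space outside regions to place non-overlapping peaks")
  seeded(seed, {
    slack <- genome_length - covered
    offsets <- sort(sample.int(slack + 1, n_regions, replace = TRUE)) - 1L
    starts <- offsets + (seq_len(n_regions) - 1L) * region_width
    regions <- data.frame(chrom = "chr1", start = starts,
                          end = starts + region_width,
                          name = sprintf("region%04d", seq_len(n_regions)),
                          score = "0", strand = ".",
                          stringsAsFactors = FALSE)
    inside_pos <- function(n) {
      reg <- sample.int(n_regions, n, replace = TRUE)
      starts[reg] + sample.int(region_width, n, replace = TRUE) - 1L
    }
    outside_pos <- function(n) {
      # gaps between/around regions, as [gap_start, gap_end)
      gs <- c(0L, starts + region_width)
      ge <- c(starts, genome_length)
      w <- ge - gs
      keep <- w > 0
      gs <- gs[keep]; w <- w[keep]
      gap <- sample.int(length(w), n, replace = TRUE, prob = w)
      gs[gap] + floor(runif(n) * w[gap])
    }
    summits <- c(if (n_in > 0) inside_pos(n_in),
                 if (n_in < n_peaks) outside_pos(n_peaks - n_in))
    planted <- seq_len(n_peaks) <= n_in
    half <- peak_width %/% 2
    pstart <- pmax(0L, as.integer(summits - half))
    pend <- pmin(genome_length, as.integer(summits + (peak_width - half)))
    peaks <- data.frame(chrom = "chr1", start = pstart, end = pend,
                        name = sprintf("peak%04d", seq_len(n_peaks)),
                        score = "0", strand = ".",
                        summit = as.integer(summits - pstart),
                        stringsAsFactors = FALSE)
    list(regions = regions, peaks = peaks,
         truth = data.frame(name = peaks$name, planted = planted,
                            stringsAsFactors = FALSE))
  })
}
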