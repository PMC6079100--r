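test_that("BED round-trips byte-faithfully and rejects bad coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr2\t0\t50"), path)
  iv <- read_bed(path)
  expect_equal(iv$start, c(100, 0))
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, out)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(out, "raw", file.size(out)))

  bed6 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t90\tpeakA\t7.5\t-", bed6)
  iv6 <- read_bed(bed6)
  expect_identical(iv6$strand, "-")
  out6 <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv6, out6)
  expect_identical(readLines(out6), "chr1\t10\t90\tpeakA\t7.5\t-")

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t200\t100"), bad)
  expect_error(read_bed(bad), "line 2")
})

test_that("summit classification uses half-open containment with promoter
           precedence", {
  regions <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  peaks <- data.frame(chrom = "chr1",
                      start = c(100, 150, 300, 140),
                      end = c(200, 250, 400, 160),
                      summit = c(50, 50, 50, 10))
  # absolute summits: 150, 200, 350, 150
  prom <- regions(100, 200)
  enh <- regions(140, 360)
  cls <- classify_summits(peaks, prom, enh)
  expect_identical(cls, c("promoter",   # 150 in [100,200) and in enhancer
                          "enhancer",   # 200 excluded from [100,200), in enh
                          "enhancer",   # 350
                          "promoter"))  # 150, both -> promoter precedence
  # midpoint default when no summit column
  mid <- data.frame(chrom = "chr1", start = 100, end = 201)
  expect_identical(classify_summits(mid, prom, regions(400, 500)), "promoter")
})

test_that("overlap enrichment equals exact combinatorial tails", {
  expect_equal(overlap_enrichment_test(4, 5, 4, 10), 6 / 252,
               tolerance = 1e-12)
  expect_equal(overlap_enrichment_test(0, 5, 4, 10), 1)
  expect_error(overlap_enrichment_test(6, 5, 4, 10), "inconsistent")
  # brute-force enumeration oracle over all draws, N <= 20
  for (case in list(c(3, 6, 5, 12), c(2, 4, 8, 16), c(5, 7, 9, 20))) {
    k <- case[1]; n <- case[2]; K <- case[3]; N <- case[4]
    expect_equal(overlap_enrichment_test(k, n, K, N),
                 brute_force_tail(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("TSS assignment windows are inclusive and strand-agnostic", {
  peaks <- data.frame(chrom = "chr1", start = c(9900, 0), end = c(10100, 200),
                      summit = c(100, 100))
  tss <- data.frame(gene_id = c("near", "edge", "far"), chrom = "chr1",
                    pos = c(55000, 60000, 60101))
  asg <- peaks_near_tss(peaks, tss, window = 50000)
  # peak 1 summit at 10,000: distances 45,000 / 50,000 / 50,101
  expect_setequal(asg$gene_id[asg$peak == 1], c("near", "edge"))
  # peak 2 summit at 100: all TSSs are > 50 kb away
  expect_false(2 %in% asg$peak)
  exact <- peaks_near_tss(data.frame(chrom = "chr1", start = 0, end = 200,
                                     summit = 100),
                          data.frame(gene_id = "g", chrom = "chr1",
                                     pos = 50100), window = 50000)
  expect_identical(exact$gene_id, "g")    # distance exactly 50,000: assigned
  past <- peaks_near_tss(data.frame(chrom = "chr1", start = 0, end = 200,
                                    summit = 100),
                         data.frame(gene_id = "g", chrom = "chr1",
                                    pos = 50101), window = 50000)
  expect_equal(nrow(past), 0)             # 50,001: not assigned
})

test_that("fragment stratification partitions at the 146-bp boundary", {
  frags <- data.frame(chrom = "chr1", start = c(0, 0, 0),
                      end = c(100, 146, 200))
  strat <- stratify_fragments(frags)
  expect_equal(strat$sub_nucleosomal$end, 100)
  expect_equal(strat$nucleosomal$end, c(146, 200))
  expect_equal(nrow(strat$sub_nucleosomal) + nrow(strat$nucleosomal),
               nrow(frags))
  empty <- stratify_fragments(frags[0, ])
  expect_equal(nrow(empty$sub_nucleosomal), 0)
  expect_equal(nrow(empty$nucleosomal), 0)
})

test_that("bound sites with a planted shift are detected and A/B swaps leave
           the comparison unchanged", {
  bound <- rep(c(TRUE, FALSE), each = 20)
  a <- withr::with_seed(4, rnorm(40))
  b <- a + ifelse(bound, 1, 0)
  res <- site_signal_compare(a, b, bound)
  expect_lt(res$p_bound_vs_unbound, 1e-6)
  swapped <- site_signal_compare(b, a, bound)
  expect_equal(swapped$delta, -res$delta)
  expect_equal(swapped$p_bound_vs_unbound, res$p_bound_vs_unbound)
  ident <- site_signal_compare(a, a, bound)
  expect_true(all(ident$delta == 0))
  expect_equal(ident$p_bound_vs_unbound, 1)
  expect_error(site_signal_compare(a, b, bound[-1]), "partition")
})

test_that("Venn region counts cover the union exactly", {
  expect_equal(pairwise_set_counts(c("r1", "r2"), c("r3")),
               c(A_only = 2L, B_only = 1L, AB = 0L))
  same <- pairwise_set_counts(c("r1", "r2"), c("r1", "r2"), c("r1", "r2"))
  expect_equal(unname(same["ABC"]), 2L)
  expect_equal(sum(same), 2L)
  three <- pairwise_set_counts(1:4, 3:6, 5:8)
  expect_equal(sum(three), 8L)
})

test_that("interval simulator plants the exact overlap fraction", {
  for (f in c(0, 0.7, 1)) {
    sim <- simulate_interval_sets(1e6, 50, 10, f, seed = 5)
    inside <- classify_summits(sim$peaks, sim$regions,
                               sim$regions[0, ]) == "promoter"
    expect_equal(sum(inside), round(f * 10))
    expect_identical(unname(inside), sim$truth$planted)
  }
  expect_error(simulate_interval_sets(1000, 5, 3, 0.5, region_width = 300),
               "pack")
})

test_that("overlap significance strengthens as the planted fraction grows", {
  pvals <- vapply(c(0.2, 0.5, 0.8), function(f) {
    sim <- simulate_interval_sets(1e6, 100, 40, f, seed = 6)
    inside <- sum(classify_summits(sim$peaks, sim$regions,
                                   sim$regions[0, ]) == "promoter")
    # universe: 1-kb tiles of the genome; regions occupy 100 of 1000 tiles
    overlap_enrichment_test(inside, 40, 100, 1000)
  }, numeric(1))
  expect_true(all(diff(pvals) < 0))
})
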