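test_that("bin tiling follows the fixed-width rule with a short last bin", {
  bm <- build_bin_map(tibble::tibble(chrom = "chr1", length = 2.5e6))
  expect_equal(nrow(bm), 3)
  expect_equal(bm$start, c(0, 1e6, 2e6))
  expect_equal(bm$end, c(1e6, 2e6, 2.5e6))

  # generic tiling invariants on an uneven multi-chromosome genome
  sizes <- tibble::tibble(chrom = c("chrA", "chrB"), length = c(7.3e6, 1e6))
  bm2 <- build_bin_map(sizes)
  for (ch in sizes$chrom) {
    b <- bm2[bm2$chrom == ch, ]
    expect_equal(nrow(b), ceiling(sizes$length[sizes$chrom == ch] / 1e6))
    expect_equal(b$start[-1], b$end[-nrow(b)]) # contiguous
    expect_true(all((b$end - b$start)[-nrow(b)] == 1e6))
  }
  expect_error(build_bin_map(sizes[0, ]), "no chromosomes")
  expect_error(build_bin_map(sizes, bin_size = 0), "positive")
})

test_that("GC fraction and N-masking are computed from sequence", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(
    ">chrGC", paste(rep("GCGCGCGCGC", 30), collapse = ""), # 300 bp all G/C
    ">chrN", paste(c(rep("N", 180), rep("A", 120)), collapse = "") # 60% N
  ), fa)
  bm <- build_bin_map(fa, bin_size = 300)
  expect_equal(bm$gc[bm$chrom == "chrGC"], 1.0)
  expect_false(bm$usable[bm$chrom == "chrN"]) # > 50% ambiguous
  expect_equal(bm$gc[bm$chrom == "chrN"], 0) # GC over the non-N part
  expect_true(all(bm$gc >= 0 & bm$gc <= 1))
})

test_that("hg19 chrom sizes give the expected autosomal bin count", {
  sizes <- hg19_chrom_sizes()
  bm <- build_bin_map(sizes, genome_build = "hg19")
  auto <- sizes[!sizes$chrom %in% c("chrX", "chrY"), ]
  # independent tally straight from the sizes table
  expected <- sum(ceiling(auto$length / 1e6))
  expect_equal(expected, 2897)
  expect_equal(sum(!bm$chrom %in% c("chrX", "chrY")), expected)
})

test_that("bin maps round-trip through BED", {
  bm <- toy_map(seed = 5)
  path <- tempfile(fileext = ".bed")
  write_bin_map(bm, path)
  back <- read_bin_map(path)
  expect_equal(back$chrom, bm$chrom)
  expect_equal(back$start, bm$start)
  expect_equal(back$gc, bm$gc, tolerance = 1e-5)
  expect_equal(back$usable, bm$usable)
})

test_that("reads land in the bin containing their leftmost base", {
  bm <- build_bin_map(tibble::tibble(chrom = "chr1", length = 3e6))
  reads <- aln_record("chr1", rep(1500000, 10))
  rc <- count_reads(reads, bm)
  expect_equal(rc$count, c(0L, 10L, 0L))
  expect_equal(attr(rc, "total_usable_reads"), 10L)
})

test_that("filter rules exclude reads and tally them by reason", {
  bm <- build_bin_map(tibble::tibble(chrom = "chr1", length = 3e6))
  reads <- dplyr::bind_rows(
    aln_record("chr1", 100, mapq = 29), # low mapq at threshold 30
    aln_record("chr1", 100, mapq = 30), # kept: boundary inclusive
    aln_record("chr1", 100, flag = 4L), # unmapped
    aln_record("chr1", 100, flag = 256L), # secondary
    aln_record("chr1", 100, flag = 2048L), # supplementary
    aln_record("chr1", 100, flag = 1024L), # duplicate
    aln_record("chrUn_gl000220", 100) # not in the bin map
  )
  rc <- count_reads(reads, bm, min_mapq = 30)
  rep <- filter_report(rc)
  expect_equal(sum(rc$count), 1L)
  expect_equal(rep$n[rep$reason == "low_mapq"], 1L)
  expect_equal(rep$n[rep$reason == "unknown_chrom"], 1L)
  expect_setequal(rep$reason, c(
    "low_mapq", "unmapped", "secondary", "supplementary", "duplicate", "unknown_chrom"
  ))
  # conservation: every input record is either counted or reported
  expect_equal(sum(rc$count) + sum(rep$n), nrow(reads))
})

test_that("counting is order-invariant and matches a brute-force tally", {
  bm <- toy_map(seed = 2, n_chroms = 1, chrom_length = 1e7) # 10 bins
  set.seed(11)
  reads <- aln_record(
    "chr1", sample.int(1e7 - 100, 10000, replace = TRUE)
  )
  rc <- count_reads(reads, bm)
  brute <- table(factor(floor((reads$pos - 1) / 1e6), levels = 0:9))
  expect_equal(rc$count, as.integer(brute))

  shuffled <- reads[sample.int(nrow(reads)), ]
  expect_equal(count_reads(shuffled, bm)$count, rc$count)
})

test_that("halving the bin size and merging bin pairs reproduces coarse counts", {
  sizes <- tibble::tibble(chrom = "chr1", length = 8e6)
  fine <- build_bin_map(sizes, bin_size = 1e6)
  coarse <- build_bin_map(sizes, bin_size = 2e6)
  set.seed(3)
  reads <- aln_record("chr1", sample.int(8e6 - 10, 5000, replace = TRUE))
  cf <- count_reads(reads, fine)$count
  cc <- count_reads(reads, coarse)$count
  merged <- cf[c(TRUE, FALSE)] + cf[c(FALSE, TRUE)]
  expect_equal(merged, cc)
})

test_that("chromosome-name dialect mismatch is an explicit error", {
  bm <- build_bin_map(tibble::tibble(chrom = "chr1", length = 3e6))
  reads <- aln_record("1", c(10, 20))
  expect_error(count_reads(reads, bm), "dialect")
  # and the error names both dialects
  expect_error(count_reads(reads, bm), "chr-prefixed")
})

test_that("count tables round-trip through TSV", {
  bm <- toy_map(seed = 7)
  prof <- simulate_profile(bm, seed = 7)
  path <- tempfile(fileext = ".tsv")
  write_counts(prof, path)
  back <- read_counts(path, bin_map = bm)
  expect_equal(back$count, prof$count)
  expect_equal(back$gc, prof$gc)
})
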