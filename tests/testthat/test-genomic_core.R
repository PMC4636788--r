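test_that("narrowPeak and bed6+pvalue peaks parse with correct coordinates and p-values", {
  np <- tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t200\tpk1\t100\t.\t5.5\t9\t7.2\t50",
               "chr2\t0\t150\tpk2\t200\t.\t3.0\t12\t10.1\t75"), np)
  pk <- read_peaks(np, "narrowPeak")
  expect_equal(start(pk), c(101, 1))   # 0-based -> 1-based
  expect_equal(end(pk), c(200, 150))
  expect_equal(mcols(pk)$pvalue, c(1e-9, 1e-12))
  expect_equal(mcols(pk)$tags, c(5.5, 3.0))

  b6 <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tpk\t0\t+\t1e-10", b6)
  pk2 <- read_peaks(b6, "bed6+pvalue")
  expect_equal(c(start(pk2) - 1, end(pk2)), c(100, 200))
  expect_equal(mcols(pk2)$pvalue, 1e-10)
})

test_that("malformed peak files are rejected with the offending line number", {
  bad <- tempfile()
  writeLines(c("chr1\t100\t200\tpk1\t0\t.\t1\t9\t1\t1",
               "chr1\t200\t100\tpk2\t0\t.\t1\t9\t1\t1"), bad)
  expect_error(read_peaks(bad, "narrowPeak"), "line 2")
  short <- tempfile()
  writeLines("chr1\t100", short)
  expect_error(read_peaks(short, "narrowPeak"), "line 1")
  expect_error(read_peaks(bad, "bogus"), "arg")
})

test_that("overlap follows the 1-bp rule with half-open adjacency", {
  a <- make_intervals("chr1", 100, 200)
  expect_true(interval_overlaps(a, make_intervals("chr1", 199, 300)))
  expect_false(interval_overlaps(a, make_intervals("chr1", 200, 300)))
  expect_false(interval_overlaps(a, make_intervals("chr2", 100, 200)))
})

test_that("distance is the gap, zero for overlap and adjacency, NA across chromosomes", {
  expect_equal(interval_distance(make_intervals("chr1", 0, 100),
                                 make_intervals("chr1", 150, 200)), 50)
  expect_equal(interval_distance(make_intervals("chr1", 0, 100),
                                 make_intervals("chr1", 50, 200)), 0)
  expect_equal(interval_distance(make_intervals("chr1", 0, 100),
                                 make_intervals("chr1", 100, 200)), 0)
  expect_true(is.na(interval_distance(make_intervals("chr1", 0, 100),
                                      make_intervals("chr2", 150, 200))))
})

test_that("overlap and distance are symmetric and consistent on random intervals", {
  set.seed(7)
  for (i in 1:200) {
    s <- sample(0:500, 2); w <- sample(1:100, 2)
    a <- make_intervals("chr1", s[1], s[1] + w[1])
    b <- make_intervals("chr1", s[2], s[2] + w[2])
    expect_identical(interval_overlaps(a, b), interval_overlaps(b, a))
    expect_identical(interval_distance(a, b), interval_distance(b, a))
    if (interval_overlaps(a, b)) expect_equal(interval_distance(a, b), 0)
  }
})

test_that("extension clips at the origin and composes additively away from it", {
  e <- extend_intervals(make_intervals("chr1", 100000, 101000), 100000)
  expect_equal(c(start(e) - 1, end(e)), c(0, 201000))
  a <- make_intervals("chr1", 50, 100)
  expect_equal(c(start(extend_intervals(a, 100)) - 1, end(extend_intervals(a, 100))),
               c(0, 200))
  expect_identical(extend_intervals(a, 0), a)
  b <- make_intervals("chr1", 5000, 6000)
  expect_identical(extend_intervals(extend_intervals(b, 300), 700),
                   extend_intervals(b, 1000))
  expect_error(extend_intervals(a, -1), "non-negative")
  clipped <- extend_intervals(make_intervals("chr1", 900, 1000), 500,
                              chrom_sizes = c(chr1 = 1200))
  expect_equal(end(clipped), 1200)
})

test_that("BED writer round-trips and sorts deterministically", {
  gr <- make_intervals(c("chr2", "chr1", "chr1"), c(10, 500, 20), c(60, 700, 90))
  path <- tempfile(fileext = ".bed")
  write_bed(gr, path)
  back <- read.table(path, sep = "\t")
  expect_equal(back$V1, c("chr1", "chr1", "chr2"))
  expect_equal(back$V2, c(20, 500, 10))
  tr <- read_tag_bed(path)
  expect_equal(length(tr$data), 3)
  empty <- tempfile(fileext = ".bed")
  write_bed(GenomicRanges::GRanges(), empty)
  expect_identical(readLines(empty), character(0))
})

test_that("signal tracks count tags and binned signal inside query regions", {
  tr <- make_track("chr1", c(10, 20, 30, 500))
  expect_equal(count_tags(tr, make_intervals("chr1", 0, 100)), 3)
  expect_equal(count_tags(tr, make_intervals("chr1", 600, 700)), 0)
  expect_equal(tr$library_size, 4)
  bins <- genomic_intervals("chr1", c(0, 100), c(100, 200))
  mcols(bins)$count <- c(5, 7)
  bt <- signal_track(bins, mode = "bins")
  expect_equal(count_tags(bt, make_intervals("chr1", 50, 150)), 12)
  expect_equal(bt$library_size, 12)
  expect_error(signal_track(bins, library_size = 3, mode = "bins"), "smaller")
})

test_that("gene annotation reader applies strand-aware TSS conventions", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tbiotype\tchrom\tstart\tend\tstrand",
               "gplus\tcoding\tchr1\t1000\t2000\t+",
               "gminus\tlncRNA\tchr1\t3000\t4000\t-"), path)
  g <- read_gene_annotation(path)
  tss <- gene_tss(g)
  expect_equal(start(tss), c(1001, 4000))  # + : start; - : end - 1 (0-based)
  expect_equal(start(tss) - 1, c(1000, 3999))
  bad <- tempfile()
  writeLines(c("gene_id\tbiotype\tchrom\tstart\tend\tstrand",
               "g1\tweird\tchr1\t0\t10\t+"), bad)
  expect_error(read_gene_annotation(bad), "biotype")
})

test_that("report percentages round halves up at the printed precision", {
  expect_equal(percent_half_up(550, 1019), 54)
  expect_equal(percent_half_up(5471, 19028), 29)
  expect_equal(percent_half_up(221, 250), 88)
  expect_equal(percent_half_up(67, 253), 26)
  expect_equal(percent_half_up(1, 8), 13)  # 12.5 rounds up
  expect_error(percent_half_up(1, 0), "positive")
})
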