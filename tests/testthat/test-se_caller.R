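test_that("p-value filter is boundary-inclusive and order-preserving", {
  pk <- make_peaks("chr1", c(0, 1000, 2000), c(500, 1500, 2500),
                   pvalue = c(1e-10, 1e-9, 1e-8))
  kept <- filter_peaks(pk, 1e-9)
  expect_equal(length(kept), 2)
  expect_equal(mcols(kept)$pvalue, c(1e-10, 1e-9))
  expect_equal(length(filter_peaks(pk, 1)), 3)
  expect_equal(length(filter_peaks(pk[0], 1e-9)), 0)
})

test_that("TSS exclusion removes peaks with any base within the window", {
  tss <- make_intervals("chr1", 1000, 1001)
  near <- make_peaks("chr1", 3000, 3100)   # closest base exactly 2000 bp away
  far <- make_peaks("chr1", 3002, 3100)    # closest base 2002 bp away
  expect_equal(length(exclude_tss_proximal(near, tss, 2000)), 0)
  expect_equal(length(exclude_tss_proximal(far, tss, 2000)), 1)
  expect_identical(exclude_tss_proximal(near, NULL, 2000), near)
})

test_that("stitching merges inclusively at the distance bound", {
  pk <- make_peaks("chr1", c(100, 10000), c(200, 10100))
  st <- stitch_peaks(pk, 12500)  # gap 9800
  expect_equal(length(st), 1)
  expect_equal(c(start(st) - 1, end(st)), c(100, 10100))
  exact <- make_peaks("chr1", c(0, 1100), c(100, 1200))  # gap exactly 1000
  expect_equal(length(stitch_peaks(exact, 1000)), 1)
  expect_equal(length(stitch_peaks(exact, 999)), 2)
  singles <- make_peaks("chr1", c(0, 20000, 40000), c(100, 20100, 40100))
  st3 <- stitch_peaks(singles, 12500)
  expect_equal(length(st3), 3)
  expect_equal(start(st3), start(sort(singles)))
})

test_that("stitching matches the union-find oracle, is idempotent and monotone", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(3:40, 1)
    df <- data.frame(chrom = paste0("chr", sample(1:2, n, replace = TRUE)),
                     start = sample(0:50000, n))
    df$end <- df$start + sample(50:2000, n, replace = TRUE)
    d <- sample(c(0, 100, 1000, 5000, 12500), 1)
    pk <- make_peaks(df$chrom, df$start, df$end)
    st <- stitch_peaks(pk, d)
    ora <- oracle_stitch(df, d)
    got <- stitched_as_df(st)
    rownames(ora) <- rownames(got) <- NULL
    expect_equal(got, ora)
    ## idempotence and conservation
    st2 <- stitch_peaks(st, d)
    expect_equal(stitched_as_df(st2)[, 1:3], got[, 1:3])
    expect_equal(sum(mcols(st)$n_constituents), n)
    expect_true(all(countOverlaps(st, st) == 1))  # pairwise non-overlapping
    ## monotone refinement: every region at distance d is inside one at 2d
    st_coarse <- stitch_peaks(pk, 2 * d + 1)
    ov <- findOverlaps(st, st_coarse, type = "within")
    expect_equal(length(unique(S4Vectors::queryHits(ov))), length(st))
  }
})

test_that("density is input-subtracted tags-per-million, clipped at zero", {
  region <- make_intervals("chr1", 0, 1000)
  t10 <- make_track("chr1", seq(0, 900, length.out = 10), library_size = 1e6)
  c4 <- make_track("chr1", seq(0, 900, length.out = 4), library_size = 1e6)
  expect_equal(compute_density(region, t10, c4), 6.0)
  t2 <- make_track("chr1", c(10, 20), library_size = 1e6)
  c10 <- make_track("chr1", seq(0, 900, length.out = 10), library_size = 1e6)
  expect_equal(compute_density(region, t2, c10), 0.0)
  t10b <- make_track("chr1", seq(0, 900, length.out = 10), library_size = 2e6)
  expect_equal(compute_density(region, t10b, NULL), 5.0)
})

test_that("inflection cutoff handles ramps, outliers, convex curves and degeneracy", {
  ramp <- seq(0, 1, length.out = 100)
  cut <- find_inflection_cutoff(ramp)
  expect_equal(cut$cutoff_rank, 100)       # slope 1 everywhere -> cutoff at top
  expect_equal(sum(ramp > cut$cutoff_density), 0)

  spike <- c(rep(1, 999), 1000)
  cut2 <- find_inflection_cutoff(spike)
  expect_equal(cut2$cutoff_density, 1)
  expect_equal(sum(spike > cut2$cutoff_density), 1)  # only the outlier is above

  n <- 1001
  x <- seq(0, 1, length.out = n)
  cut3 <- find_inflection_cutoff(x^2)      # slope-1 tangency of y = x^2 at x = 0.5
  expect_equal((cut3$cutoff_rank - 1) / (n - 1), 0.5, tolerance = 2 / n)

  expect_warning(res <- find_inflection_cutoff(rep(3, 10)), "degenerate")
  expect_true(res$degenerate)
  expect_equal(sum(rep(3, 10) > res$cutoff_density), 0)
  expect_error(find_inflection_cutoff(5), "at least 2")
})

test_that("inflection cutoff agrees with the geometric tangency oracle and is scale-invariant", {
  set.seed(11)
  for (rep in 1:120) {
    n <- sample(2:300, 1)
    d <- switch(sample(3, 1),
                sort(rlnorm(n, 1, 1)),
                sort(round(runif(n, 0, 50))),
                sort(c(rlnorm(n, 1, 0.3), rlnorm(max(1, n %/% 20), 4, 0.5))))
    if (max(d) == min(d)) d[length(d)] <- d[length(d)] + 1
    cut <- find_inflection_cutoff(d)
    expect_equal(cut$cutoff_rank, oracle_inflection(d))
    scaled <- find_inflection_cutoff(d * 17.3)
    expect_equal(scaled$cutoff_rank, cut$cutoff_rank)
    expect_equal(scaled$cutoff_density, 17.3 * cut$cutoff_density)
  }
})

test_that("the full caller recovers planted SEs exactly when the bulk is concentrated", {
  ## tight bulk: the rank curve's bulk section stays under unit slope, so the
  ## cutoff lands at the bulk ceiling and the >= 10x-separated planted
  ## clusters are exactly the SEs
  for (s in 1:3) {
    cfg <- sim_config(seed = s, n_ce = 400, n_se = 8, se_multiplier = 20,
                      ce_sdlog = 0.05, noise_sdlog = 0, background_per_kb = 0,
                      n_decoy_peaks = 20,
                      n_genes = c(coding = 100, lncRNA = 30, miRNA = 10))
    sim <- simulate_landscape(cfg)
    tss <- gene_tss(sim$genes[sim$genes$biotype == "coding"])
    rk <- call_superenhancers(sim$peaks$A, tss, sim$signal$A, control = NULL)
    planted <- truth_se_granges(sim, "A")
    called <- se_regions(rk)
    expect_equal(sum(IRanges::overlapsAny(planted, called)), length(planted))
    expect_equal(length(called), length(planted))
    ## SEs form a contiguous suffix of the ascending ranking
    lab <- mcols(rk$enhancers)$label
    expect_true(all(diff(lab == "SE") >= 0))
    expect_equal(rk$n_se + rk$n_ce, length(rk$enhancers))
  }
})

test_that("the caller is deterministic and fails informatively on emptied input", {
  cfg <- quick_config(3)
  sim <- simulate_landscape(cfg)
  tss <- gene_tss(sim$genes[sim$genes$biotype == "coding"])
  r1 <- call_superenhancers(sim$peaks$A, tss, sim$signal$A, sim$control)
  r2 <- call_superenhancers(sim$peaks$A, tss, sim$signal$A, sim$control)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  pk <- make_peaks("chr1", c(500, 1500), c(800, 1800), pvalue = 1e-12)
  tss_near <- make_intervals("chr1", 600, 601)
  tr <- make_track("chr1", c(550, 560, 1600))
  expect_error(call_superenhancers(pk, tss_near, tr), "TSS exclusion")
  weak <- make_peaks("chr1", c(0, 100), c(50, 150), pvalue = 0.5)
  expect_error(call_superenhancers(weak, NULL, tr), "p-value filter")
})

test_that("SE-set comparison counts shared union loci and pairwise overlaps", {
  a <- make_intervals("chr1", c(0, 50000), c(10000, 60000))
  ident <- compare_se_sets(list(x = a, y = a))
  expect_equal(ident$shared_all_pct, 100)
  disjoint <- compare_se_sets(list(x = make_intervals("chr1", 0, 1000),
                                   y = make_intervals("chr1", 5000, 6000)))
  expect_equal(disjoint$shared_all_pct, 0)
  expect_equal(length(disjoint$loci), 2)

  venn3 <- compare_se_sets(list(
    A = make_intervals("chr1", 0, 10000),
    B = make_intervals("chr1", 9999, 20000),
    C = GenomicRanges::GRanges()))
  expect_equal(unname(venn3$venn["A&B"]), 1)
  expect_equal(venn3$shared_all_pct, 0)
  expect_equal(venn3$shared_two_plus_pct, 100)
})

test_that("SE recovery reports the recovered fraction of a reference set", {
  ref <- make_intervals("chr1", seq(0, 9 * 50000, by = 50000),
                        seq(0, 9 * 50000, by = 50000) + 10000)
  qry <- ref[1:8]
  rec <- se_recovery(qry, ref)
  expect_equal(rec$n_recovered, 8)
  expect_equal(rec$n_reference_only, 2)
  expect_equal(rec$pct, 80)
})
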