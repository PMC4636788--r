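test_that("identical config and seed give byte-identical serialized landscapes", {
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  cfg <- quick_config(101)
  simulate_landscape(cfg, out_dir = d1)
  simulate_landscape(cfg, out_dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("serialized landscapes pass every reader and round-trip coordinates", {
  dir <- file.path(tempdir(), "sim_rt")
  cfg <- quick_config(7)
  sim <- simulate_landscape(cfg, out_dir = dir)
  expect_no_warning({
    pk <- read_peaks(file.path(dir, "A", "peaks.narrowPeak"), "narrowPeak")
    tags <- read_tag_bed(file.path(dir, "A", "tags.bed"))
    ctrl <- read_tag_bed(file.path(dir, "input_tags.bed"))
    genes <- read_gene_annotation(file.path(dir, "genes.tsv"))
    expr <- read_expression(file.path(dir, "expression.tsv"))
    ld <- read_ld_regions(file.path(dir, "ld.bed"))
    sizes <- read_chrom_sizes(file.path(dir, "chrom_sizes.tsv"))
  })
  expect_equal(length(pk), length(sim$peaks$A))
  expect_equal(start(pk), start(sim$peaks$A))
  expect_equal(length(tags$data), length(sim$signal$A$data))
  expect_equal(mcols(genes)$gene_id, mcols(sim$genes)$gene_id)
  expect_equal(mcols(genes)$tss, mcols(sim$genes)$tss)
  expect_equal(expr$gene_id, sim$expression$gene_id)
  expect_equal(length(ld), length(sim$ld))
  expect_equal(unname(sizes), unname(sim$chrom_sizes))
  unlink(dir, recursive = TRUE)
})

test_that("planted SE-to-CE tag ratio tracks the configured multiplier", {
  ratios <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = s, n_ce = 100, n_se = 5, chrom_length = 4e6,
                      n_genes = c(coding = 30, lncRNA = 10, miRNA = 5))
    sim <- simulate_landscape(cfg)
    tr <- sim$truth$loci
    members <- grepl("A", tr$module)
    mean(tr$count_A[tr$class == "SE" & members]) /
      mean(tr$count_A[tr$class == "CE"])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 20) / 20, 0.2)
})

test_that("structural guarantees of the landscape hold", {
  cfg <- quick_config(55)
  sim <- simulate_landscape(cfg)
  tr <- sim$truth$loci
  loci <- genomic_intervals(tr$chrom, tr$start, tr$end)
  ## loci are farther apart than the stitch distance, so they stay distinct
  expect_true(all(countOverlaps(loci, loci, maxgap = 12500) == 1))
  ## planted SEs keep clear of coding TSSs (exclusion window is 2 kb)
  se <- truth_se_granges(sim)
  tss <- gene_tss(sim$genes[sim$genes$biotype == "coding"])
  expect_true(all(countOverlaps(se, tss, maxgap = 2500) == 0))
  ## every planted SE has a coding gene within 100 kb
  expect_true(all(countOverlaps(extend_intervals(se, 100000), tss) >= 1))
  ## constituent peaks of every SE stitch back into exactly one region
  pk <- sim$peaks$A
  strong <- filter_peaks(pk, 1e-9)
  st <- stitch_peaks(strong, 12500)
  expect_equal(length(st), nrow(tr))
})

test_that("without a planted high-density tail the called-SE fraction stays small", {
  ## concentrated bulk, no planted clusters: the cutoff sits at the top of the
  ## bulk's largest density block and only the thin upper remnant is called
  cfg <- sim_config(seed = 77, n_ce = 400, n_se = 0, chrom_length = 8e6,
                    ce_sdlog = 0.05, noise_sdlog = 0, background_per_kb = 0,
                    n_genes = c(coding = 60, lncRNA = 20, miRNA = 10))
  sim <- simulate_landscape(cfg)
  tss <- gene_tss(sim$genes[sim$genes$biotype == "coding"])
  rk <- call_superenhancers(sim$peaks$A, tss, sim$signal$A, control = NULL)
  expect_lt(rk$n_se / length(rk$enhancers), 0.1)
  ## a literally flat landscape is degenerate and yields zero SEs
  expect_warning(flat <- find_inflection_cutoff(rep(5, 50)), "degenerate")
  expect_equal(sum(rep(5, 50) > flat$cutoff_density), 0)
})

test_that("infeasible packing and bad fractions fail before sampling", {
  tiny <- sim_config(seed = 1, n_ce = 5000, n_se = 10, chrom_length = 1e6)
  expect_error(simulate_landscape(tiny), "infeasible packing")
  expect_error(simulate_state_transition(quick_config(1), 0.7, 0.6), "sum")
  expect_error(sim_config(n_ce = 10, module_plan = c("A_only")), "module_plan")
})

test_that("state transitions plant recoverable induced loci with seed enhancers", {
  cfg <- sim_config(seed = 3, n_ce = 300, n_se = 12, se_multiplier = 10,
                    chrom_length = 8e6,
                    n_genes = c(coding = 60, lncRNA = 20, miRNA = 10))
  sim <- simulate_state_transition(cfg, induced_fraction = 0.5,
                                   repressed_fraction = 0.25)
  tr <- sim$truth$loci
  expect_equal(sum(tr$direction == "induced", na.rm = TRUE), 6)
  expect_equal(sum(tr$direction == "repressed", na.rm = TRUE), 3)
  ## induced loci are bulk-level at rest, amplified when stimulated
  ind <- tr[!is.na(tr$direction) & tr$direction == "induced", ]
  expect_true(all(ind$count_stim > 3 * ind$count_rest))
  ## pipeline: induced loci all overlap a resting enhancer call (seed origin)
  tss <- gene_tss(sim$genes[sim$genes$biotype == "coding"])
  rk_rest <- call_superenhancers(sim$peaks$rest, tss, sim$signal$rest, sim$control)
  igr <- genomic_intervals(ind$chrom, ind$start, ind$end)
  rep_ <- seed_enhancer_report(igr, rk_rest)
  expect_equal(rep_$from_seed_fraction, 1.0)
})

test_that("an all-stable transition keeps the two states' SE landscapes aligned", {
  cfg <- sim_config(seed = 9, n_ce = 300, n_se = 10, chrom_length = 8e6,
                    n_genes = c(coding = 60, lncRNA = 20, miRNA = 10))
  sim <- simulate_state_transition(cfg, induced_fraction = 0,
                                   repressed_fraction = 0)
  expect_true(all(sim$truth$loci$direction %in% c(NA, "stable")))
  tss <- gene_tss(sim$genes[sim$genes$biotype == "coding"])
  rk_rest <- call_superenhancers(sim$peaks$rest, tss, sim$signal$rest, sim$control)
  rk_stim <- call_superenhancers(sim$peaks$stim, tss, sim$signal$stim, sim$control)
  planted <- truth_se_granges(sim)
  expect_equal(sum(IRanges::overlapsAny(planted, se_regions(rk_rest))), 10)
  expect_equal(sum(IRanges::overlapsAny(planted, se_regions(rk_stim))), 10)
})
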