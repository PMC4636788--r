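## ---------------------------------------------------------------------------
## Synthetic enhancer landscapes with a ground-truth manifest.
##
## The generator emulates the statistical structure the analysis assumes:
## a heavy-tailed bulk of conventional enhancer densities with a small planted
## high-density tail (SE clusters of several constituent peaks within stitching
## distance), cell-type-specific and shared SEs across conditions, elevated
## expression of SE-proximal genes, lncRNAs transcribed from within enhancers,
## and eQTL LD blocks enriched inside SEs. Tag signal is emitted as individual
## tag placements so density computation exercises real counting.
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Defaults define the reference landscape: a 3 x 10 Mb pseudo-genome, 1,000
#' bulk (CE) sites with lognormal(log 5, 0.5) tag counts, 10 planted SE
#' clusters of 3-6 peaks over 20 kb receiving `se_multiplier` times their bulk
#' draw, three conditions with a mixed specificity-module plan, 4-fold
#' expression elevation of SE-proximal genes in member conditions, and eQTL LD
#' blocks planted in 60 % of SEs and 10 % of CEs.
#'
#' @param seed RNG seed (integer).
#' @param n_chrom,chrom_length genome shape.
#' @param n_genes named counts per biotype (coding, lncRNA, miRNA).
#' @param n_ce,n_se numbers of bulk sites and planted SE clusters.
#' @param se_peaks_per_cluster integer range (min, max) of constituents.
#' @param se_cluster_span span of an SE cluster in bp.
#' @param ce_meanlog,ce_sdlog lognormal parameters of the bulk tag counts.
#' @param se_multiplier multiple of the bulk draw received by SE clusters in
#'   member conditions (> 1).
#' @param noise_sdlog sd (log scale) of per-condition multiplicative noise on
#'   tag counts, and of expression noise.
#' @param conditions condition names.
#' @param module_plan optional character vector (length `n_se`) of module
#'   labels built from `conditions` (e.g. `"A_only"`, `"A_B"`, `"A_B_C"`);
#'   default allocates 40 % all-shared and spreads the rest over the other six
#'   classes.
#' @param expression_effect fold elevation of SE-proximal gene expression in
#'   member conditions.
#' @param eqtl_rates planting rates of LD regions inside SEs and CEs.
#' @param transcribed_rates rates at which a lncRNA TSS is planted inside an
#'   SE / CE region.
#' @param background_per_kb,control_per_kb uniform background tag rates
#'   (treatment and input control).
#' @param n_decoy_peaks weak (p > 1e-9) decoy peak calls added to each
#'   condition's peak list.
#' @param min_locus_gap,max_extra_gap spacing between planted loci: the gap is
#'   `min_locus_gap` (must exceed the stitch distance so loci stay distinct)
#'   plus a uniform extra up to `max_extra_gap`.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 3, chrom_length = 1e7,
                       n_genes = c(coding = 400, lncRNA = 150, miRNA = 60),
                       n_ce = 1000, n_se = 10,
                       se_peaks_per_cluster = c(3, 6),
                       se_cluster_span = 20000,
                       ce_meanlog = log(5), ce_sdlog = 0.5,
                       se_multiplier = 20,
                       noise_sdlog = 0.2,
                       conditions = c("A", "B", "C"),
                       module_plan = NULL,
                       expression_effect = 4,
                       eqtl_rates = c(se = 0.6, ce = 0.1),
                       transcribed_rates = c(se = 0.25, ce = 0.02),
                       background_per_kb = 0.2,
                       control_per_kb = 0.3,
                       n_decoy_peaks = 50,
                       min_locus_gap = 15000,
                       max_extra_gap = 10000) {
  stopifnot(n_chrom >= 1, chrom_length > 0, n_ce >= 0, n_se >= 0,
            se_multiplier > 1, noise_sdlog >= 0,
            all(eqtl_rates >= 0), all(eqtl_rates <= 1),
            all(transcribed_rates >= 0), all(transcribed_rates <= 1),
            expression_effect > 0, length(conditions) >= 1)
  if (!is.null(module_plan) && length(module_plan) != n_se) {
    stop("module_plan must have one label per planted SE")
  }
  structure(as.list(environment()), class = "sim_config")
}

default_module_plan <- function(n_se, conditions) {
  k <- length(conditions)
  if (k == 1) return(rep(paste0(conditions, "_only"), n_se))
  singles <- paste0(conditions, "_only")
  pairs <- if (k >= 2) {
    cmb <- utils::combn(sort(conditions), 2)
    apply(cmb, 2, paste, collapse = "_")
  } else character(0)
  all_lab <- paste(sort(conditions), collapse = "_")
  n_all <- round(0.4 * n_se)
  rest <- c(pairs, singles)
  labels <- c(rep(all_lab, n_all),
              rep(rest, length.out = n_se - n_all))
  labels[seq_len(n_se)]
}

module_members <- function(labels, conditions) {
  t(vapply(labels, function(lb) {
    members <- strsplit(sub("_only$", "", lb), "_", fixed = TRUE)[[1]]
    conditions %in% members
  }, logical(length(conditions))))
}

## Place n_loci loci (classes "CE"/"SE") on the pseudo-genome; returns a list
## of per-locus peak coordinate data.frames (0-based half-open).
place_loci <- function(cfg, classes) {
  n <- length(classes)
  margin <- 50000
  per_chrom <- ceiling(n / cfg$n_chrom)
  worst_ce <- cfg$min_locus_gap + cfg$max_extra_gap + 1500
  worst_se <- cfg$min_locus_gap + cfg$max_extra_gap + cfg$se_cluster_span
  budget_needed <- per_chrom * worst_ce +
    ceiling(cfg$n_se / cfg$n_chrom) * (worst_se - worst_ce)
  if (budget_needed > cfg$chrom_length - 2 * margin) {
    stop("infeasible packing: too many loci for the genome length")
  }
  chrom_of <- rep(seq_len(cfg$n_chrom), length.out = n)
  loci <- vector("list", n)
  pos <- rep(margin, cfg$n_chrom)
  for (i in seq_len(n)) {
    ch <- chrom_of[i]
    pos[ch] <- pos[ch] + cfg$min_locus_gap + floor(runif(1) * cfg$max_extra_gap)
    if (classes[i] == "CE") {
      w <- round(runif(1, 600, 1400))
      pk <- data.frame(start = pos[ch], end = pos[ch] + w)
      span_end <- pos[ch] + w
    } else {
      ks <- seq(cfg$se_peaks_per_cluster[1], cfg$se_peaks_per_cluster[2])
      k <- if (length(ks) == 1) ks else sample(ks, 1)
      slot <- cfg$se_cluster_span / k
      s <- pos[ch] + round((seq_len(k) - 1) * slot + runif(k, 0, 0.2 * slot))
      w <- round(runif(k, 800, 1200))
      e <- pmin(s + w, pos[ch] + cfg$se_cluster_span)
      pk <- data.frame(start = s, end = e)
      span_end <- max(e)
    }
    loci[[i]] <- list(chrom = paste0("chr", ch), peaks = pk,
                      start = min(pk$start), end = span_end,
                      class = classes[i])
    pos[ch] <- span_end
    if (pos[ch] > cfg$chrom_length - margin) {
      stop("infeasible packing: ran past the chromosome end during placement")
    }
  }
  loci
}

## Genes placed in the gap downstream of host loci; returns 0-based body
## coordinates. SE hosts get a guaranteed coding gene.
place_genes <- function(cfg, loci) {
  n_loci <- length(loci)
  se_idx <- which(vapply(loci, `[[`, "", "class") == "SE")
  ce_idx <- setdiff(seq_len(n_loci), se_idx)
  rows <- list()
  gid <- 0L
  add_gene <- function(biotype, host, inside = FALSE) {
    gid <<- gid + 1L
    lc <- loci[[host]]
    strand <- if (runif(1) < 0.5) "+" else "-"
    if (inside) {
      pk <- lc$peaks[sample(nrow(lc$peaks), 1), ]
      tss <- floor((pk$start + pk$end) / 2)
      strand <- "+"
    } else {
      tss <- lc$end + round(runif(1, 3000, 9000))
    }
    len <- if (biotype == "miRNA") round(runif(1, 80, 120)) else round(runif(1, 2000, 8000))
    if (strand == "+") {
      start <- tss; end <- tss + len
    } else {
      start <- max(0, tss - len + 1); end <- tss + 1
    }
    data.frame(gene_id = sprintf("%s%04d", switch(biotype, coding = "GENE",
                                                  lncRNA = "LNC", miRNA = "MIR"), gid),
               biotype = biotype, chrom = lc$chrom, start = start, end = end,
               strand = strand, host_locus = host, inside_host = inside,
               stringsAsFactors = FALSE)
  }
  ## one coding gene per SE, guaranteed
  for (i in se_idx) rows[[length(rows) + 1]] <- add_gene("coding", i)
  n_coding_left <- max(0, cfg$n_genes[["coding"]] - length(se_idx))
  host_pool <- if (length(ce_idx) > 0) ce_idx else seq_len(n_loci)
  hosts <- rep(host_pool, length.out = n_coding_left)
  for (h in hosts) rows[[length(rows) + 1]] <- add_gene("coding", h)
  ## lncRNAs: planted inside SEs/CEs at the transcribed rates, rest in gaps
  n_lnc <- cfg$n_genes[["lncRNA"]]
  in_se <- se_idx[runif(length(se_idx)) < cfg$transcribed_rates[["se"]]]
  in_ce <- ce_idx[runif(length(ce_idx)) < cfg$transcribed_rates[["ce"]]]
  planted <- c(in_se, in_ce)
  if (length(planted) > n_lnc) planted <- planted[seq_len(n_lnc)]
  for (h in planted) rows[[length(rows) + 1]] <- add_gene("lncRNA", h, inside = TRUE)
  hosts <- rep(sample(n_loci), length.out = max(0, n_lnc - length(planted)))
  for (h in hosts) rows[[length(rows) + 1]] <- add_gene("lncRNA", h)
  hosts <- rep(sample(n_loci), length.out = cfg$n_genes[["miRNA"]])
  for (h in hosts) rows[[length(rows) + 1]] <- add_gene("miRNA", h)
  do.call(rbind, rows)
}

uniform_background <- function(cfg, rate_per_kb) {
  n_per_chrom <- stats::rpois(cfg$n_chrom, rate_per_kb * cfg$chrom_length / 1000)
  chrom <- rep(paste0("chr", seq_len(cfg$n_chrom)), n_per_chrom)
  pos <- floor(runif(sum(n_per_chrom)) * (cfg$chrom_length - 1))
  genomic_intervals(chrom, pos, pos + 1)
}

## Core generator shared by the landscape and state-transition entry points.
## multipliers: n_loci x n_conditions matrix of density multipliers.
simulate_core <- function(cfg, conditions, classes, multipliers, module_of) {
  n_loci <- length(classes)
  loci <- place_loci(cfg, classes)
  genes_df <- place_genes(cfg, loci)

  ## bulk sites span the full lognormal; planted clusters vary half as much on
  ## the log scale, so the planted multiplier (not the base draw) carries the
  ## contrast the manifest promises
  base_count <- rlnorm(n_loci, cfg$ce_meanlog, cfg$ce_sdlog)
  se_rows <- classes == "SE"
  base_count[se_rows] <- rlnorm(sum(se_rows), cfg$ce_meanlog, cfg$ce_sdlog / 2)

  ## tag tracks per condition: planted locus tags + uniform background
  signal <- list()
  peaks <- list()
  counts <- matrix(0, n_loci, length(conditions),
                   dimnames = list(NULL, conditions))
  for (ci in seq_along(conditions)) {
    tag_chrom <- character(0); tag_pos <- numeric(0)
    for (i in seq_len(n_loci)) {
      cnt <- round(base_count[i] * multipliers[i, ci] *
                     exp(rnorm(1, 0, cfg$noise_sdlog)))
      counts[i, ci] <- cnt
      if (cnt > 0) {
        pk <- loci[[i]]$peaks
        widths <- pk$end - pk$start
        alloc <- as.vector(stats::rmultinom(1, cnt, widths / sum(widths)))
        for (j in seq_len(nrow(pk))) {
          if (alloc[j] > 0) {
            tag_chrom <- c(tag_chrom, rep(loci[[i]]$chrom, alloc[j]))
            tag_pos <- c(tag_pos, pk$start[j] + floor(runif(alloc[j]) * widths[j]))
          }
        }
      }
    }
    planted <- genomic_intervals(tag_chrom, tag_pos, tag_pos + 1)
    bg <- uniform_background(cfg, cfg$background_per_kb)
    signal[[conditions[ci]]] <- signal_track(sort_intervals(c(planted, bg)))

    ## peak calls: every planted peak interval (significant), plus weak decoys
    pk_chrom <- unlist(lapply(loci, function(l) rep(l$chrom, nrow(l$peaks))))
    pk_start <- unlist(lapply(loci, function(l) l$peaks$start))
    pk_end <- unlist(lapply(loci, function(l) l$peaks$end))
    pk_p <- 10^(-runif(length(pk_start), 9.2, 30))
    if (cfg$n_decoy_peaks > 0) {
      hosts <- sample(n_loci, cfg$n_decoy_peaks, replace = TRUE)
      d_start <- vapply(hosts, function(h) loci[[h]]$start, 0) -
        round(runif(cfg$n_decoy_peaks, 4000, 6000))
      pk_chrom <- c(pk_chrom, vapply(loci[hosts], `[[`, "", "chrom"))
      pk_start <- c(pk_start, d_start)
      pk_end <- c(pk_end, d_start + round(runif(cfg$n_decoy_peaks, 300, 600)))
      pk_p <- c(pk_p, 10^(-runif(cfg$n_decoy_peaks, 3, 8)))
    }
    gr <- genomic_intervals(pk_chrom, pk_start, pk_end)
    mcols(gr)$name <- sprintf("peak_%s_%05d", conditions[ci], seq_along(gr))
    mcols(gr)$pvalue <- pk_p
    mcols(gr)$tags <- rep(NA_real_, length(gr))
    peaks[[conditions[ci]]] <- sort_intervals(gr)
  }
  control <- signal_track(sort_intervals(uniform_background(cfg, cfg$control_per_kb)))

  ## gene annotation GRanges
  genes <- genomic_intervals(genes_df$chrom, genes_df$start, genes_df$end,
                             genes_df$strand)
  mcols(genes)$gene_id <- genes_df$gene_id
  mcols(genes)$biotype <- genes_df$biotype
  mcols(genes)$tss <- ifelse(genes_df$strand == "-", genes_df$end,
                             genes_df$start + 1)

  ## expression: SE-proximal genes elevated in member conditions
  locus_gr <- genomic_intervals(
    vapply(loci, `[[`, "", "chrom"),
    vapply(loci, function(l) l$start, 0),
    vapply(loci, function(l) l$end, 0))
  se_mask <- classes == "SE"
  se_gr <- locus_gr[se_mask]
  se_members <- multipliers[se_mask, , drop = FALSE] > 1
  near_se <- rep(NA_integer_, length(genes))
  if (length(se_gr) > 0) {
    suppressWarnings({
      hits <- GenomicRanges::distanceToNearest(gene_tss(genes), se_gr,
                                               ignore.strand = TRUE)
    })
    ok <- mcols(hits)$distance <= 100000
    near_se[queryHits(hits)[ok]] <- subjectHits(hits)[ok]
  }
  base_expr <- rlnorm(length(genes), log(10), 0.8)
  expression <- data.frame(gene_id = genes_df$gene_id, stringsAsFactors = FALSE)
  for (ci in seq_along(conditions)) {
    elevated <- if (nrow(se_members) > 0) {
      !is.na(near_se) & se_members[pmax(near_se, 1), ci]
    } else rep(FALSE, length(genes))
    eff <- ifelse(elevated, cfg$expression_effect, 1)
    expression[[conditions[ci]]] <-
      base_expr * eff * exp(rnorm(length(genes), 0, cfg$noise_sdlog))
  }

  ## eQTL LD regions planted inside loci at the class rates
  ld_rows <- list()
  has_eqtl <- rep(FALSE, n_loci)
  for (cls in c("SE", "CE")) {
    idx <- which(classes == cls)
    rate <- cfg$eqtl_rates[[tolower(if (cls == "SE") "se" else "ce")]]
    n_pick <- round(rate * length(idx))
    if (n_pick > 0) has_eqtl[idx[sample.int(length(idx), n_pick)]] <- TRUE
  }
  for (i in seq_len(n_loci)) {
    if (has_eqtl[i]) {
      w_locus <- loci[[i]]$end - loci[[i]]$start
      wld <- min(w_locus, round(runif(1, if (classes[i] == "SE") 1000 else 200,
                                      if (classes[i] == "SE") 5000 else 800)))
      s <- loci[[i]]$start + floor(runif(1) * (w_locus - wld + 1))
      ld_rows[[length(ld_rows) + 1]] <- data.frame(
        chrom = loci[[i]]$chrom, start = s, end = s + wld,
        snp_id = sprintf("rs%07d", i), stringsAsFactors = FALSE)
    }
  }
  ld <- if (length(ld_rows) > 0) {
    df <- do.call(rbind, ld_rows)
    gr <- genomic_intervals(df$chrom, df$start, df$end)
    mcols(gr)$snp_id <- df$snp_id
    mcols(gr)$r2_cutoff <- rep(0.8, length(gr))
    sort_intervals(gr)
  } else {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$snp_id <- character(0)
    mcols(gr)$r2_cutoff <- numeric(0)
    gr
  }

  truth_loci <- data.frame(
    locus_id = sprintf("locus_%04d", seq_len(n_loci)),
    chrom = vapply(loci, `[[`, "", "chrom"),
    start = vapply(loci, function(l) l$start, 0),
    end = vapply(loci, function(l) l$end, 0),
    class = classes,
    module = module_of,
    n_constituents = vapply(loci, function(l) nrow(l$peaks), 0),
    base_count = base_count,
    has_eqtl = has_eqtl,
    stringsAsFactors = FALSE)
  for (ci in seq_along(conditions)) {
    truth_loci[[paste0("count_", conditions[ci])]] <- counts[, ci]
  }
  truth_genes <- data.frame(
    gene_id = genes_df$gene_id,
    biotype = genes_df$biotype,
    host_locus = truth_loci$locus_id[genes_df$host_locus],
    inside_host = genes_df$inside_host,
    near_se = ifelse(is.na(near_se), "",
                     truth_loci$locus_id[which(se_mask)][near_se]),
    stringsAsFactors = FALSE)

  list(config = cfg,
       conditions = conditions,
       peaks = peaks,
       signal = signal,
       control = control,
       genes = genes,
       expression = expression,
       ld = ld,
       chrom_sizes = setNames(rep(cfg$chrom_length, cfg$n_chrom),
                              paste0("chr", seq_len(cfg$n_chrom))),
       truth = list(loci = truth_loci, genes = truth_genes))
}

with_sim_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Simulate a multi-condition enhancer landscape
#'
#' Generates peaks, tag signal, input control, gene annotation, expression,
#' eQTL LD regions and a ground-truth manifest under a [sim_config()].
#' Identical config and seed give identical output (byte-identical files when
#' `out_dir` is used).
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, everything is serialized in
#'   the standard formats (per-condition `peaks.narrowPeak` and `tags.bed`,
#'   `input_tags.bed`, `genes.tsv`, `expression.tsv`, `ld.bed`,
#'   `chrom_sizes.tsv`, `truth_loci.tsv`, `truth_genes.tsv`).
#' @return a list with elements `config`, `conditions`, `peaks` (named list of
#'   `GRanges`), `signal` (named list of [signal_track()]s), `control`,
#'   `genes`, `expression`, `ld`, `chrom_sizes` and `truth` (manifest
#'   data.frames `loci` and `genes`).
#' @export
simulate_landscape <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sim <- with_sim_rng(config$seed, {
    classes <- sample(c(rep("SE", config$n_se), rep("CE", config$n_ce)))
    plan <- config$module_plan %||%
      default_module_plan(config$n_se, config$conditions)
    members <- module_members(plan, config$conditions)
    multipliers <- matrix(1, length(classes), length(config$conditions))
    multipliers[classes == "SE", ] <-
      ifelse(members, config$se_multiplier, 1)
    module_of <- rep(NA_character_, length(classes))
    module_of[classes == "SE"] <- plan
    simulate_core(config, config$conditions, classes, multipliers, module_of)
  })
  if (!is.null(out_dir)) write_landscape(sim, out_dir)
  sim
}

#' Simulate a two-state (resting vs stimulated) landscape
#'
#' A fraction of the planted SE loci is induced (bulk-level density at rest,
#' `se_multiplier` times that when stimulated), a disjoint fraction repressed
#' (mirrored), and the rest stable (high in both states). Expression of genes
#' near induced SEs is elevated only in the stimulated state.
#'
#' @param config a [sim_config()]; its `conditions` are overridden by
#'   `c("rest", "stim")`.
#' @param induced_fraction,repressed_fraction fractions of SE loci (sum <= 1).
#' @param out_dir optional serialization directory, as in
#'   [simulate_landscape()].
#' @return as [simulate_landscape()], with a `direction` column
#'   (`induced`/`repressed`/`stable`) in `truth$loci`.
#' @export
simulate_state_transition <- function(config = sim_config(),
                                      induced_fraction = 0.5,
                                      repressed_fraction = 0.25,
                                      out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (induced_fraction < 0 || repressed_fraction < 0 ||
      induced_fraction + repressed_fraction > 1) {
    stop("induced and repressed fractions must be in [0, 1] and sum to <= 1")
  }
  conditions <- c("rest", "stim")
  sim <- with_sim_rng(config$seed, {
    classes <- sample(c(rep("SE", config$n_se), rep("CE", config$n_ce)))
    n_ind <- round(induced_fraction * config$n_se)
    n_rep <- round(repressed_fraction * config$n_se)
    direction <- rep("stable", config$n_se)
    direction[seq_len(n_ind)] <- "induced"
    if (n_rep > 0) direction[n_ind + seq_len(n_rep)] <- "repressed"
    direction <- sample(direction)
    multipliers <- matrix(1, length(classes), 2,
                          dimnames = list(NULL, conditions))
    se_rows <- which(classes == "SE")
    multipliers[se_rows[direction == "induced"], "stim"] <- config$se_multiplier
    multipliers[se_rows[direction == "repressed"], "rest"] <- config$se_multiplier
    multipliers[se_rows[direction == "stable"], ] <- config$se_multiplier
    module_of <- rep(NA_character_, length(classes))
    module_of[se_rows] <- direction
    out <- simulate_core(config, conditions, classes, multipliers, module_of)
    names(out$truth$loci)[names(out$truth$loci) == "module"] <- "direction"
    out
  })
  if (!is.null(out_dir)) write_landscape(sim, out_dir)
  sim
}

#' Serialize a simulated landscape in standard formats
#'
#' @param sim result of [simulate_landscape()] or
#'   [simulate_state_transition()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, `out_dir`.
#' @export
write_landscape <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in sim$conditions) {
    cdir <- file.path(out_dir, cond)
    dir.create(cdir, showWarnings = FALSE)
    pk <- sim$peaks[[cond]]
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s\t%s\t-1\t-1",
                     as.character(seqnames(pk)), start(pk) - 1, end(pk),
                     mcols(pk)$name,
                     pmin(1000L, as.integer(round(-10 * log10(mcols(pk)$pvalue)))),
                     ifelse(is.na(mcols(pk)$tags), "0",
                            sprintf("%.3f", mcols(pk)$tags)),
                     sprintf("%.4f", -log10(mcols(pk)$pvalue)))
    writeLines(lines, file.path(cdir, "peaks.narrowPeak"))
    write_bed(sim$signal[[cond]]$data, file.path(cdir, "tags.bed"))
  }
  write_bed(sim$control$data, file.path(out_dir, "input_tags.bed"))
  g <- sim$genes
  write_tsv(data.frame(gene_id = mcols(g)$gene_id, biotype = mcols(g)$biotype,
                       chrom = as.character(seqnames(g)), start = start(g) - 1,
                       end = end(g),
                       strand = as.character(GenomicRanges::strand(g)),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "genes.tsv"))
  write_tsv(sim$expression, file.path(out_dir, "expression.tsv"))
  write_bed(sim$ld, file.path(out_dir, "ld.bed"), name = "snp_id")
  writeLines(sprintf("%s\t%d", names(sim$chrom_sizes),
                     as.integer(sim$chrom_sizes)),
             file.path(out_dir, "chrom_sizes.tsv"))
  write_tsv(sim$truth$loci, file.path(out_dir, "truth_loci.tsv"))
  write_tsv(sim$truth$genes, file.path(out_dir, "truth_genes.tsv"))
  invisible(out_dir)
}

#' Simulate per-condition values with planted specificity modules
#'
#' Entities get a lognormal base level; member conditions receive `contrast`
#' times the non-member level, with multiplicative lognormal noise. Planted
#' labels cycle through all seven classes of a three-condition design.
#'
#' @param n_entities number of entities.
#' @param conditions condition names (default A, B, C).
#' @param contrast member / non-member fold contrast (default 4).
#' @param noise_sdlog sd (log scale) of the multiplicative noise
#'   (default 0.2).
#' @param base_meanlog,base_sdlog lognormal parameters of the base level.
#' @param seed RNG seed.
#' @return list with `values` (matrix entities x conditions) and `labels`
#'   (planted module labels, in [assign_module()] notation).
#' @export
simulate_module_values <- function(n_entities, conditions = c("A", "B", "C"),
                                   contrast = 4, noise_sdlog = 0.2,
                                   base_meanlog = log(20), base_sdlog = 0.5,
                                   seed = 1) {
  with_sim_rng(seed, {
    singles <- paste0(sort(conditions), "_only")
    pairs <- apply(utils::combn(sort(conditions), 2), 2, paste, collapse = "_")
    all_lab <- paste(sort(conditions), collapse = "_")
    classes <- c(singles, pairs, all_lab)
    labels <- sample(rep(classes, length.out = n_entities))
    members <- module_members(labels, conditions)
    base <- rlnorm(n_entities, base_meanlog, base_sdlog)
    noise <- matrix(exp(rnorm(n_entities * length(conditions), 0, noise_sdlog)),
                    n_entities)
    values <- base * ifelse(members, contrast, 1) * noise
    colnames(values) <- conditions
    list(values = values, labels = labels)
  })
}
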