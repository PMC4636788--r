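## Builders and independent brute-force oracles shared across the suite.
## Coordinates passed to builders are 0-based half-open (BED convention).

library(GenomicRanges)

make_intervals <- function(chrom, start, end, strand = ".") {
  genomic_intervals(chrom, start, end, strand)
}

make_peaks <- function(chrom, start, end, pvalue = 1e-12) {
  gr <- genomic_intervals(chrom, start, end)
  mcols(gr)$pvalue <- rep(pvalue, length.out = length(gr))
  gr
}

## tag track from 0-based tag positions
make_track <- function(chrom, pos, library_size = NULL) {
  signal_track(genomic_intervals(rep(chrom, length.out = length(pos)), pos, pos + 1),
               library_size = library_size)
}

make_genes <- function(chrom, start, end, strand = "+", biotype = "coding",
                       gene_id = NULL) {
  n <- length(start)
  gr <- genomic_intervals(rep(chrom, length.out = n), start, end,
                          rep(strand, length.out = n))
  mcols(gr)$gene_id <- gene_id %||% sprintf("g%03d", seq_len(n))
  mcols(gr)$biotype <- rep(biotype, length.out = n)
  mcols(gr)$tss <- ifelse(as.character(strand(gr)) == "-", end, start + 1)
  gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Oracle: unit-slope tangency by O(n^2) geometric enumeration — for each
## candidate point, draw the slope-1 line through it on the rescaled curve and
## keep the candidates whose line supports the whole curve from below; the
## cutoff is the largest such index.
oracle_inflection <- function(densities, eps = 1e-12) {
  d <- sort(densities)
  n <- length(d)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (d - d[1]) / (d[n] - d[1])
  feasible <- vapply(seq_len(n), function(i) {
    b <- y[i] - x[i]
    all(y >= x + b - eps)
  }, logical(1))
  max(which(feasible))
}

## Oracle: transitive stitching by union-find over all pairwise gaps.
## peaks: data.frame(chrom, start, end) 0-based half-open. Returns regions
## sorted by (chrom, start) as a data.frame.
oracle_stitch <- function(peaks, stitch_distance) {
  n <- nrow(peaks)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && peaks$chrom[i] == peaks$chrom[j]) {
        gap <- max(peaks$start[i] - peaks$end[j], peaks$start[j] - peaks$end[i], 0)
        if (gap <= stitch_distance) union_(i, j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(unique(comp), function(cp) {
    m <- peaks[comp == cp, , drop = FALSE]
    data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
               n_constituents = nrow(m), stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

## Oracle: classical pooled two-sample t statistic from the closed form.
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

## Oracle: Pearson X^2 from expected counts derived off the marginals.
oracle_chisq <- function(a, b, c, d) {
  obs <- matrix(c(a, c, b, d), 2)
  tot <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / tot
  sum((obs - expd)^2 / expd)
}

## data.frame view of stitched regions for oracle comparison
stitched_as_df <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1,
             end = end(gr), n_constituents = mcols(gr)$n_constituents,
             stringsAsFactors = FALSE)
}

## Small landscape config for fast end-to-end tests
quick_config <- function(seed, ...) {
  sim_config(seed = seed, n_ce = 150, n_se = 5,
             n_genes = c(coding = 60, lncRNA = 30, miRNA = 10), ...)
}

truth_se_granges <- function(sim, condition = NULL) {
  tr <- sim$truth$loci
  keep <- tr$class == "SE"
  if (!is.null(condition)) keep <- keep & grepl(condition, tr$module)
  tr <- tr[keep, , drop = FALSE]
  genomic_intervals(tr$chrom, tr$start, tr$end)
}
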