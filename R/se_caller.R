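## ---------------------------------------------------------------------------
## Super-enhancer calling: p-value filter -> TSS exclusion -> stitching ->
## input-subtracted density -> rank curve -> inflection-point cutoff.
## ---------------------------------------------------------------------------

#' Configuration for the super-enhancer caller
#'
#' Defaults follow the established ROSE-style procedure: peaks at
#' p <= 1e-9, stitching within 12,500 bp, exclusion of peaks within 2,000 bp
#' of a TSS, and a pseudocount of 1 tag-per-million in fold-change contexts.
#'
#' @param pvalue_max peak significance threshold (probability, inclusive).
#' @param stitch_distance maximum gap (bp) merged by stitching, inclusive.
#' @param tss_exclusion TSS exclusion window (bp).
#' @param pseudocount tags-per-million added in fold-change contexts.
#' @param tss_exclusion_stage whether TSS-proximal peaks are dropped before or
#'   after stitching (`"pre_stitch"` is the ROSE convention and the default).
#' @return a list of class `se_config`.
#' @export
se_config <- function(pvalue_max = 1e-9, stitch_distance = 12500,
                      tss_exclusion = 2000, pseudocount = 1,
                      tss_exclusion_stage = c("pre_stitch", "post_stitch")) {
  stopifnot(pvalue_max > 0, pvalue_max <= 1, stitch_distance > 0,
            tss_exclusion >= 0, pseudocount > 0)
  structure(list(pvalue_max = pvalue_max,
                 stitch_distance = stitch_distance,
                 tss_exclusion = tss_exclusion,
                 pseudocount = pseudocount,
                 tss_exclusion_stage = match.arg(tss_exclusion_stage)),
            class = "se_config")
}

#' Keep peaks passing a significance threshold
#'
#' @param peaks `GRanges` with a `pvalue` metadata column.
#' @param pvalue_max inclusive threshold; peaks with `pvalue <= pvalue_max`
#'   are retained in their original order.
#' @return filtered `GRanges`.
#' @export
filter_peaks <- function(peaks, pvalue_max = 1e-9) {
  p <- mcols(peaks)$pvalue
  if (is.null(p)) stop("peaks must carry a 'pvalue' metadata column")
  peaks[!is.na(p) & p <= pvalue_max]
}

#' Drop peaks near transcription start sites
#'
#' A peak is removed iff any of its bases lies within `window` bp of a TSS
#' (so a peak whose closest base is exactly `window` bp away is removed,
#' `window + 1` bp away is kept).
#'
#' @param peaks `GRanges`.
#' @param tss `GRanges` of width-1 TSS positions (see [gene_tss()]), or `NULL`
#'   for no exclusion.
#' @param window exclusion radius in bp.
#' @return filtered `GRanges`.
#' @export
exclude_tss_proximal <- function(peaks, tss, window = 2000) {
  stopifnot(window >= 0)
  if (is.null(tss) || length(tss) == 0) return(peaks)
  win <- GenomicRanges::GRanges(seqnames(tss),
                                IRanges::IRanges(pmax(1, start(tss) - window),
                                                 start(tss) + window))
  peaks[!IRanges::overlapsAny(peaks, win)]
}

#' Stitch nearby peaks into enhancer regions
#'
#' Per chromosome, peaks whose gap is at most `stitch_distance` bp are
#' transitively merged; each stitched region spans from the first to the last
#' constituent. Output is sorted by (chrom, start) and pairwise non-overlapping;
#' every peak belongs to exactly one region.
#'
#' @param peaks `GRanges`.
#' @param stitch_distance inclusive merge gap in bp.
#' @return `GRanges` of stitched regions with metadata columns
#'   `n_constituents` and `revmap` (indices of the constituent peaks, in the
#'   coordinate-sorted order of the input).
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500) {
  stopifnot(stitch_distance >= 0)
  if (length(peaks) == 0) {
    out <- GenomicRanges::GRanges()
    mcols(out)$n_constituents <- integer(0)
    return(out)
  }
  peaks <- sort_intervals(peaks)
  out <- GenomicRanges::reduce(peaks, min.gapwidth = stitch_distance + 1,
                               with.revmap = TRUE, ignore.strand = TRUE)
  out <- sort_intervals(out)
  mcols(out)$n_constituents <- lengths(mcols(out)$revmap)
  out
}

#' Input-subtracted tags-per-million density of regions
#'
#' `density = max(0, 1e6 * t / T - 1e6 * c / C)` with `t`, `c` the treatment
#' and control tag counts in the region and `T`, `C` the library sizes.
#' Without a control track, `density = 1e6 * t / T`. Densities are total (not
#' per-bp) normalized counts, as ranking works on normalized read counts.
#'
#' @param regions `GRanges`.
#' @param treatment a [signal_track()].
#' @param control optional [signal_track()] of matched input.
#' @return numeric vector of non-negative densities (tags per million).
#' @export
compute_density <- function(regions, treatment, control = NULL) {
  stopifnot(inherits(treatment, "signal_track"))
  if (treatment$library_size <= 0) stop("treatment library size must be positive")
  d <- 1e6 * count_tags(treatment, regions) / treatment$library_size
  if (!is.null(control)) {
    stopifnot(inherits(control, "signal_track"))
    if (control$library_size <= 0) stop("control library size must be positive")
    d <- d - 1e6 * count_tags(control, regions) / control$library_size
  }
  pmax(0, d)
}

#' Inflection-point cutoff of the ranked density curve
#'
#' Both rank and density are min-max rescaled to `[0, 1]`; the cutoff is the
#' point where a line of slope 1 supports the ascending curve from below (the
#' geometric "inflection point" of the hockey-stick curve), taking the largest
#' index among ties. Densities strictly above the cutoff density define
#' super-enhancers.
#'
#' @param densities numeric vector of non-negative densities (sorted
#'   internally; ranks refer to the ascending order).
#' @return list with `cutoff_rank` (index in the ascending order),
#'   `cutoff_density` (unscaled density at the cutoff), and `degenerate`
#'   (TRUE when all densities are equal, in which case no enhancer exceeds the
#'   cutoff).
#' @export
find_inflection_cutoff <- function(densities) {
  n <- length(densities)
  if (n < 2) stop("need at least 2 densities to locate an inflection point")
  if (any(!is.finite(densities)) || any(densities < 0)) {
    stop("densities must be finite and non-negative")
  }
  d <- sort(densities)
  if (d[n] == d[1]) {
    warning("all densities equal; degenerate rank curve, no super-enhancers called")
    return(list(cutoff_rank = n, cutoff_density = d[n], degenerate = TRUE))
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (d - d[1]) / (d[n] - d[1])
  resid <- y - x
  cutoff_rank <- max(which(resid <= min(resid) + 1e-12))
  list(cutoff_rank = cutoff_rank, cutoff_density = d[cutoff_rank],
       degenerate = FALSE)
}

#' Call super-enhancers from peaks and signal
#'
#' The full procedure: significance filter, TSS exclusion, stitching,
#' input-subtracted density, ascending ranking, inflection-point cutoff.
#' Regions with density strictly above the cutoff are labeled `SE`, the rest
#' `CE`.
#'
#' @param peaks `GRanges` of peak calls with a `pvalue` metadata column.
#' @param tss `GRanges` of TSS positions used for exclusion (or `NULL`).
#' @param treatment,control [signal_track()]s; `control` may be `NULL`.
#' @param config an [se_config()].
#' @param regions optional `GRanges` of pre-defined enhancer regions to rank
#'   instead of stitching (the route used when previously reported enhancer
#'   sites are re-scored).
#' @return an object of class `enhancer_ranking`: list with `enhancers`
#'   (`GRanges` sorted by ascending density with metadata `density`, `rank`,
#'   `label`, `n_constituents`), `cutoff_rank`, `cutoff_density`, `n_se`,
#'   `n_ce`, `curve` (data.frame rank/density/x/y/is_se) and `config`.
#' @export
call_superenhancers <- function(peaks, tss = NULL, treatment, control = NULL,
                                config = se_config(), regions = NULL) {
  stopifnot(inherits(config, "se_config"))
  if (is.null(regions)) {
    kept <- filter_peaks(peaks, config$pvalue_max)
    if (length(kept) == 0) stop("no peaks left after p-value filter")
    if (config$tss_exclusion_stage == "pre_stitch") {
      kept <- exclude_tss_proximal(kept, tss, config$tss_exclusion)
      if (length(kept) == 0) stop("no peaks left after TSS exclusion")
      regions <- stitch_peaks(kept, config$stitch_distance)
    } else {
      regions <- stitch_peaks(kept, config$stitch_distance)
      regions <- exclude_tss_proximal(regions, tss, config$tss_exclusion)
      if (length(regions) == 0) stop("no enhancer regions left after TSS exclusion")
    }
  } else {
    regions <- sort_intervals(regions)
    if (is.null(mcols(regions)$n_constituents)) {
      mcols(regions)$n_constituents <- rep(NA_integer_, length(regions))
    }
  }
  if (length(regions) < 2) {
    stop("fewer than 2 enhancer regions; cannot rank a density curve")
  }
  dens <- compute_density(regions, treatment, control)
  o <- order(dens, as.character(seqnames(regions)), start(regions))
  enhancers <- regions[o]
  dens <- dens[o]
  cut <- find_inflection_cutoff(dens)
  label <- ifelse(dens > cut$cutoff_density, "SE", "CE")
  mcols(enhancers)$density <- dens
  mcols(enhancers)$rank <- seq_along(enhancers)
  mcols(enhancers)$label <- label
  mcols(enhancers)$enhancer_id <- sprintf(
    "%s:%s-%s", as.character(seqnames(enhancers)),
    format(start(enhancers) - 1, scientific = FALSE, trim = TRUE),
    format(end(enhancers), scientific = FALSE, trim = TRUE))
  n <- length(dens)
  rng <- max(dens) - min(dens)
  curve <- data.frame(
    rank = seq_len(n),
    density = dens,
    x = (seq_len(n) - 1) / (n - 1),
    y = if (rng > 0) (dens - min(dens)) / rng else rep(0, n),
    is_se = label == "SE")
  structure(list(enhancers = enhancers,
                 cutoff_rank = cut$cutoff_rank,
                 cutoff_density = cut$cutoff_density,
                 n_se = sum(label == "SE"),
                 n_ce = sum(label == "CE"),
                 curve = curve,
                 config = config),
            class = "enhancer_ranking")
}

#' @export
print.enhancer_ranking <- function(x, ...) {
  cat(sprintf("enhancer_ranking: %d enhancers (%d SE, %d CE); cutoff density %.4f at rank %d\n",
              length(x$enhancers), x$n_se, x$n_ce, x$cutoff_density, x$cutoff_rank))
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.enhancer_ranking <- function(x, ...) {
  e <- x$enhancers
  data.frame(chrom = as.character(seqnames(e)),
             start = start(e) - 1, end = end(e),
             enhancer_id = mcols(e)$enhancer_id,
             n_constituents = mcols(e)$n_constituents,
             density = mcols(e)$density,
             rank = mcols(e)$rank,
             label = mcols(e)$label,
             stringsAsFactors = FALSE)
}

#' Regions of one class from a ranking (or labeled GRanges)
#'
#' @param x an `enhancer_ranking` or a `GRanges` with a `label` column.
#' @param label `"SE"` or `"CE"`.
#' @return `GRanges` sorted by coordinate.
#' @export
enhancer_regions <- function(x, label = c("SE", "CE")) {
  label <- match.arg(label)
  gr <- if (inherits(x, "enhancer_ranking")) x$enhancers else x
  if (is.null(mcols(gr)$label)) stop("no 'label' metadata column")
  sort_intervals(gr[mcols(gr)$label == label])
}

#' @rdname enhancer_regions
#' @export
se_regions <- function(x) enhancer_regions(x, "SE")

#' @rdname enhancer_regions
#' @export
ce_regions <- function(x) enhancer_regions(x, "CE")

#' Recovery of one SE set by another
#'
#' Fraction of reference SEs overlapped (>= 1 bp) by at least one query SE —
#' the "recovered" statistic of cross-mark comparisons — together with the
#' count of reference-only SEs.
#'
#' @param query,reference `GRanges` of SE regions (or `enhancer_ranking`s).
#' @return list with `n_recovered`, `n_reference`, `n_reference_only`, `pct`
#'   (integer-rounded percentage, halves up).
#' @export
se_recovery <- function(query, reference) {
  if (inherits(query, "enhancer_ranking")) query <- se_regions(query)
  if (inherits(reference, "enhancer_ranking")) reference <- se_regions(reference)
  hit <- IRanges::overlapsAny(reference, query)
  list(n_recovered = sum(hit),
       n_reference = length(reference),
       n_reference_only = sum(!hit),
       pct = percent_half_up(sum(hit), length(reference)))
}

#' Compare SE sets across conditions
#'
#' SE regions from all conditions are merged into union loci (1-bp overlap
#' chains); each locus is scored for membership in every condition by >= 1 bp
#' overlap. Reports Venn pattern counts and shared fractions over the merged
#' union loci.
#'
#' @param se_sets named list (length >= 2) of `GRanges` SE sets or
#'   `enhancer_ranking`s.
#' @return list with `loci` (merged `GRanges`), `membership` (logical matrix
#'   loci x conditions), `venn` (named counts by membership pattern),
#'   `shared_all_pct`, `shared_two_plus_pct` and `pairwise_pct` (matrix:
#'   fraction of row-condition SE loci also hit by the column condition).
#' @export
compare_se_sets <- function(se_sets) {
  if (length(se_sets) < 2) stop("need at least 2 conditions")
  if (is.null(names(se_sets)) || any(!nzchar(names(se_sets)))) {
    names(se_sets) <- paste0("cond", seq_along(se_sets))
  }
  se_sets <- lapply(se_sets, function(x) {
    if (inherits(x, "enhancer_ranking")) se_regions(x) else x
  })
  all_se <- do.call(c, unname(lapply(se_sets, function(g) {
    GenomicRanges::granges(g, use.mcols = FALSE)
  })))
  loci <- GenomicRanges::reduce(sort_intervals(all_se), ignore.strand = TRUE)
  membership <- vapply(se_sets, function(g) IRanges::overlapsAny(loci, g),
                       logical(length(loci)))
  if (length(loci) == 1) membership <- matrix(membership, nrow = 1,
                                              dimnames = list(NULL, names(se_sets)))
  pattern <- apply(membership, 1, function(r) paste(names(se_sets)[r], collapse = "&"))
  venn <- table(pattern)
  k <- ncol(membership)
  n_shared <- rowSums(membership)
  pairwise <- matrix(NA_real_, k, k, dimnames = list(names(se_sets), names(se_sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      in_i <- membership[, i]
      pairwise[i, j] <- if (sum(in_i) > 0) {
        percent_half_up(sum(in_i & membership[, j]), sum(in_i))
      } else NA_real_
    }
  }
  list(loci = loci,
       membership = membership,
       venn = venn,
       shared_all_pct = percent_half_up(sum(n_shared == k), length(loci)),
       shared_two_plus_pct = percent_half_up(sum(n_shared >= 2), length(loci)),
       pairwise_pct = pairwise)
}
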