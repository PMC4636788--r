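## ---------------------------------------------------------------------------
## Cell-type specificity across three conditions (ternary coordinates, seven
## membership modules) and cell-state dynamics (resting vs stimulated density,
## top-k induced/repressed SEs, seed-enhancer origins).
## ---------------------------------------------------------------------------

as_value_matrix <- function(values, conditions = NULL) {
  m <- as.matrix(values)
  if (!is.numeric(m)) stop("values must be numeric")
  if (is.null(dim(m)) || ncol(m) == 1) m <- matrix(m, nrow = 1)
  if (!is.null(conditions)) colnames(m) <- conditions
  if (is.null(colnames(m))) colnames(m) <- LETTERS[seq_len(ncol(m))]
  m
}

#' Ternary (relative-fraction) coordinates
#'
#' Each entity's per-condition values are divided by their sum, giving points
#' on the simplex (the coordinates of a ternary plot for three conditions).
#' Entities whose values sum to zero are flagged `undefined` and get `NA`
#' fractions; negative values are an error.
#'
#' @param values numeric matrix/data.frame (entities x conditions) or a single
#'   vector of per-condition values.
#' @param conditions optional condition names (defaults to the column names).
#' @return data.frame with one fraction column per condition plus `undefined`.
#' @export
ternary_coordinates <- function(values, conditions = NULL) {
  m <- as_value_matrix(values, conditions)
  if (any(m < 0)) stop("values must be non-negative")
  tot <- rowSums(m)
  frac <- m / ifelse(tot > 0, tot, NA_real_)
  out <- as.data.frame(frac)
  out$undefined <- tot == 0
  rownames(out) <- rownames(m)
  out
}

#' Specificity-module assignment by dominance threshold
#'
#' A condition is a member for an entity iff its value is at least
#' `dominance` times the entity's maximum value; the module label is the
#' member set (one member: `"X_only"`; several: the member names joined with
#' `"_"` in alphabetical order). With three conditions this yields exactly
#' seven classes (three unique, three pairwise, one all-shared). The rule is
#' scale-invariant. Entities with zero total signal are an error.
#'
#' @param values numeric matrix/data.frame (entities x conditions) or a vector
#'   of per-condition values.
#' @param dominance membership threshold as a fraction of the maximum
#'   (default 0.5).
#' @param conditions optional condition names.
#' @return character vector of module labels, one per entity.
#' @export
assign_module <- function(values, dominance = 0.5, conditions = NULL) {
  m <- as_value_matrix(values, conditions)
  if (any(m < 0)) stop("values must be non-negative")
  if (dominance <= 0 || dominance > 1) stop("dominance must be in (0, 1]")
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop(sprintf("entity %d has zero total signal; module undefined",
                 which(tot == 0)[1]))
  }
  mx <- apply(m, 1, max)
  members <- m >= dominance * mx
  apply(members, 1, function(r) {
    nm <- sort(colnames(m)[r])
    if (length(nm) == 1) paste0(nm, "_only") else paste(nm, collapse = "_")
  })
}

#' Merge SE/enhancer loci across conditions and recompute densities
#'
#' Regions from all conditions are merged into union loci by 1-bp overlap
#' chains; per merged locus the input-subtracted density is recomputed in
#' every condition over the identical merged interval, making densities
#' directly comparable.
#'
#' @param region_sets named list (length >= 2) of `GRanges` (e.g. SE sets or
#'   all stitched enhancers per condition) or `enhancer_ranking`s (whose full
#'   enhancer sets are used).
#' @param treatments named list of [signal_track()]s, matching
#'   `names(region_sets)`.
#' @param controls optional named list of matched input [signal_track()]s.
#' @return list with `loci` (merged `GRanges`) and `density` (matrix loci x
#'   conditions).
#' @export
match_se_loci <- function(region_sets, treatments, controls = NULL) {
  if (length(region_sets) < 2) stop("need at least 2 conditions")
  if (is.null(names(region_sets))) {
    names(region_sets) <- paste0("cond", seq_along(region_sets))
  }
  region_sets <- lapply(region_sets, function(x) {
    if (inherits(x, "enhancer_ranking")) x$enhancers else x
  })
  merged <- GenomicRanges::reduce(
    sort_intervals(do.call(c, unname(lapply(region_sets, function(g) {
      GenomicRanges::granges(g, use.mcols = FALSE)
    })))), ignore.strand = TRUE)
  dens <- vapply(names(region_sets), function(cn) {
    compute_density(merged, treatments[[cn]],
                    if (is.null(controls)) NULL else controls[[cn]])
  }, numeric(length(merged)))
  if (length(merged) == 1) {
    dens <- matrix(dens, nrow = 1, dimnames = list(NULL, names(region_sets)))
  }
  list(loci = merged, density = dens)
}

#' Rank loci by resting-to-stimulated fold change
#'
#' `log2FC = log2((density_stim + pc) / (density_rest + pc))`; loci are sorted
#' by descending fold change with deterministic coordinate tie-breaks. The
#' top-k are the induced list, the bottom-k (reversed, most repressed first)
#' the repressed list. A configurable stable band colours the scatter only and
#' does not affect the rankings. If gene annotations and an expression table
#' are supplied, each record is annotated with the genes within `flank` bp and
#' their expression fold changes.
#'
#' @param loci `GRanges` of merged loci (see [match_se_loci()]).
#' @param density_rest,density_stim numeric densities per locus
#'   (tags per million).
#' @param k size of the induced/repressed lists (default 25).
#' @param pseudocount tags-per-million pseudocount (default 1).
#' @param stable_band |log2FC| below which a locus is called stable for
#'   scatter colouring (default 0.263, about 1.2-fold).
#' @param genes optional `GRanges` of gene annotations.
#' @param expression optional expression data.frame with `rest_col`/`stim_col`
#'   columns.
#' @param rest_col,stim_col expression column names for the two states.
#' @param flank gene-annotation window in bp (default 100,000).
#' @return list with `records` (data.frame of all loci, descending log2FC),
#'   `top_induced`, `top_repressed` (data.frames of k rows each).
#' @export
rank_dynamic_ses <- function(loci, density_rest, density_stim, k = 25,
                             pseudocount = 1, stable_band = 0.263,
                             genes = NULL, expression = NULL,
                             rest_col = "rest", stim_col = "stim",
                             flank = 100000) {
  n <- length(loci)
  stopifnot(length(density_rest) == n, length(density_stim) == n,
            pseudocount > 0)
  if (k > n) stop("k exceeds the number of loci")
  lfc <- log2((density_stim + pseudocount) / (density_rest + pseudocount))
  direction <- ifelse(abs(lfc) < stable_band, "stable",
                      ifelse(lfc > 0, "induced", "repressed"))
  rec <- data.frame(
    locus_id = enhancer_ids(loci),
    chrom = as.character(seqnames(loci)),
    start = start(loci) - 1, end = end(loci),
    density_rest = density_rest, density_stim = density_stim,
    log2_fold_change = lfc, direction = direction,
    stringsAsFactors = FALSE)
  if (!is.null(genes) && !is.null(expression)) {
    hits <- GenomicRanges::findOverlaps(extend_intervals(loci, flank), genes,
                                        ignore.strand = TRUE)
    idx <- match(mcols(genes)$gene_id, expression$gene_id)
    efc <- (expression[[stim_col]][idx] + 1) / (expression[[rest_col]][idx] + 1)
    ann <- rep("", n)
    for (i in unique(queryHits(hits))) {
      g <- subjectHits(hits)[queryHits(hits) == i]
      ann[i] <- paste(sprintf("%s (%.2fx)", mcols(genes)$gene_id[g], efc[g]),
                      collapse = ", ")
    }
    rec$nearby_genes <- ann
  }
  o <- order(-rec$log2_fold_change, rec$chrom, rec$start)
  rec <- rec[o, , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec,
       top_induced = head(rec, k),
       top_repressed = tail(rec, k)[k:1, , drop = FALSE])
}

#' Classify induced SEs by their resting-state origin
#'
#' An induced SE is classed `from_low_density_enhancer` iff it overlaps (>= 1
#' bp) at least one enhancer called in the resting state ("seed" enhancer);
#' otherwise `de_novo`.
#'
#' @param induced `GRanges` of induced SE loci.
#' @param resting_enhancers `GRanges` of resting-state enhancer calls (SEs and
#'   CEs), or an `enhancer_ranking`.
#' @return list with `origin` (per-locus class), `from_seed_fraction`,
#'   `de_novo_fraction`.
#' @export
seed_enhancer_report <- function(induced, resting_enhancers) {
  if (inherits(resting_enhancers, "enhancer_ranking")) {
    resting_enhancers <- resting_enhancers$enhancers
  }
  if (length(induced) == 0) {
    return(list(origin = character(0), from_seed_fraction = NA_real_,
                de_novo_fraction = NA_real_))
  }
  hit <- IRanges::overlapsAny(induced, resting_enhancers,
                                    ignore.strand = TRUE)
  origin <- ifelse(hit, "from_low_density_enhancer", "de_novo")
  list(origin = origin,
       from_seed_fraction = mean(hit),
       de_novo_fraction = mean(!hit))
}
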