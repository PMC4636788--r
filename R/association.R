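## ---------------------------------------------------------------------------
## Assignment of genes, non-coding RNAs and eQTL LD regions to enhancers:
## the 100-kb extension / 1-bp overlap rule, "directly transcribed from"
## calls, eQTL overlap fractions and nearest-SE distances.
## ---------------------------------------------------------------------------

enhancer_ids <- function(gr) {
  ids <- mcols(gr)$enhancer_id
  if (is.null(ids)) {
    ids <- sprintf("%s:%s-%s", as.character(seqnames(gr)),
                   format(start(gr) - 1, scientific = FALSE, trim = TRUE),
                   format(end(gr), scientific = FALSE, trim = TRUE))
  }
  ids
}

element_ids <- function(gr) {
  ids <- mcols(gr)$gene_id %||% mcols(gr)$snp_id
  if (is.null(ids)) ids <- enhancer_ids(gr)
  ids
}

element_classes <- function(gr) {
  cls <- mcols(gr)$biotype
  if (is.null(cls)) {
    cls <- if (!is.null(mcols(gr)$snp_id)) rep("eQTL", length(gr))
           else rep("element", length(gr))
  }
  cls
}

#' Assign annotated elements to enhancers within a flank
#'
#' An element is linked to an enhancer iff the element's coordinates overlap
#' the enhancer extended by `flank` bp on both sides by >= 1 bp. The recorded
#' distance is the gap between the unextended enhancer and the element (0 when
#' they overlap directly).
#'
#' @param enhancers `GRanges` (an `enhancer_ranking`'s regions or any labeled
#'   set).
#' @param elements `GRanges` of genes ([read_gene_annotation()]) or LD regions
#'   ([read_ld_regions()]).
#' @param flank extension in bp (default 100,000).
#' @param anchor `"body"` compares the element's full coordinates (default);
#'   `"tss"` anchors genes at their TSS only.
#' @return data.frame with columns `enhancer_id`, `enhancer_label`,
#'   `element_id`, `element_class`, `distance`, `relation`
#'   (`direct_overlap` / `within_flank`).
#' @export
assign_elements <- function(enhancers, elements, flank = 100000,
                            anchor = c("body", "tss")) {
  anchor <- match.arg(anchor)
  if (flank < 0) stop("flank must be non-negative")
  if (inherits(enhancers, "enhancer_ranking")) enhancers <- enhancers$enhancers
  target <- if (anchor == "tss") gene_tss(elements) else elements
  ext <- extend_intervals(enhancers, flank)
  hits <- GenomicRanges::findOverlaps(ext, target, ignore.strand = TRUE)
  q <- queryHits(hits)
  s <- subjectHits(hits)
  d <- interval_distance(enhancers[q], target[s])
  labels <- mcols(enhancers)$label %||% rep(NA_character_, length(enhancers))
  out <- data.frame(
    enhancer_id = enhancer_ids(enhancers)[q],
    enhancer_label = labels[q],
    element_id = element_ids(target)[s],
    element_class = element_classes(target)[s],
    distance = d,
    relation = ifelse(d == 0, "direct_overlap", "within_flank"),
    stringsAsFactors = FALSE)
  out[order(out$enhancer_id, out$element_id), , drop = FALSE]
}

#' Transcripts directly transcribed from enhancers
#'
#' Under the default rule a transcript arises from an enhancer iff its TSS
#' lies within the (unextended) enhancer region; `"any_overlap"` instead
#' requires >= 1 bp overlap of the transcript body.
#'
#' @param ranking an `enhancer_ranking` (or `GRanges` with `label`).
#' @param transcripts `GRanges` of (typically lncRNA) annotations.
#' @param rule `"tss_within"` (default) or `"any_overlap"`.
#' @return list with `se_fraction` / `ce_fraction` (fraction of SEs / CEs with
#'   >= 1 transcript), `se_pct` / `ce_pct` (integer-rounded percentages),
#'   counts (`n_se_transcribed`, `n_se`, `n_ce_transcribed`, `n_ce`),
#'   `transcript_origin` (per-transcript: `SE`, `CE` or `none`),
#'   `from_se_fraction` / `from_ce_fraction` (fraction of transcripts arising
#'   from each class) and `degenerate` (TRUE when there are no transcripts).
#' @export
transcribed_from <- function(ranking, transcripts,
                             rule = c("tss_within", "any_overlap")) {
  rule <- match.arg(rule)
  se <- se_regions(ranking)
  ce <- ce_regions(ranking)
  n_tx <- length(transcripts)
  anchors <- if (rule == "tss_within") gene_tss(transcripts) else transcripts
  if (n_tx == 0) {
    return(list(se_fraction = 0, ce_fraction = 0,
                se_pct = 0, ce_pct = 0,
                n_se_transcribed = 0L, n_se = length(se),
                n_ce_transcribed = 0L, n_ce = length(ce),
                transcript_origin = character(0),
                from_se_fraction = 0, from_ce_fraction = 0,
                degenerate = TRUE))
  }
  se_has <- IRanges::overlapsAny(se, anchors, ignore.strand = TRUE)
  ce_has <- IRanges::overlapsAny(ce, anchors, ignore.strand = TRUE)
  in_se <- IRanges::overlapsAny(anchors, se, ignore.strand = TRUE)
  in_ce <- IRanges::overlapsAny(anchors, ce, ignore.strand = TRUE)
  origin <- ifelse(in_se, "SE", ifelse(in_ce, "CE", "none"))
  list(se_fraction = if (length(se) > 0) mean(se_has) else 0,
       ce_fraction = if (length(ce) > 0) mean(ce_has) else 0,
       se_pct = if (length(se) > 0) percent_half_up(sum(se_has), length(se), 1) else 0,
       ce_pct = if (length(ce) > 0) percent_half_up(sum(ce_has), length(ce), 1) else 0,
       n_se_transcribed = sum(se_has), n_se = length(se),
       n_ce_transcribed = sum(ce_has), n_ce = length(ce),
       transcript_origin = origin,
       from_se_fraction = mean(origin == "SE"),
       from_ce_fraction = mean(origin == "CE"),
       degenerate = FALSE)
}

#' eQTL LD-region overlap by enhancer class
#'
#' An enhancer counts as overlapping iff it shares >= 1 bp with at least one
#' LD region. Returns counts and integer-rounded percentages per class, in the
#' style "550/1019 (54 %) vs 5471/19028 (29 %)".
#'
#' @param ranking an `enhancer_ranking` or labeled `GRanges`.
#' @param ld_regions `GRanges` of LD regions.
#' @return list with `se_overlapping`, `se_total`, `ce_overlapping`,
#'   `ce_total`, `se_fraction`, `ce_fraction`, `se_pct`, `ce_pct`.
#' @export
eqtl_overlap <- function(ranking, ld_regions) {
  se <- se_regions(ranking)
  ce <- ce_regions(ranking)
  se_hit <- if (length(ld_regions) > 0) {
    IRanges::overlapsAny(se, ld_regions, ignore.strand = TRUE)
  } else rep(FALSE, length(se))
  ce_hit <- if (length(ld_regions) > 0) {
    IRanges::overlapsAny(ce, ld_regions, ignore.strand = TRUE)
  } else rep(FALSE, length(ce))
  list(se_overlapping = sum(se_hit), se_total = length(se),
       ce_overlapping = sum(ce_hit), ce_total = length(ce),
       se_fraction = if (length(se) > 0) mean(se_hit) else 0,
       ce_fraction = if (length(ce) > 0) mean(ce_hit) else 0,
       se_pct = if (length(se) > 0) percent_half_up(sum(se_hit), length(se)) else 0,
       ce_pct = if (length(ce) > 0) percent_half_up(sum(ce_hit), length(ce)) else 0)
}

#' Distance from each gene TSS to the nearest SE
#'
#' 0 when the TSS lies inside an SE; `NA` for genes on chromosomes without
#' any SE (excluded from downstream tests).
#'
#' @param genes `GRanges` of gene annotations.
#' @param se `GRanges` of SE regions (or an `enhancer_ranking`).
#' @return numeric vector of bp distances, one per gene.
#' @export
nearest_se_distance <- function(genes, se) {
  if (inherits(se, "enhancer_ranking")) se <- se_regions(se)
  tss <- gene_tss(genes)
  out <- rep(NA_real_, length(genes))
  if (length(se) == 0) return(out)
  shared <- intersect(unique(as.character(seqnames(tss))),
                      unique(as.character(seqnames(se))))
  if (length(shared) == 0) return(out)
  ok <- as.character(seqnames(tss)) %in% shared
  if (!any(ok)) return(out)
  suppressWarnings({
    hits <- GenomicRanges::distanceToNearest(tss[ok], se, ignore.strand = TRUE)
  })
  d <- rep(NA_real_, sum(ok))
  d[queryHits(hits)] <- mcols(hits)$distance
  out[ok] <- d
  out
}
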