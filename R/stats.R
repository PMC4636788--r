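## ---------------------------------------------------------------------------
## The statistical tests applied downstream: two-sample t-tests on expression
## and distances, Pearson chi-squared on overlap proportions, and the grouped
## SE-vs-CE expression comparison.
## ---------------------------------------------------------------------------

#' @importFrom stats t.test chisq.test p.adjust

test_result <- function(statistic, pvalue, df, n1, n2, method) {
  structure(list(statistic = unname(statistic), pvalue = unname(pvalue),
                 df = unname(df), n1 = n1, n2 = n2, method = method),
            class = "se_test_result")
}

#' @export
print.se_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$df, x$pvalue, x$n1, x$n2))
  invisible(x)
}

#' Two-sided two-sample t-test
#'
#' The classical Student pooled-variance test by default (matching the
#' convention "Students t-test" names); Welch's unequal-variance variant is
#' available.
#'
#' @param x,y numeric samples (each of size >= 2, finite values).
#' @param variant `"student_pooled"` (default) or `"welch"`.
#' @return an `se_test_result` (statistic, pvalue, df, n1, n2, method).
#' @export
two_sample_t <- function(x, y, variant = c("student_pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) stop("each sample needs >= 2 values")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("samples must be finite")
  if (variant == "student_pooled" && stats::var(x) == 0 && stats::var(y) == 0) {
    stop("pooled variance is zero; t statistic undefined")
  }
  ht <- t.test(x, y, var.equal = (variant == "student_pooled"),
               alternative = "two.sided")
  test_result(ht$statistic, ht$p.value, ht$parameter,
              length(x), length(y),
              if (variant == "student_pooled") "two_sample_t_pooled"
              else "two_sample_t_welch")
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Cells are `(a, b)` in row 1 and `(c, d)` in row 2; continuity correction is
#' off by default ("Pearson's Chi-squared test"), toggleable.
#'
#' @param a,b,c,d non-negative counts.
#' @param correction apply Yates continuity correction (default `FALSE`).
#' @return an `se_test_result` with df = 1; `n1`, `n2` are the row totals.
#' @export
chi_squared_2x2 <- function(a, b, c, d, correction = FALSE) {
  tab <- matrix(c(a, c, b, d), nrow = 2)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-squared undefined: a marginal total is zero")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correction))
  test_result(ht$statistic, ht$p.value, ht$parameter,
              a + b, c + d,
              if (correction) "pearson_chisq_yates" else "pearson_chisq")
}

#' Expression of genes by enhancer class
#'
#' Splits genes into three groups — within `flank` of an SE, within `flank` of
#' a CE only, and all expressed genes (expression > 0) — and compares
#' `log2(expression + 1)` between SE-genes and CE-genes, and SE-genes and all
#' expressed genes, with two-sample t-tests. A gene near both an SE and a CE
#' counts in the SE group only.
#'
#' @param expression expression data.frame ([read_expression()]).
#' @param associations association table ([assign_elements()]) whose
#'   `enhancer_label` column separates SE from CE links.
#' @param condition expression column to analyse.
#' @param variant t-test variant, see [two_sample_t()].
#' @return list with `groups` (per-group n, mean, median of log2(x+1) and raw
#'   median), `se_vs_ce`, `se_vs_all` (`se_test_result`s) and `gene_groups`
#'   (named character vector of group per gene).
#' @export
expression_by_enhancer_class <- function(expression, associations, condition,
                                         variant = "student_pooled") {
  if (!condition %in% names(expression)) {
    stop("condition column not found in expression table: ", condition)
  }
  se_genes <- unique(associations$element_id[associations$enhancer_label == "SE"])
  ce_genes <- setdiff(
    unique(associations$element_id[associations$enhancer_label == "CE"]),
    se_genes)
  expr <- setNames(expression[[condition]], expression$gene_id)
  expressed <- names(expr)[expr > 0]
  grp <- setNames(rep("other", length(expr)), names(expr))
  grp[names(expr) %in% ce_genes] <- "CE"
  grp[names(expr) %in% se_genes] <- "SE"
  take <- function(ids, label) {
    v <- expr[intersect(ids, names(expr))]
    if (length(v) == 0) stop("empty group: ", label)
    v
  }
  se_v <- take(se_genes, "SE-proximal genes")
  ce_v <- take(ce_genes, "CE-proximal genes")
  all_v <- take(expressed, "all expressed genes")
  l2 <- function(v) log2(v + 1)
  summarise <- function(v, label) {
    data.frame(group = label, n = length(v), mean_log2 = mean(l2(v)),
               median_log2 = stats::median(l2(v)), median_raw = stats::median(v),
               stringsAsFactors = FALSE)
  }
  list(groups = rbind(summarise(se_v, "SE"), summarise(ce_v, "CE"),
                      summarise(all_v, "all_expressed")),
       se_vs_ce = two_sample_t(l2(se_v), l2(ce_v), variant),
       se_vs_all = two_sample_t(l2(se_v), l2(all_v), variant),
       gene_groups = grp)
}

#' Per-module enrichment of genes near condition-unique SEs
#'
#' For each condition X, compares `log10(distance + 1)` from gene TSS to the
#' nearest X-unique SE between module-X genes and all other genes (two-sample
#' t-test). Genes without a defined distance (no X-unique SE on their
#' chromosome) are excluded; empty modules are skipped with a warning.
#'
#' @param genes `GRanges` of gene annotations.
#' @param gene_modules character vector of module labels, parallel to `genes`
#'   (labels as produced by [assign_module()]).
#' @param se `GRanges` of SE loci.
#' @param se_modules character vector of module labels, parallel to `se`.
#' @param conditions condition names (default the unique singleton prefixes).
#' @return data.frame with one row per condition: n in/out, mean log10
#'   distances, t statistic, df, p-value and BH-adjusted q-value.
#' @export
module_distance_enrichment <- function(genes, gene_modules, se, se_modules,
                                       conditions = NULL) {
  stopifnot(length(gene_modules) == length(genes),
            length(se_modules) == length(se))
  if (is.null(conditions)) {
    conditions <- sort(unique(sub("_only$", "", grep("_only$", se_modules,
                                                     value = TRUE))))
  }
  rows <- list()
  for (cond in conditions) {
    unique_se <- se[se_modules == paste0(cond, "_only")]
    in_mod <- gene_modules == paste0(cond, "_only")
    if (length(unique_se) == 0 || sum(in_mod) < 2 || sum(!in_mod) < 2) {
      warning("skipping condition with empty module: ", cond)
      next
    }
    d <- nearest_se_distance(genes, unique_se)
    ok <- !is.na(d)
    x <- log10(d[ok & in_mod] + 1)
    y <- log10(d[ok & !in_mod] + 1)
    if (length(x) < 2 || length(y) < 2) {
      warning("skipping condition with too few usable distances: ", cond)
      next
    }
    tt <- two_sample_t(x, y)
    rows[[cond]] <- data.frame(
      condition = cond, n_module = length(x), n_other = length(y),
      mean_log10_dist_module = mean(x), mean_log10_dist_other = mean(y),
      statistic = tt$statistic, df = tt$df, pvalue = tt$pvalue,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(condition = character(0), n_module = integer(0),
                      n_other = integer(0), mean_log10_dist_module = numeric(0),
                      mean_log10_dist_other = numeric(0), statistic = numeric(0),
                      df = numeric(0), pvalue = numeric(0), qvalue = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$qvalue <- p.adjust(out$pvalue, method = "BH")
  rownames(out) <- NULL
  out
}
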