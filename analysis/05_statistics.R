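#!/usr/bin/env Rscript
## The statistical layer: expression of genes by enhancer class (SE vs CE vs
## all expressed), per-module distance enrichment of genes to condition-unique
## SEs, and the printed-count report arithmetic for the published overlap
## figures.

library(secaller)

sim_dir <- "results/sim/landscape"
out_dir <- "results/stats"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

genes <- read_gene_annotation(file.path(sim_dir, "genes.tsv"))
tss <- gene_tss(genes[genes$biotype == "coding"])
control <- read_tag_bed(file.path(sim_dir, "input_tags.bed"))
expr <- read_expression(file.path(sim_dir, "expression.tsv"))

cond <- "A"
peaks <- read_peaks(file.path(sim_dir, cond, "peaks.narrowPeak"), "narrowPeak")
treat <- read_tag_bed(file.path(sim_dir, cond, "tags.bed"))
rk <- call_superenhancers(peaks, tss, treat, control)
assoc <- assign_elements(rk, genes[genes$biotype == "coding"], flank = 100000)

cat("== Expression by enhancer class (log2(x+1), pooled t) ==\n")
res <- expression_by_enhancer_class(expr, assoc, cond)
print(res$groups, row.names = FALSE)
cat(sprintf("SE-genes vs CE-genes: t = %.2f, p = %.3g\n",
            res$se_vs_ce$statistic, res$se_vs_ce$pvalue))
cat(sprintf("SE-genes vs all expressed: t = %.2f, p = %.3g\n",
            res$se_vs_all$statistic, res$se_vs_all$pvalue))
tests_df <- data.frame(
  test = c("se_vs_ce", "se_vs_all"),
  statistic = c(res$se_vs_ce$statistic, res$se_vs_all$statistic),
  df = c(res$se_vs_ce$df, res$se_vs_all$df),
  pvalue = c(res$se_vs_ce$pvalue, res$se_vs_all$pvalue))
tests_df$qvalue <- p.adjust(tests_df$pvalue, "BH")
write_tsv(tests_df, file.path(out_dir, "expression_tests.tsv"))
write_tsv(res$groups, file.path(out_dir, "expression_groups.tsv"))

cat("\n== Module distance enrichment (genes to condition-unique SEs) ==\n")
mods_se <- read.table("results/specificity/modules_se.tsv", header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
mods_gene <- read.table("results/specificity/modules_genes.tsv", header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
se_gr <- genomic_intervals(mods_se$chrom, mods_se$start, mods_se$end)
gidx <- match(mods_gene$gene_id, genes$gene_id)
enr <- module_distance_enrichment(genes[gidx], mods_gene$module,
                                  se_gr, mods_se$module,
                                  conditions = c("A", "B", "C"))
print(enr, row.names = FALSE)
write_tsv(enr, file.path(out_dir, "module_distance_enrichment.tsv"))

cat("\n== Printed-count report arithmetic ==\n")
cat(sprintf("cross-mark recovery 221/250 -> %s%%; reference-only: %d\n",
            percent_half_up(221, 250), 250 - 221))
cat(sprintf("two-state sharing 67/253 -> %s%%\n", percent_half_up(67, 253)))
cat(sprintf("eQTL overlap 550/1019 -> %s%%; 5471/19028 -> %s%%\n",
            percent_half_up(550, 1019), percent_half_up(5471, 19028)))
chi <- chi_squared_2x2(550, 469, 5471, 13557)
cat(sprintf("SE vs CE eQTL enrichment: X2 = %.1f, p %s\n", chi$statistic,
            if (chi$pvalue < 2.2e-16) "< 2.2e-16" else sprintf("= %.3g", chi$pvalue)))
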