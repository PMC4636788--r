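#!/usr/bin/env Rscript
## Assign genes, lncRNAs, miRNAs and eQTL LD regions to the called enhancers
## (100-kb extension, 1-bp overlap), compute which lncRNAs are directly
## transcribed from enhancers, and contrast eQTL overlap between SEs and CEs.

library(secaller)

sim_dir <- "results/sim/landscape"
out_dir <- "results/association"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

genes <- read_gene_annotation(file.path(sim_dir, "genes.tsv"))
tss <- gene_tss(genes[genes$biotype == "coding"])
control <- read_tag_bed(file.path(sim_dir, "input_tags.bed"))
ld <- read_ld_regions(file.path(sim_dir, "ld.bed"))

cond <- "A"
peaks <- read_peaks(file.path(sim_dir, cond, "peaks.narrowPeak"), "narrowPeak")
treat <- read_tag_bed(file.path(sim_dir, cond, "tags.bed"))
rk <- call_superenhancers(peaks, tss, treat, control)
cat(sprintf("[%s] %d enhancers (%d SE / %d CE)\n", cond,
            length(rk$enhancers), rk$n_se, rk$n_ce))

assoc <- assign_elements(rk, genes, flank = 100000)
write_tsv(assoc, file.path(out_dir, "associations.tsv"))
se_genes <- unique(assoc$element_id[assoc$enhancer_label == "SE" &
                                      assoc$element_class == "coding"])
cat(sprintf("coding genes within 100 kb of an SE: %d\n", length(se_genes)))
write_tsv(data.frame(gene_id = sort(se_genes)),
          file.path(out_dir, "se_gene_list.tsv"))

lnc <- genes[genes$biotype == "lncRNA"]
tf <- transcribed_from(rk, lnc)
cat(sprintf("lncRNAs directly transcribed from enhancers: %.1f%% of SEs vs %.1f%% of CEs\n",
            tf$se_pct, tf$ce_pct))
chi_tf <- chi_squared_2x2(tf$n_se_transcribed, tf$n_se - tf$n_se_transcribed,
                          tf$n_ce_transcribed, tf$n_ce - tf$n_ce_transcribed)
cat(sprintf("  Pearson chi-squared: X2 = %.2f, p = %.3g\n",
            chi_tf$statistic, chi_tf$pvalue))

eo <- eqtl_overlap(rk, ld)
cat(sprintf("eQTL LD overlap: %d/%d SEs (%s%%) vs %d/%d CEs (%s%%)\n",
            eo$se_overlapping, eo$se_total, eo$se_pct,
            eo$ce_overlapping, eo$ce_total, eo$ce_pct))
chi_eq <- chi_squared_2x2(eo$se_overlapping, eo$se_total - eo$se_overlapping,
                          eo$ce_overlapping, eo$ce_total - eo$ce_overlapping)
cat(sprintf("  Pearson chi-squared: X2 = %.2f, p = %.3g\n",
            chi_eq$statistic, chi_eq$pvalue))

summary_df <- data.frame(
  statistic = c("se_transcribed_pct", "ce_transcribed_pct",
                "eqtl_se_pct", "eqtl_ce_pct",
                "transcribed_chisq_p", "eqtl_chisq_p"),
  value = c(tf$se_pct, tf$ce_pct, eo$se_pct, eo$ce_pct,
            chi_tf$pvalue, chi_eq$pvalue))
write_tsv(summary_df, file.path(out_dir, "association_summary.tsv"))
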