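#!/usr/bin/env Rscript
# Translation efficiency: per-condition TE (normalized RPF over mRNA), the
# condition-by-assay interaction Wald test, TE classes, and the
# translational-buffering correlation between mRNA fold change and TE fold
# change.

source("analysis/00_config.R")
d <- load_study()

sf <- estimate_size_factors(d$cm)
disp <- estimate_dispersions(d$cm, sf)
te <- te_results(d$cm, sf, disp)
write_tsv_results(te, file.path(RESULTS_DIR, "te.tsv"))

cat(sprintf("TE classes: %d up, %d down, %d unchanged (%d excluded below mRNA floor)\n",
            sum(te$te_class == "up"), sum(te$te_class == "down"),
            sum(te$te_class == "unchanged"), sum(te$excluded)))

de <- nb_wald_test(d$cm, sf, disp, assay = "mRNA")
buf <- buffering_correlation(de, te)
cat(sprintf("translational buffering: Spearman rho = %.2f (p = %.2g, n = %d)\n",
            buf$rho, buf$pvalue, buf$n))
write_tsv_results(data.frame(rho = buf$rho, pvalue = buf$pvalue, n = buf$n),
                  file.path(RESULTS_DIR, "buffering.tsv"))

m <- merge(te, d$truth, by = "gene_id")
eff <- m$is_te & !m$excluded
cat(sprintf("TE log2FC bias on planted genes: %.3f\n",
            mean(m$te_log2fc[eff] - m$delta[eff])))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  pd <- merge(de[, c("gene_id", "log2fc")], te[, c("gene_id", "te_log2fc")],
              by = "gene_id")
  ggsave(file.path(RESULTS_DIR, "buffering.png"),
         ggplot(pd, aes(log2fc, te_log2fc)) + geom_point(alpha = 0.4) +
           geom_smooth(method = "lm", formula = y ~ x) +
           labs(x = "mRNA log2FC (auto/het)", y = "TE log2FC") + theme_bw(),
         width = 5, height = 4, dpi = 120)
}
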