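#!/usr/bin/env Rscript
# Normalization, PCA QC and differential expression: median-of-ratios size
# factors, moment dispersions with trend shrinkage, NB Wald test of
# autotrophic over heterotrophic for the mRNA and RPF assays, DEGs at the
# two-fold / adjusted-p < 0.05 criterion.

source("analysis/00_config.R")
d <- load_study()

sf <- estimate_size_factors(d$cm)
disp <- estimate_dispersions(d$cm, sf)
write_tsv_results(data.frame(sample_id = names(sf$size_factors),
                             size_factor = unname(sf$size_factors)),
                  file.path(RESULTS_DIR, "size_factors.tsv"))

pca <- pca_qc(subset_samples(d$cm, assay = "mRNA"),
              sf$size_factors[d$cm$samples$assay == "mRNA"])
cat(sprintf("PCA (mRNA): PC1 %.0f%%, PC2 %.0f%% of variance\n",
            100 * pca$var_explained[1], 100 * pca$var_explained[2]))

de <- nb_wald_test(d$cm, sf, disp, assay = "mRNA")
de_rpf <- nb_wald_test(d$cm, sf, disp, assay = "RPF")
write_tsv_results(de, file.path(RESULTS_DIR, "de_mrna.tsv"))
write_tsv_results(de_rpf, file.path(RESULTS_DIR, "de_rpf.tsv"))

cat(sprintf("mRNA DEGs: %d of %d genes (%d up, %d down), lfc range [%.1f, %.1f]\n",
            sum(de$is_deg), nrow(de),
            sum(de$is_deg & de$log2fc > 0), sum(de$is_deg & de$log2fc < 0),
            min(de$log2fc), max(de$log2fc)))

m <- merge(de, d$truth, by = "gene_id")
strong <- m$is_de & abs(m$beta) >= 1
cat(sprintf("direction recovery on strongly planted genes: %.1f%%\n",
            100 * mean(sign(m$log2fc[strong]) == sign(m$beta[strong]))))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  pd <- data.frame(pca$coords[, 1:2], pca$samples[, c("condition", "replicate")])
  ggsave(file.path(RESULTS_DIR, "pca_mrna.png"),
         ggplot(pd, aes(PC1, PC2, colour = condition)) +
           geom_point(size = 3) + theme_bw(),
         width = 5, height = 4, dpi = 120)
}
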