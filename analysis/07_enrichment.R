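#!/usr/bin/env Rscript
# Functional enrichment of DEGs: hypergeometric test per term over the
# annotated universe with BH correction, then kappa-score grouping of the
# enriched terms.

source("analysis/00_config.R")
d <- load_study()

sf <- estimate_size_factors(d$cm)
disp <- estimate_dispersions(d$cm, sf)
de <- nb_wald_test(d$cm, sf, disp, assay = "mRNA")

for (dir in c("up", "down")) {
  degs <- de$gene_id[de$is_deg & (if (dir == "up") de$log2fc > 0 else de$log2fc < 0)]
  enr <- hypergeom_enrich(degs, d$ann)
  write_tsv_results(enr, file.path(RESULTS_DIR,
                                   paste0("enrichment_", dir, ".tsv")))
  sig <- enr$term_id[enr$pvalue < 0.05]
  cat(sprintf("%s-regulated DEGs: %d genes, %d/%d terms at p < 0.05\n",
              dir, length(degs), length(sig), nrow(enr)))
  if (length(sig) >= 2) {
    km <- kappa_matrix(sig, d$ann, degs)
    cl <- kappa_cluster(km, kappa_threshold = 0.4)
    cat(sprintf("  kappa >= 0.4 grouping: %d groups over %d terms\n",
                length(unique(cl$group)), nrow(cl)))
    write_tsv_results(cl, file.path(RESULTS_DIR,
                                    paste0("kappa_groups_", dir, ".tsv")))
  }
}
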