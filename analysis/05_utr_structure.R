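#!/usr/bin/env Rscript
# 5'UTR secondary structure: extract UTRs from the genome, fold them under
# the nearest-neighbor MFE model, and compare folding free energies between
# TE-up and TE-down genes (Wilcoxon rank-sum).

source("analysis/00_config.R")
d <- load_study()

genome <- read_fasta(file.path(DATA_DIR, "genome.fasta"))
seqs <- extract_utr5(d$ann, genome)
cat("folded", length(seqs), "5'UTR sequences\n")
folds <- fold_utr5(seqs)
write_tsv_results(folds, file.path(RESULTS_DIR, "utr_folds.tsv"))

sf <- estimate_size_factors(d$cm)
disp <- estimate_dispersions(d$cm, sf)
te <- te_results(d$cm, sf, disp)

cc <- compare_classes(folds, te, classes = c("up", "down"))
cat(sprintf("median dG: TE-up %.1f kcal/mol (n=%d), TE-down %.1f kcal/mol (n=%d)\n",
            cc$medians[1], cc$n[1], cc$medians[2], cc$n[2]))
cat(sprintf("Wilcoxon rank-sum p = %.3g (%s)\n", cc$pvalue, cc$method))
write_tsv_results(
  data.frame(te_class = cc$classes, n = cc$n, median_dg = cc$medians,
             pvalue = cc$pvalue, method = cc$method),
  file.path(RESULTS_DIR, "utr_class_comparison.tsv"))
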