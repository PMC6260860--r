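#!/usr/bin/env Rscript
# Metagene footprint coverage: per-gene 5'UTR/CDS/3'UTR profiles normalized
# to the CDS mean, median profiles per condition, and a rank-sum comparison
# of 5'UTR occupancy between conditions (overall and on TE-down genes,
# where the generator plants elevated UTR occupancy under autotrophy).

source("analysis/00_config.R")
d <- load_study()

tr_h <- read_bedgraph(file.path(DATA_DIR, "coverage_het.bedgraph"))
tr_a <- read_bedgraph(file.path(DATA_DIR, "coverage_auto.bedgraph"))

ph <- metagene_profiles(tr_h, d$ann)
pa <- metagene_profiles(tr_a, d$ann)
write_tsv_results(data.frame(bin = seq_along(ph$median_profile),
                             het = ph$median_profile,
                             auto = pa$median_profile),
                  file.path(RESULTS_DIR, "metagene_profile.tsv"))

all_cmp <- aggregate_and_compare(ph, pa, "utr5")
cat(sprintf("all genes: median 5'UTR occupancy het %.2f vs auto %.2f, p = %.3g\n",
            all_cmp$medians[1], all_cmp$medians[2], all_cmp$pvalue))

down <- d$truth$gene_id[d$truth$te_class == "down"]
ph_d <- metagene_profiles(tr_h, d$ann, genes = down)
pa_d <- metagene_profiles(tr_a, d$ann, genes = down)
down_cmp <- aggregate_and_compare(ph_d, pa_d, "utr5")
cat(sprintf("TE-down genes (n=%d): median 5'UTR occupancy het %.2f vs auto %.2f, p = %.3g\n",
            length(down), down_cmp$medians[1], down_cmp$medians[2],
            down_cmp$pvalue))
write_tsv_results(
  data.frame(gene_set = c("all", "te_down"),
             median_het = c(all_cmp$medians[1], down_cmp$medians[1]),
             median_auto = c(all_cmp$medians[2], down_cmp$medians[2]),
             pvalue = c(all_cmp$pvalue, down_cmp$pvalue)),
  file.path(RESULTS_DIR, "metagene_utr5_comparison.tsv"))
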