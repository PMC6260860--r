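#!/usr/bin/env Rscript
# Reporter-assay relative translation efficiency: the promoter-5'UTR lacZ
# constructs assayed by qPCR (mRNA fold change) and beta-galactosidase
# activity (protein fold change) between autotrophic and heterotrophic
# growth.  Relative TE = protein FC / mRNA FC, two decimals.

source("analysis/00_config.R")

measurements <- data.frame(
  construct_id = c("ELIM_c1647", "ELIM_c1650", "ELIM_c1491"),
  mrna_fc = c(1.01, 20.91, 2.75),
  protein_fc = c(0.62, 0.99, 3.90))

res <- reporter_relative_te(measurements)
print(res)
write_tsv_results(res, file.path(RESULTS_DIR, "reporter_te.tsv"))
cat("relative TE well below 1 marks translational repression through the",
    "construct's 5'UTR;\nvalues near or above 1 mark neutral or enhanced",
    "translation.\n")
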