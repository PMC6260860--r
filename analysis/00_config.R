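# Shared settings for the analysis scripts.  The simulated study mirrors the
# profiled experiment: two growth conditions (heterotrophic glucose vs
# autotrophic H2/CO2), biological duplicates, paired mRNA and RPF libraries,
# ~30% of genes transcriptionally responsive, a smaller fraction with a
# translation-efficiency effect negatively coupled to the mRNA response
# (buffering), operon pairs with 1:1 subunit stoichiometry, and structured
# 5'UTRs on TE-down genes.

library(riboTE)

ANALYSIS_SEED <- 20181123L %% 10000L   # small fixed seed
DATA_DIR <- "results/data"
RESULTS_DIR <- "results"

study_config <- function(seed = ANALYSIS_SEED) {
  sim_config(
    n_genes = 600,
    n_replicates = 2,
    seed = seed,
    frac_de = 0.3,          # ~30% of genes transcriptionally responsive
    lfc_condition_sd = 2,
    frac_te = 0.15,
    lfc_te_sd = 1.5,
    buffering_rho = -0.5,
    n_operons = 30,
    dispersion = c(0.01, 0.5),
    library_size_factors = c(1, 1.15, 0.9, 1.1, 0.95, 1.2, 0.85, 1.05))
}

need_data <- function() {
  if (!file.exists(file.path(DATA_DIR, "counts.tsv")))
    stop("run analysis/01_simulate.R first")
}

load_study <- function() {
  need_data()
  list(
    ann = read_annotation(file.path(DATA_DIR, "annotation.gff3")),
    cm = read_counts(file.path(DATA_DIR, "counts.tsv"),
                     file.path(DATA_DIR, "samples.tsv")),
    truth = read.delim(file.path(DATA_DIR, "truth.tsv")))
}
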