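#' Pipeline configuration
#'
#' Collects input paths (or a simulation config), thresholds, seed and
#' stage toggles for [run_pipeline].  The configuration serializes to a
#' stable hash recorded in every output table and in the run manifest.
#'
#' @param out_dir output directory (created if absent).
#' @param sim optional [sim_config]; when given, inputs are simulated into
#'   `out_dir/inputs` and used directly.
#' @param annotation,counts,metadata,genome,coverage_het,coverage_auto,terms
#'   input file paths (GFF3, counts TSV, metadata TSV, FASTA, bedGraph x2,
#'   gene-term TSV); ignored when `sim` is given.
#' @param stages stages to run, subset of
#'   `c("de", "te", "stoich", "utr", "metagene", "enrich")`.
#' @param lfc_threshold,alpha_threshold DEG/TE-class thresholds (two-fold,
#'   adjusted p 0.05).
#' @param kappa_threshold kappa grouping threshold (0.4).
#' @param mrna_floor minimum mean normalized mRNA for TE.
#' @param ratio_tol equimolar tolerance for complex ratios.
#' @param seed integer seed for any stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = NULL,
                            annotation = NULL, counts = NULL, metadata = NULL,
                            genome = NULL, coverage_het = NULL,
                            coverage_auto = NULL, terms = NULL,
                            stages = c("de", "te", "stoich", "utr",
                                       "metagene", "enrich"),
                            lfc_threshold = 1, alpha_threshold = 0.05,
                            kappa_threshold = 0.4, mrna_floor = 1,
                            ratio_tol = 1.5, seed = 1) {
  stopifnot(all(stages %in% c("de", "te", "stoich", "utr", "metagene",
                              "enrich")),
            lfc_threshold >= 0, alpha_threshold > 0, alpha_threshold <= 1,
            kappa_threshold >= -1, kappa_threshold <= 1, ratio_tol >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Stable hash of a pipeline configuration
#'
#' @param config a `pipeline_config`.
#' @return Character hash (independent of `out_dir`).
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  x$sim <- if (!is.null(x$sim)) unclass(x$sim)
  rlang::hash(x)
}

#' Write a synthetic dataset to disk
#'
#' Generates annotation, counts + metadata, genome FASTA and per-condition
#' coverage bedGraphs (plus the truth table) from a [sim_config], through
#' the package's own writers.
#'
#' @param sim a [sim_config].
#' @param dir output directory.
#' @return Named list of the file paths written, plus the in-memory
#'   objects (`annotation_obj`, `counts_obj`, `truth_obj`, `utr`).
#' @export
simulate_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(sim)
  cnt <- simulate_counts(sim, ann)
  utr <- simulate_utr_sequences(sim, ann, cnt$truth)
  cov_h <- simulate_coverage(sim, ann, cnt$truth, "heterotrophic")
  cov_a <- simulate_coverage(sim, ann, cnt$truth, "autotrophic")
  paths <- list(
    annotation = file.path(dir, "annotation.gff3"),
    counts = file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "samples.tsv"),
    genome = file.path(dir, "genome.fasta"),
    coverage_het = file.path(dir, "coverage_het.bedgraph"),
    coverage_auto = file.path(dir, "coverage_auto.bedgraph"),
    truth = file.path(dir, "truth.tsv"))
  write_annotation(ann, paths$annotation)
  write_counts(cnt$counts, paths$counts, paths$metadata)
  write_fasta(utr$genome, paths$genome)
  write_bedgraph(cov_h, paths$coverage_het)
  write_bedgraph(cov_a, paths$coverage_auto)
  write.table(cnt$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  c(paths, list(annotation_obj = ann, counts_obj = cnt$counts,
                truth_obj = cnt$truth, utr = utr))
}

#' Run the integrated RNA-Seq + Ribo-Seq pipeline
#'
#' Stages run in dependency order (normalization always; then the enabled
#' stages), each writing a TSV under `out_dir` stamped with the pipeline
#' version and configuration hash.  A `manifest.yaml` records versions,
#' hash, seed and output checksums; a rerun with the same configuration and
#' inputs is bit-identical for the deterministic stages (all of them — the
#' seed only enters through simulated inputs).
#'
#' @param config a [pipeline_config].
#' @return Invisible list of stage results (and input objects).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)

  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    inp <- simulate_dataset(sim, file.path(out, "inputs"))
  } else {
    needed <- c("annotation", "counts", "metadata")
    if ("utr" %in% config$stages) needed <- c(needed, "genome")
    if ("metagene" %in% config$stages)
      needed <- c(needed, "coverage_het", "coverage_auto")
    for (f in needed) {
      if (is.null(config[[f]]))
        stop("stage inputs missing: ", f, " is required")
      if (!file.exists(config[[f]]))
        stop("stage inputs missing: no such file: ", config[[f]])
    }
    inp <- config
  }

  ann <- if (!is.null(inp$annotation_obj)) inp$annotation_obj else
    read_annotation(inp$annotation)
  cm <- if (!is.null(inp$counts_obj)) inp$counts_obj else
    read_counts(inp$counts, inp$metadata)

  res <- list(annotation = ann, counts = cm)
  sf <- estimate_size_factors(cm)
  disp <- estimate_dispersions(cm, sf)
  res$size_factors <- sf
  res$dispersions <- disp
  emit <- function(tab, name) write_tsv_results(tab, file.path(out, name), hash)
  emit(data.frame(sample_id = names(sf$size_factors),
                  size_factor = unname(sf$size_factors)), "size_factors.tsv")

  if ("de" %in% config$stages) {
    res$de <- nb_wald_test(cm, sf, disp, assay = "mRNA",
                           lfc_threshold = config$lfc_threshold,
                           alpha_threshold = config$alpha_threshold)
    res$de_rpf <- nb_wald_test(cm, sf, disp, assay = "RPF",
                               lfc_threshold = config$lfc_threshold,
                               alpha_threshold = config$alpha_threshold)
    emit(res$de, "de_mrna.tsv"); emit(res$de_rpf, "de_rpf.tsv")
    pca <- pca_qc(subset_samples(cm, assay = "mRNA"),
                  sf$size_factors[cm$samples$assay == "mRNA"])
    emit(data.frame(sample_id = rownames(pca$coords),
                    pc1 = pca$coords[, 1], pc2 = pca$coords[, 2],
                    var1 = pca$var_explained[1], var2 = pca$var_explained[2]),
         "pca_mrna.tsv")
    res$pca <- pca
  }
  if ("te" %in% config$stages) {
    res$te <- te_results(cm, sf, disp, mrna_floor = config$mrna_floor,
                         lfc_threshold = config$lfc_threshold,
                         alpha_threshold = config$alpha_threshold)
    emit(res$te, "te.tsv")
    if (!is.null(res$de)) {
      res$buffering <- buffering_correlation(res$de, res$te)
      emit(data.frame(rho = res$buffering$rho, pvalue = res$buffering$pvalue,
                      n = res$buffering$n), "buffering.tsv")
    }
  }
  if ("stoich" %in% config$stages) {
    res$pairs <- operon_pair_stats(ann, cm, sf)
    emit(res$pairs, "operon_pairs.tsv")
    cors <- lapply(c("heterotrophic", "autotrophic"), function(cond)
      tryCatch(pair_correlation(res$pairs, cond), error = function(e) NULL))
    keep <- !vapply(cors, is.null, TRUE)
    if (any(keep))
      emit(data.frame(condition = c("heterotrophic", "autotrophic")[keep],
                      r = vapply(cors[keep], `[[`, 1.0, "r"),
                      n_pairs = vapply(cors[keep], `[[`, 1L, "n_pairs")),
           "pair_correlation.tsv")
    res$pair_cor <- cors
  }
  if ("utr" %in% config$stages) {
    genome <- if (!is.null(inp$utr)) inp$utr$genome else read_fasta(inp$genome)
    seqs <- extract_utr5(ann, genome)
    res$folds <- fold_utr5(seqs)
    emit(res$folds, "utr_folds.tsv")
    if (!is.null(res$te)) {
      cc <- tryCatch(compare_classes(res$folds, res$te), error = function(e) NULL)
      if (!is.null(cc)) {
        emit(data.frame(class = cc$classes, n = cc$n, median_dg = cc$medians,
                        pvalue = cc$pvalue), "utr_class_comparison.tsv")
        res$utr_comparison <- cc
      }
    }
  }
  if ("metagene" %in% config$stages) {
    tr_h <- if (!is.null(inp$coverage_het) && is.character(inp$coverage_het))
      read_bedgraph(inp$coverage_het) else inp$coverage_het
    tr_a <- if (!is.null(inp$coverage_auto) && is.character(inp$coverage_auto))
      read_bedgraph(inp$coverage_auto) else inp$coverage_auto
    res$metagene_het <- metagene_profiles(tr_h, ann)
    res$metagene_auto <- metagene_profiles(tr_a, ann)
    res$metagene_utr5 <- aggregate_and_compare(res$metagene_het,
                                               res$metagene_auto, "utr5")
    emit(data.frame(bin = seq_along(res$metagene_het$median_profile),
                    het = res$metagene_het$median_profile,
                    auto = res$metagene_auto$median_profile),
         "metagene_profile.tsv")
    emit(data.frame(region = "utr5",
                    median_het = res$metagene_utr5$medians[1],
                    median_auto = res$metagene_utr5$medians[2],
                    pvalue = res$metagene_utr5$pvalue), "metagene_utr5.tsv")
  }
  if ("enrich" %in% config$stages) {
    g2t <- if (!is.null(config$terms) && is.null(config$sim))
      read.delim(config$terms, stringsAsFactors = FALSE) else ann
    if (is.null(res$de))
      res$de <- nb_wald_test(cm, sf, disp, assay = "mRNA")
    degs <- res$de$gene_id[res$de$is_deg]
    if (length(degs) >= 3) {
      res$enrich <- hypergeom_enrich(degs, g2t)
      emit(res$enrich, "enrichment.tsv")
      sig <- res$enrich$term_id[res$enrich$padj < config$alpha_threshold]
      if (length(sig) >= 2) {
        km <- kappa_matrix(sig, g2t, degs)
        res$kappa_groups <- kappa_cluster(km, config$kappa_threshold)
        emit(res$kappa_groups, "kappa_groups.tsv")
      }
    }
  }

  manifest <- list(
    pipeline = "riboTE", version = pipeline_version(),
    config_hash = hash, seed = config$seed,
    stages = as.list(config$stages),
    outputs = as.list(vapply(
      sort(setdiff(list.files(out), c("inputs", "manifest.yaml"))),
      function(f) unname(tools::md5sum(file.path(out, f))), "")))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(res)
}
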