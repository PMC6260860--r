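#' Simulation configuration
#'
#' Collects every parameter of the synthetic-data generator.  Defaults mirror
#' the design of a two-condition (heterotrophic vs autotrophic) bacterial
#' experiment profiled in biological duplicate with both RNA-Seq (mRNA) and
#' Ribo-Seq (RPF) libraries: negative-binomial counts with per-gene
#' dispersion, a condition effect on a fraction of genes, an assay-by-
#' condition interaction (the translation-efficiency effect) on another
#' fraction, negative correlation between the two effect sizes
#' (translational buffering), operon-structured gene pairs with 1:1 subunit
#' stoichiometry, 5'UTRs whose folding stability tracks the TE class, and
#' ribosome footprint coverage enriched in the 5'UTR of TE-down genes under
#' autotrophy.
#'
#' @param n_genes number of genes.
#' @param n_replicates biological replicates per condition/assay (>= 2).
#' @param seed integer seed; each generator operation derives its own stream
#'   from it, so stages are individually reproducible.
#' @param base_mean_log_range range of log2 base means `q_g` (counts scale).
#' @param dispersion range of per-gene NB dispersions `alpha`
#'   (`var = mu + alpha mu^2`); a single value is used for all genes.
#' @param frac_de fraction of genes with a condition (mRNA) effect.
#' @param lfc_condition_sd SD of the condition log2 fold changes.
#' @param frac_te fraction of genes with a TE (condition x assay) effect.
#' @param lfc_te_sd SD of the TE log2 fold changes.
#' @param lfc_assay_sd SD of the assay (RPF vs mRNA) baseline offsets.
#' @param buffering_rho target correlation between condition and TE log2
#'   fold changes (negative = translational buffering).
#' @param n_operons number of adjacent 1:1-stoichiometry gene pairs;
#'   `NULL` means `min(30, n_genes %/% 4)`.
#' @param utr5_length_range range of 5'UTR lengths (nt).
#' @param utr3_length 3'UTR length (nt), fixed.
#' @param hairpin_stem_range range of planted hairpin stem lengths (bp) for
#'   TE-down genes; stems are drawn from the upper half of the range.
#' @param library_size_factors per-sample positive scale factors, recycled
#'   over samples; `NULL` means all 1.
#' @param n_terms number of functional-term ids to scatter over genes.
#' @param coverage_scale expected CDS coverage per unit of RPF mean
#'   (reads/base).
#' @param utr5_cov_base baseline 5'UTR/CDS coverage ratio `u`.
#' @param utr5_cov_tedown elevated `u` for TE-down genes under autotrophy.
#' @param utr3_cov 3'UTR/CDS coverage ratio.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 400, n_replicates = 2, seed = 1,
                       base_mean_log_range = c(3, 10),
                       dispersion = c(0.01, 0.5),
                       frac_de = 0.3, lfc_condition_sd = 2,
                       frac_te = 0.15, lfc_te_sd = 1.5,
                       lfc_assay_sd = 0.5,
                       buffering_rho = -0.5,
                       n_operons = NULL,
                       utr5_length_range = c(20L, 150L),
                       utr3_length = 30L,
                       hairpin_stem_range = c(4L, 10L),
                       library_size_factors = NULL,
                       n_terms = 40,
                       coverage_scale = 0.02,
                       utr5_cov_base = 0.2,
                       utr5_cov_tedown = 0.6,
                       utr3_cov = 0.1) {
  cfg <- as.list(environment())
  if (is.null(cfg$n_operons)) cfg$n_operons <- min(30L, cfg$n_genes %/% 4L)
  stopifnot(cfg$n_genes >= 1, cfg$frac_de >= 0, cfg$frac_de <= 1,
            cfg$frac_te >= 0, cfg$frac_te <= 1,
            all(cfg$dispersion > 0),
            cfg$buffering_rho >= -1, cfg$buffering_rho <= 1,
            cfg$n_operons * 2 <= cfg$n_genes)
  if (cfg$n_replicates < 2)
    stop("n_replicates must be >= 2: dispersion estimation needs replication")
  if (!is.null(cfg$library_size_factors) && any(cfg$library_size_factors <= 0))
    stop("library size factors must be positive")
  class(cfg) <- "sim_config"
  cfg
}

# sample() that treats length-1 x as a one-element population
resample <- function(x, size = 1, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# run expr under a dedicated RNG stream derived from (seed, tag), restoring
# the caller's RNG state afterwards
with_op_seed <- function(seed, tag, expr) {
  offsets <- c(counts = 101L, annotation = 211L, utr = 307L, coverage = 401L,
               genome = 503L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((as.integer(seed) + offsets[[tag]]) %% .Machine$integer.max)
  expr
}

#' Simulate a gene annotation
#'
#' Genes are laid out on one contig with 5'UTR lengths drawn from
#' `utr5_length_range`, CDS lengths of 300-1500 nt, and a fixed 3'UTR.  The
#' first `2 * n_operons` genes form disjoint adjacent operon pairs (subunit
#' indices 1 and 2) on the + strand; the rest get random strands.  Each gene
#' receives 1-3 functional-term ids.
#'
#' @param config a [sim_config].
#' @return A [gene_annotation].
#' @export
simulate_annotation <- function(config) {
  with_op_seed(config$seed, "annotation", {
    n <- config$n_genes
    in_operon <- seq_len(n) <= 2L * config$n_operons
    strand <- ifelse(in_operon, "+", sample(c("+", "-"), n, replace = TRUE))
    l5 <- resample(config$utr5_length_range[1]:config$utr5_length_range[2],
                   n, replace = TRUE)
    lcds <- sample(seq(300L, 1500L, by = 3L), n, replace = TRUE)
    gap <- sample(50:200, n, replace = TRUE)
    tx_len <- l5 + lcds + config$utr3_length
    tx_start <- cumsum(c(100L, head(tx_len + gap, -1L)))
    tss <- cds_start <- cds_end <- integer(n)
    for (k in seq_len(n)) {
      if (strand[k] == "+") {
        tss[k] <- tx_start[k]
        cds_start[k] <- tss[k] + l5[k]
        cds_end[k] <- cds_start[k] + lcds[k]
      } else {
        tx_end <- tx_start[k] + tx_len[k]
        tss[k] <- tx_end - 1L
        cds_end[k] <- tss[k] + 1L - l5[k]
        cds_start[k] <- cds_end[k] - lcds[k]
      }
    }
    operon_id <- rep(NA_character_, n)
    subunit <- rep(NA_integer_, n)
    if (config$n_operons > 0) {
      idx <- seq_len(2L * config$n_operons)
      operon_id[idx] <- rep(sprintf("op%03d", seq_len(config$n_operons)), each = 2)
      subunit[idx] <- rep(1:2, config$n_operons)
    }
    terms <- lapply(seq_len(n), function(i)
      sort(sample(sprintf("T%03d", seq_len(config$n_terms)),
                  sample(1:3, 1))))
    gene_annotation(
      gene_id = sprintf("g%04d", seq_len(n)), contig = "chr",
      strand = strand, cds_start = cds_start, cds_end = cds_end,
      tss = tss, utr3_length = config$utr3_length,
      operon_id = operon_id, subunit_index = subunit, terms = terms)
  })
}

#' Simulate paired mRNA/RPF count data
#'
#' Counts follow `NB(mean = q_g * sf_s * 2^(x_cond beta_g + x_assay gamma_g
#' + x_cond x_assay delta_g), dispersion alpha_g)` with `x_cond = 1` for
#' autotrophic samples and `x_assay = 1` for RPF libraries, so the true
#' mRNA condition log2FC is `beta_g` and the true TE log2FC is `delta_g`.
#' Every gene draws a latent bivariate-normal `(beta, delta)` pair with
#' correlation `buffering_rho`; DE/TE indicator masks select which genes
#' actually carry each effect.  Genes in the same operon share their
#' expression parameters (1:1 subunit stoichiometry).
#'
#' @param config a [sim_config].
#' @param annotation optional [gene_annotation] supplying gene ids and operon
#'   structure; when `NULL` a plain gene list is used.
#' @return A list with elements `counts` (a [count_matrix]) and `truth`
#'   (data.frame of per-gene generative parameters and flags).
#' @export
simulate_counts <- function(config, annotation = NULL) {
  with_op_seed(config$seed, "counts", {
    n <- config$n_genes
    ids <- if (!is.null(annotation)) annotation$gene_id else
      sprintf("g%04d", seq_len(n))
    stopifnot(length(ids) == n)

    q <- 2^runif(n, config$base_mean_log_range[1], config$base_mean_log_range[2])
    alpha <- if (length(config$dispersion) == 1) rep(config$dispersion, n) else
      runif(n, config$dispersion[1], config$dispersion[2])
    # latent correlated (beta, delta)
    rho <- config$buffering_rho
    z1 <- rnorm(n); z2 <- rnorm(n)
    beta_lat <- config$lfc_condition_sd * z1
    delta_lat <- config$lfc_te_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    is_de <- runif(n) < config$frac_de
    is_te <- runif(n) < config$frac_te
    beta <- beta_lat * is_de
    delta <- delta_lat * is_te
    gamma <- rnorm(n, 0, config$lfc_assay_sd)

    # operon pairs share parameters (subunit stoichiometry 1:1)
    if (!is.null(annotation)) {
      op <- annotation$operon_id
      for (o in unique(op[!is.na(op)])) {
        m <- which(op == o)
        q[m] <- q[m[1]]; alpha[m] <- alpha[m[1]]; beta[m] <- beta[m[1]]
        delta[m] <- delta[m[1]]; gamma[m] <- gamma[m[1]]
        is_de[m] <- is_de[m[1]]; is_te[m] <- is_te[m[1]]
      }
    }

    conds <- c("heterotrophic", "autotrophic")
    assays <- c("mRNA", "RPF")
    samples <- expand.grid(replicate = seq_len(config$n_replicates),
                           assay = assays, condition = conds,
                           stringsAsFactors = FALSE)
    samples <- order_samples(samples)
    samples$sample_id <- paste(substr(samples$condition, 1, 4),
                               samples$assay, samples$replicate, sep = "_")
    rownames(samples) <- NULL
    ns <- nrow(samples)
    sf <- if (is.null(config$library_size_factors)) rep(1, ns) else
      rep_len(config$library_size_factors, ns)

    counts <- matrix(0L, n, ns, dimnames = list(ids, samples$sample_id))
    for (s in seq_len(ns)) {
      xc <- as.numeric(samples$condition[s] == "autotrophic")
      xa <- as.numeric(samples$assay[s] == "RPF")
      mu <- q * sf[s] * 2^(xc * beta + xa * gamma + xc * xa * delta)
      counts[, s] <- if (all(alpha < 1e-12)) rpois(n, mu) else
        rnbinom(n, size = 1 / pmax(alpha, 1e-12), mu = mu)
    }
    truth <- data.frame(
      gene_id = ids, q = q, alpha = alpha,
      beta = beta, delta = delta, gamma = gamma,
      beta_latent = beta_lat, delta_latent = delta_lat,
      is_de = is_de, is_te = is_te,
      te_class = ifelse(is_te & delta >= 1, "up",
                 ifelse(is_te & delta <= -1, "down", "unchanged")),
      stringsAsFactors = FALSE)
    list(counts = count_matrix(counts, samples[, c("sample_id", "condition",
                                                   "assay", "replicate")]),
         truth = truth)
  })
}

revcomp_dna <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

random_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Simulate 5'UTR sequences and an embedding genome
#'
#' TE-down genes receive a planted hairpin: a random stem drawn from the
#' upper half of `hairpin_stem_range`, a 4-nt loop, and the stem's reverse
#' complement, inserted at a random position of an otherwise i.i.d. uniform
#' ACGU background.  All other genes get pure random sequence.  The returned
#' genome carries each UTR at its genomic coordinates (reverse-complemented
#' on the - strand) over a random DNA background, so strand-aware UTR
#' extraction can be checked against the planted sequences.
#'
#' @param config a [sim_config].
#' @param annotation a [gene_annotation].
#' @param truth truth table from [simulate_counts] (supplies the TE class).
#' @return A list: `utr5` (named RNA sequences, genes with a non-empty
#'   5'UTR), `stem_len` (planted stem length, 0 when none), `genome`
#'   (named DNA contig sequences).
#' @export
simulate_utr_sequences <- function(config, annotation, truth) {
  with_op_seed(config$seed, "utr", {
    lens <- utr5_length(annotation)
    keep <- which(annotation$has_tss & lens > 0)
    utr5 <- character(0); stem_len <- integer(0)
    tedown <- truth$te_class[match(annotation$gene_id, truth$gene_id)] == "down"
    for (k in keep) {
      L <- lens[k]
      smin <- ceiling(mean(config$hairpin_stem_range))
      smax <- config$hairpin_stem_range[2]
      s <- if (isTRUE(tedown[k])) resample(smin:smax) else 0L
      if (s > 0 && 2 * s + 4 <= L) {
        stem <- random_seq(s)
        rc <- chartr("ACGU", "UGCA", paste(rev(strsplit(stem, "")[[1]]),
                                           collapse = ""))
        hp <- paste0(stem, random_seq(4), rc)
        pad <- L - nchar(hp)
        at <- resample(0:pad)
        seq <- paste0(random_seq(at), hp, random_seq(pad - at))
      } else {
        s <- 0L
        seq <- random_seq(L)
      }
      utr5[annotation$gene_id[k]] <- seq
      stem_len[annotation$gene_id[k]] <- s
    }
    # embed in a genome
    genome <- list()
    for (ct in unique(annotation$contig)) {
      rows <- annotation$contig == ct
      glen <- max(annotation$cds_end[rows], annotation$utr3_end[rows],
                  annotation$tss[rows] + 1L, na.rm = TRUE) + 100L
      g <- with_op_seed(config$seed, "genome",
                        sample(c("A", "C", "G", "T"), glen, replace = TRUE))
      for (k in which(rows)) {
        id <- annotation$gene_id[k]
        if (is.na(utr5[id] %||% NA)) next
        if (!id %in% names(utr5)) next
        dna <- chartr("U", "T", utr5[[id]])
        if (annotation$strand[k] == "-") dna <- revcomp_dna(dna)
        i0 <- annotation$utr5_start[k] + 1L
        g[i0:(i0 + nchar(dna) - 1L)] <- strsplit(dna, "")[[1]]
      }
      genome[[ct]] <- paste(g, collapse = "")
    }
    list(utr5 = utr5, stem_len = stem_len, genome = unlist(genome))
  })
}

#' Simulate ribosome footprint coverage tracks
#'
#' Per-base counts are Poisson with CDS rate `lambda_cds = coverage_scale *
#' E[RPF mean]` for the gene in the given condition; the 5'UTR rate is
#' `u * lambda_cds` and the 3'UTR rate `utr3_cov * lambda_cds`.  By default
#' `u` is `utr5_cov_base`, elevated to `utr5_cov_tedown` for TE-down genes
#' under the autotrophic condition.
#'
#' @param config a [sim_config].
#' @param annotation a [gene_annotation].
#' @param truth truth table from [simulate_counts].
#' @param condition `"heterotrophic"` or `"autotrophic"`.
#' @param u optional scalar overriding the 5'UTR/CDS rate ratio for all
#'   genes.
#' @return A [coverage_track] spanning the contig.
#' @export
simulate_coverage <- function(config, annotation, truth,
                              condition = "autotrophic", u = NULL) {
  stopifnot(condition %in% c("heterotrophic", "autotrophic"))
  with_op_seed(config$seed, "coverage", {
    tr <- truth[match(annotation$gene_id, truth$gene_id), ]
    xc <- as.numeric(condition == "autotrophic")
    mu_rpf <- tr$q * 2^(xc * tr$beta + tr$gamma + xc * tr$delta)
    lam_cds <- config$coverage_scale * mu_rpf
    glen <- max(annotation$cds_end, annotation$utr3_end,
                annotation$tss + 1L, na.rm = TRUE) + 100L
    values <- numeric(glen)
    for (k in seq_len(nrow(annotation))) {
      uk <- if (!is.null(u)) u else
        if (xc == 1 && identical(tr$te_class[k], "down"))
          config$utr5_cov_tedown else config$utr5_cov_base
      put <- function(a, b, lam) {
        if (is.na(a) || is.na(b) || b <= a) return()
        i <- (a + 1L):b
        values[i] <<- values[i] + rpois(length(i), lam)
      }
      put(annotation$cds_start[k], annotation$cds_end[k], lam_cds[k])
      put(annotation$utr5_start[k], annotation$utr5_end[k], uk * lam_cds[k])
      put(annotation$utr3_start[k], annotation$utr3_end[k],
          config$utr3_cov * lam_cds[k])
    }
    coverage_track(annotation$contig[1], "+", 0L, values)
  })
}
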