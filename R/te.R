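#' Translation efficiency point estimates
#'
#' TE of a gene in a condition is its replicate-averaged normalized RPF
#' level divided by its replicate-averaged normalized mRNA level.  Genes
#' whose mean normalized mRNA falls below `mrna_floor` in either condition
#' are flagged `excluded` (their TE ratios blow up) and carry `NA`
#' estimates.  A zero group mean in a retained gene is replaced by a 0.5
#' pseudo-count on the normalized scale for the point estimate.
#'
#' @param cm a [count_matrix] with both assays in both conditions.
#' @param size_factors a `size_factor_set` or numeric vector.
#' @param mrna_floor minimum mean normalized mRNA (default 1).
#' @return data.frame with `te_het`, `te_auto`, `te_log2fc` and the per-
#'   condition assay means, plus an `excluded` flag.
#' @export
compute_te <- function(cm, size_factors, mrna_floor = 1) {
  y <- normalized_counts(cm, size_factors)
  s <- cm$samples
  cell_mean <- function(cond, assay) {
    j <- s$condition == cond & s$assay == assay
    if (!any(j)) stop("missing assay ", assay, " for condition ", cond)
    rowMeans(y[, j, drop = FALSE])
  }
  m_mrna_h <- cell_mean("heterotrophic", "mRNA")
  m_mrna_a <- cell_mean("autotrophic", "mRNA")
  m_rpf_h <- cell_mean("heterotrophic", "RPF")
  m_rpf_a <- cell_mean("autotrophic", "RPF")
  excluded <- m_mrna_h < mrna_floor | m_mrna_a < mrna_floor
  eps <- function(m) ifelse(m == 0, 0.5, m)
  te_h <- eps(m_rpf_h) / m_mrna_h
  te_a <- eps(m_rpf_a) / m_mrna_a
  out <- data.frame(
    gene_id = rownames(cm$counts),
    mrna_het = m_mrna_h, mrna_auto = m_mrna_a,
    rpf_het = m_rpf_h, rpf_auto = m_rpf_a,
    te_het = te_h, te_auto = te_a,
    te_log2fc = log2(te_a / te_h),
    excluded = excluded, stringsAsFactors = FALSE)
  out$te_het[excluded] <- out$te_auto[excluded] <- out$te_log2fc[excluded] <- NA_real_
  out
}

#' Wald test for the condition-by-assay (TE) interaction
#'
#' Per gene, an NB GLM with log link and one mean per (condition, assay)
#' cell is fit with the shared per-gene dispersion held fixed; the tested
#' quantity is the interaction contrast
#' `(RPF:auto - mRNA:auto) - (RPF:het - mRNA:het)`, i.e. the TE log fold
#' change (autotrophic over heterotrophic).  Two-sided Wald p-values are
#' BH-adjusted across tested genes; all-zero genes get `p = 1` and are
#' flagged.
#'
#' @param cm a [count_matrix] with both assays and conditions.
#' @param size_factors a `size_factor_set` or numeric vector.
#' @param dispersions named per-gene dispersion vector.
#' @return data.frame with `te_log2fc_mle`, `se`, `stat`, `pvalue`, `padj`,
#'   `all_zero`.
#' @export
te_interaction_test <- function(cm, size_factors, dispersions) {
  sf <- sf_vector(size_factors, cm)
  s <- cm$samples
  cells <- list(
    mh = s$condition == "heterotrophic" & s$assay == "mRNA",
    ma = s$condition == "autotrophic" & s$assay == "mRNA",
    rh = s$condition == "heterotrophic" & s$assay == "RPF",
    ra = s$condition == "autotrophic" & s$assay == "RPF")
  if (any(vapply(cells, sum, 1L) < 2))
    stop("need >= 2 replicates in every (condition, assay) cell")
  alpha <- dispersions[rownames(cm$counts)]
  if (any(is.na(alpha))) stop("dispersions missing for some genes")
  n <- nrow(cm$counts)
  est <- se <- stat <- p <- numeric(n)
  zero <- logical(n)
  for (i in seq_len(n)) {
    y <- cm$counts[i, ]
    if (sum(y) == 0) {
      zero[i] <- TRUE; est[i] <- 0; se[i] <- NA_real_; stat[i] <- 0; p[i] <- 1
      next
    }
    f <- lapply(cells, function(j) nb_fit_group(y[j], sf[j], alpha[i]))
    d <- (f$ra$eta - f$ma$eta) - (f$rh$eta - f$mh$eta)
    v <- sum(vapply(f, function(x) 1 / x$info, 1.0))
    est[i] <- d / log(2)
    se[i] <- sqrt(v) / log(2)
    stat[i] <- d / sqrt(v)
    p[i] <- 2 * pnorm(-abs(stat[i]))
  }
  data.frame(gene_id = rownames(cm$counts),
             te_log2fc_mle = est, se = se, stat = stat,
             pvalue = p, padj = benjamini_hochberg(p),
             all_zero = zero, stringsAsFactors = FALSE)
}

#' Full translation-efficiency results with class calls
#'
#' Combines [compute_te] point estimates with the [te_interaction_test]
#' significance and classifies genes as TE `up` (`te_log2fc >= 1` and
#' `padj < 0.05`), `down` (symmetric) or `unchanged`.  Excluded (low-mRNA)
#' genes are classified `unchanged` and keep their `excluded` flag.
#'
#' @inheritParams te_interaction_test
#' @param mrna_floor minimum mean normalized mRNA (default 1).
#' @param lfc_threshold,alpha_threshold class-calling thresholds.
#' @return data.frame merging both sets of columns plus `te_class`.
#' @export
te_results <- function(cm, size_factors, dispersions, mrna_floor = 1,
                       lfc_threshold = 1, alpha_threshold = 0.05) {
  pt <- compute_te(cm, size_factors, mrna_floor = mrna_floor)
  tst <- te_interaction_test(cm, size_factors, dispersions)
  out <- merge(pt, tst, by = "gene_id", sort = FALSE)
  out <- out[match(pt$gene_id, out$gene_id), ]
  ok <- !out$excluded & !out$all_zero
  out$padj <- NA_real_
  out$padj[ok] <- benjamini_hochberg(out$pvalue[ok])
  out$te_class <- "unchanged"
  out$te_class[ok & out$te_log2fc >= lfc_threshold &
                 out$padj < alpha_threshold] <- "up"
  out$te_class[ok & out$te_log2fc <= -lfc_threshold &
                 out$padj < alpha_threshold] <- "down"
  rownames(out) <- NULL
  out
}

#' Translational-buffering correlation
#'
#' Spearman correlation between the mRNA condition log2 fold change and the
#' TE log2 fold change over genes present in both tables; a negative value
#' is the translational-buffering signature.
#'
#' @param de_mrna result of [nb_wald_test] on the mRNA assay.
#' @param te result of [te_results] or [compute_te].
#' @return List with `rho`, `pvalue` and `n`.
#' @export
buffering_correlation <- function(de_mrna, te) {
  m <- merge(de_mrna[, c("gene_id", "log2fc")],
             te[, c("gene_id", "te_log2fc")], by = "gene_id")
  m <- m[is.finite(m$log2fc) & is.finite(m$te_log2fc), ]
  ct <- suppressWarnings(cor.test(m$log2fc, m$te_log2fc, method = "spearman"))
  list(rho = unname(ct$estimate), pvalue = ct$p.value, n = nrow(m))
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Relative translation efficiency of reporter constructs
#'
#' For a promoter-5'UTR reporter construct assayed in two conditions, the
#' relative TE is the protein expression fold change (e.g. from a
#' beta-galactosidase assay) divided by the mRNA expression fold change,
#' reported to two decimals (half-up).
#'
#' @param measurements data.frame with columns `construct_id`, `mrna_fc`,
#'   `protein_fc` (all fold changes positive).
#' @return The input with a `relative_te` column appended.
#' @export
reporter_relative_te <- function(measurements) {
  measurements <- as.data.frame(measurements)
  need <- c("construct_id", "mrna_fc", "protein_fc")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns ", paste(need, collapse = ", "))
  if (any(measurements$mrna_fc <= 0) || any(measurements$protein_fc <= 0))
    stop("fold changes must be positive")
  measurements$relative_te <-
    round_half_up(measurements$protein_fc / measurements$mrna_fc, 2)
  measurements
}
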