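#' Median-of-ratios size factors
#'
#' The reference is the per-gene geometric mean across samples; a sample's
#' size factor is the median over genes of its count divided by the
#' reference.  Genes with a zero count in any sample are excluded from the
#' reference.  The returned factors are rescaled so their geometric mean is
#' 1 (a pure representation choice: fold changes are invariant to it).
#'
#' @param cm a [count_matrix] or a plain counts matrix.
#' @param pseudo_reference if `TRUE`, a 0.5 pseudo-count is added before the
#'   geometric mean so matrices without an all-nonzero gene can still be
#'   normalized.
#' @return An object of class `size_factor_set`: list with `size_factors`
#'   (named, positive, geometric mean 1) and `reference` (per-gene geometric
#'   means; `NA` for genes excluded from the reference).
#' @export
estimate_size_factors <- function(cm, pseudo_reference = FALSE) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  x <- counts
  if (pseudo_reference) x <- x + 0.5
  all_pos <- rowSums(x > 0) == ncol(x)
  if (!any(all_pos))
    stop("no gene has nonzero counts in every sample; ",
         "rerun with pseudo_reference = TRUE")
  ref <- rep(NA_real_, nrow(x))
  ref[all_pos] <- exp(rowMeans(log(x[all_pos, , drop = FALSE])))
  sf <- apply(x[all_pos, , drop = FALSE], 2, function(col)
    median(col / ref[all_pos]))
  if (any(sf <= 0)) stop("nonpositive size factor estimated")
  sf <- sf / exp(mean(log(sf)))
  structure(list(size_factors = sf, reference = ref),
            class = "size_factor_set")
}

sf_vector <- function(size_factors, cm = NULL) {
  sf <- if (inherits(size_factors, "size_factor_set"))
    size_factors$size_factors else size_factors
  if (!is.null(cm) && length(sf) != ncol(cm$counts))
    stop("size factor length does not match sample count")
  sf
}

#' Normalized counts
#'
#' @param cm a [count_matrix].
#' @param size_factors a `size_factor_set` or numeric vector.
#' @return Matrix of counts divided by their sample's size factor.
#' @export
normalized_counts <- function(cm, size_factors) {
  sweep(cm$counts, 2, sf_vector(size_factors, cm), "/")
}

#' Per-gene NB dispersion by method of moments with trend shrinkage
#'
#' Within each (condition, assay) replicate group the moment estimator
#' `alpha = (var - mean * E(1/sf)) / mean^2` is computed on normalized
#' counts and pooled across groups with weights `n_group - 1`.  A parametric
#' mean-dispersion trend `alpha(mu) = a0 + a1 / mu` is then fit over genes
#' with a positive moment estimate, and each such gene is shrunk halfway
#' toward the trend on the log scale.  Genes with a nonpositive moment
#' estimate (under-dispersed, e.g. constant genes) are set to the floor
#' directly.
#'
#' @param cm a [count_matrix].
#' @param size_factors a `size_factor_set` or numeric vector.
#' @param shrink_weight weight on the trend in log space (default 0.5).
#' @param alpha_floor lower bound on the returned dispersions.
#' @return Named numeric vector of per-gene dispersions (>= `alpha_floor`).
#' @export
estimate_dispersions <- function(cm, size_factors, shrink_weight = 0.5,
                                 alpha_floor = 1e-4) {
  sf <- sf_vector(size_factors, cm)
  y <- normalized_counts(cm, size_factors)
  grp <- interaction(cm$samples$condition, cm$samples$assay, drop = TRUE)
  if (!all(table(grp) >= 2))
    stop("every (condition, assay) group needs >= 2 replicates")
  num <- den <- rep(0, nrow(y))
  mu_bar <- rowMeans(y)
  for (g in levels(grp)) {
    j <- which(grp == g)
    m <- rowMeans(y[, j, drop = FALSE])
    v <- apply(y[, j, drop = FALSE], 1, var)
    w <- length(j) - 1
    a <- (v - m * mean(1 / sf[j])) / m^2
    ok <- is.finite(a)
    num[ok] <- num[ok] + w * a[ok]
    den[ok] <- den[ok] + w
  }
  raw <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
  alpha <- rep(alpha_floor, nrow(y))
  pos <- which(is.finite(raw) & raw > 0 & mu_bar > 0)
  if (length(pos) >= 10) {
    fit <- stats::lm(raw[pos] ~ I(1 / mu_bar[pos]))
    a0 <- max(unname(coef(fit)[1]), alpha_floor)
    a1 <- max(unname(coef(fit)[2]), 0)
    trend <- a0 + a1 / mu_bar[pos]
    alpha[pos] <- exp((1 - shrink_weight) * log(raw[pos]) +
                        shrink_weight * log(trend))
  } else if (length(pos)) {
    alpha[pos] <- raw[pos]
  }
  alpha <- pmax(alpha, alpha_floor)
  names(alpha) <- rownames(y)
  alpha
}

# MLE of a single NB group mean on the log scale with sample offsets.
# Score S(eta) = sum (y - mu_i) / (1 + alpha mu_i), expected information
# I(eta) = sum mu_i / (1 + alpha mu_i), mu_i = exp(eta) sf_i.
# A group with zero total count has its mean floored at 0.5 / sum(sf).
nb_fit_group <- function(y, sf, alpha) {
  tot <- sum(y)
  if (tot == 0) {
    mu0 <- 0.5 / sum(sf)
    m <- mu0 * sf
    return(list(eta = log(mu0), info = sum(m / (1 + alpha * m)), zero = TRUE))
  }
  eta <- log(tot / sum(sf))
  for (it in 1:100) {
    m <- exp(eta) * sf
    s <- sum((y - m) / (1 + alpha * m))
    info <- sum(m / (1 + alpha * m))
    step <- s / info
    eta <- eta + step
    if (abs(step) < 1e-12) break
  }
  m <- exp(eta) * sf
  list(eta = eta, info = sum(m / (1 + alpha * m)), zero = FALSE)
}

#' Negative-binomial Wald test for a condition contrast
#'
#' Fits, per gene, an NB GLM with log link in which each condition group has
#' its own mean (with size factors as offsets and the supplied dispersion
#' held fixed), then tests the log fold change `contrast[1]` over
#' `contrast[2]` with a two-sided Wald test.  Genes with all-zero counts get
#' `p = 1`, `log2fc = 0` and are flagged.  Significance and effect-size
#' calls follow the two-fold / adjusted-p 0.05 convention.
#'
#' @param cm a [count_matrix].
#' @param size_factors a `size_factor_set` or numeric vector (full matrix).
#' @param dispersions named per-gene dispersion vector.
#' @param contrast character(2): numerator and denominator conditions
#'   (default autotrophic over heterotrophic).
#' @param assay which assay to test (`"mRNA"` or `"RPF"`).
#' @param lfc_threshold,alpha_threshold DEG-calling thresholds.
#' @return data.frame with per-gene group means (normalized), `log2fc`,
#'   `se`, `stat`, `pvalue`, `padj`, `is_deg`, `all_zero`.
#' @export
nb_wald_test <- function(cm, size_factors, dispersions,
                         contrast = c("autotrophic", "heterotrophic"),
                         assay = "mRNA",
                         lfc_threshold = 1, alpha_threshold = 0.05) {
  sf_all <- sf_vector(size_factors, cm)
  keep <- cm$samples$assay == assay
  if (!any(keep)) stop("assay ", assay, " absent from count matrix")
  counts <- cm$counts[, keep, drop = FALSE]
  sams <- cm$samples[keep, , drop = FALSE]
  sf <- sf_all[keep]
  g1 <- which(sams$condition == contrast[1])
  g2 <- which(sams$condition == contrast[2])
  if (length(g1) < 2 || length(g2) < 2)
    stop("need >= 2 replicates per condition in assay ", assay)
  alpha <- dispersions[rownames(counts)]
  if (any(is.na(alpha))) stop("dispersions missing for some genes")

  n <- nrow(counts)
  lfc <- se <- stat <- p <- numeric(n)
  m1 <- m2 <- numeric(n)
  zero <- logical(n)
  for (i in seq_len(n)) {
    y1 <- counts[i, g1]; y2 <- counts[i, g2]
    m1[i] <- mean(y1 / sf[g1]); m2[i] <- mean(y2 / sf[g2])
    if (sum(y1) + sum(y2) == 0) {
      zero[i] <- TRUE
      lfc[i] <- 0; se[i] <- NA_real_; stat[i] <- 0; p[i] <- 1
      next
    }
    f1 <- nb_fit_group(y1, sf[g1], alpha[i])
    f2 <- nb_fit_group(y2, sf[g2], alpha[i])
    d <- f1$eta - f2$eta
    v <- 1 / f1$info + 1 / f2$info
    lfc[i] <- d / log(2)
    se[i] <- sqrt(v) / log(2)
    stat[i] <- d / sqrt(v)
    p[i] <- 2 * pnorm(-abs(stat[i]))
  }
  padj <- benjamini_hochberg(p)
  data.frame(
    gene_id = rownames(counts),
    mean_num = m1, mean_den = m2,
    log2fc = lfc, se = se, stat = stat,
    pvalue = p, padj = padj,
    is_deg = !zero & abs(lfc) >= lfc_threshold & padj < alpha_threshold,
    all_zero = zero,
    stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure with monotonicity enforcement; the result does not
#' depend on input order beyond each element's own value and rank.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  n <- length(p)
  if (!n) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  adj[is.na(p)] <- NA_real_
  adj
}

#' Reads per kilobase per million (RPKM)
#'
#' `rpkm = 1e9 * count / (gene_length * library_total)`, per sample.
#'
#' @param cm a [count_matrix] or counts matrix.
#' @param gene_lengths named vector of gene lengths in nt.
#' @return Matrix of RPKM values, same shape as the counts.
#' @export
compute_rpkm <- function(cm, gene_lengths) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  len <- gene_lengths[rownames(counts)]
  if (any(is.na(len))) stop("gene lengths missing for some genes")
  tot <- colSums(counts)
  1e9 * sweep(sweep(counts, 1, len, "/"), 2, tot, "/")
}

#' PCA quality control of normalized counts
#'
#' Samples are projected on the principal components of
#' `log2(normalized + 1)` after gene centering (SVD, no scaling).
#'
#' @param cm a [count_matrix].
#' @param size_factors a `size_factor_set` or numeric vector.
#' @return List with `coords` (samples x components), `var_explained`
#'   (fraction of variance per component; all zero for degenerate input)
#'   and `samples` (the sample table).
#' @export
pca_qc <- function(cm, size_factors) {
  y <- log2(normalized_counts(cm, size_factors) + 1)
  yc <- y - rowMeans(y)
  sv <- svd(t(yc))
  tot <- sum(sv$d^2)
  ve <- if (tot <= 1e-12) rep(0, length(sv$d)) else sv$d^2 / tot
  coords <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(coords) <- colnames(cm$counts)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  list(coords = coords, var_explained = ve, samples = cm$samples)
}
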