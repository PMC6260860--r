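#' Operon subunit pair statistics
#'
#' For every operon with subunit indices 1 and 2, returns the mean
#' normalized RPF level of each gene per condition.  Pairs in which either
#' gene falls below the expression floor in a condition are dropped for that
#' condition's correlation.
#'
#' @param annotation a [gene_annotation] with operon assignments.
#' @param cm a [count_matrix] containing RPF samples.
#' @param size_factors a `size_factor_set` or numeric vector.
#' @param floor minimum mean normalized RPF for a pair to count.
#' @return data.frame with one row per (operon, condition): `operon_id`,
#'   `condition`, `gene1`, `gene2`, `rpf1`, `rpf2`, `log_ratio`, `pass`.
#' @export
operon_pair_stats <- function(annotation, cm, size_factors, floor = 1) {
  y <- normalized_counts(cm, size_factors)
  s <- cm$samples
  ops <- unique(annotation$operon_id[!is.na(annotation$operon_id)])
  rows <- list()
  for (o in ops) {
    g <- annotation[which(annotation$operon_id == o), ]
    g <- g[order(g$subunit_index), ]
    if (nrow(g) < 2) next
    g1 <- g$gene_id[1]; g2 <- g$gene_id[2]
    if (!all(c(g1, g2) %in% rownames(y))) next
    for (cond in unique(s$condition)) {
      j <- s$condition == cond & s$assay == "RPF"
      if (!any(j)) next
      r1 <- mean(y[g1, j]); r2 <- mean(y[g2, j])
      rows[[length(rows) + 1L]] <- data.frame(
        operon_id = o, condition = cond, gene1 = g1, gene2 = g2,
        rpf1 = r1, rpf2 = r2,
        log_ratio = log10(r1) - log10(r2),
        pass = r1 >= floor & r2 >= floor,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pearson correlation of paired subunit RPF levels
#'
#' Correlation of `log10(rpf1)` vs `log10(rpf2)` across operon pairs in one
#' condition; a value near 1 indicates stoichiometric (1:1) subunit
#' synthesis.
#'
#' @param pairs output of [operon_pair_stats].
#' @param condition condition to evaluate.
#' @return List with `r`, `pvalue` and `n_pairs`.
#' @export
pair_correlation <- function(pairs, condition) {
  d <- pairs[pairs$condition == condition & pairs$pass, ]
  if (nrow(d) < 3) stop("need >= 3 expressed pairs")
  ct <- cor.test(log10(d$rpf1), log10(d$rpf2), method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value, n_pairs = nrow(d))
}

#' Synthesis-rate ratios between gene groups
#'
#' The synthesis-rate proxy of a group (e.g. the methyl or the carbonyl
#' branch of the Wood-Ljungdahl pathway) is the mean normalized RPF level of
#' its member genes in the given condition.  Pairwise ratios between groups
#' are flagged `equimolar` when they fall within `[1/ratio_tol, ratio_tol]`.
#'
#' @param groups named list of gene-id character vectors.
#' @param cm a [count_matrix] containing RPF samples.
#' @param size_factors a `size_factor_set` or numeric vector.
#' @param condition condition to evaluate.
#' @param ratio_tol tolerance for the equimolar call (default 1.5).
#' @return List with `rates` (named per-group means), `ratios` (matrix of
#'   `rates[i] / rates[j]`), `equimolar` (logical matrix).
#' @export
complex_ratio <- function(groups, cm, size_factors,
                          condition = "autotrophic", ratio_tol = 1.5) {
  stopifnot(ratio_tol >= 1)
  y <- normalized_counts(cm, size_factors)
  j <- cm$samples$condition == condition & cm$samples$assay == "RPF"
  if (!any(j)) stop("no RPF samples for condition ", condition)
  rates <- vapply(groups, function(gs) {
    gs <- intersect(gs, rownames(y))
    if (!length(gs)) stop("group has no genes in the count matrix")
    mean(rowMeans(y[gs, j, drop = FALSE]))
  }, 1.0)
  ratios <- outer(rates, rates, "/")
  list(rates = rates, ratios = ratios,
       equimolar = ratios >= 1 / ratio_tol & ratios <= ratio_tol)
}
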