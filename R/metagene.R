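#' Binned coverage profile of one gene
#'
#' Extracts per-base coverage over the 5'UTR, CDS and 3'UTR, orients it 5'
#' to 3' (minus-strand genes are reversed), averages it into fixed numbers
#' of bins per region, and normalizes all bins by the gene's mean per-base
#' CDS coverage.  Regions shorter than their bin count are resampled to the
#' bin grid per base (linear interpolation).  Genes with zero CDS coverage
#' are excluded (`NULL` is returned).
#'
#' @param track a [coverage_track].
#' @param gene one row of a [gene_annotation].
#' @param bins integer vector `c(utr5, cds, utr3)` (default 20/50/20).
#' @return List with `utr5`, `cds`, `utr3` (normalized bin vectors; `NULL`
#'   for absent regions) and `norm_const` (mean CDS coverage), or `NULL`.
#' @export
gene_profile <- function(track, gene, bins = c(utr5 = 20L, cds = 50L, utr3 = 20L)) {
  region <- function(a, b) {
    if (is.na(a) || is.na(b) || b <= a) return(NULL)
    v <- track_slice(track, a, b)
    if (gene$strand == "-") rev(v) else v
  }
  v5 <- region(gene$utr5_start, gene$utr5_end)
  vc <- region(gene$cds_start, gene$cds_end)
  v3 <- region(gene$utr3_start, gene$utr3_end)
  norm_const <- mean(vc)
  if (!is.finite(norm_const) || norm_const <= 0) return(NULL)
  bin_vec <- function(v, b) {
    if (is.null(v)) return(NULL)
    L <- length(v)
    if (L >= b) {
      edges <- floor(L * (0:b) / b)
      vapply(seq_len(b), function(k) mean(v[(edges[k] + 1):edges[k + 1]]), 1.0)
    } else if (L == 1) {
      rep(v, b)
    } else {
      approx(seq(0, 1, length.out = L), v, xout = seq(0, 1, length.out = b))$y
    }
  }
  list(utr5 = bin_vec(v5, bins[[1]]) / norm_const,
       cds = bin_vec(vc, bins[[2]]) / norm_const,
       utr3 = bin_vec(v3, bins[[3]]) / norm_const,
       norm_const = norm_const)
}

#' Metagene profiles for a set of genes
#'
#' @param track a [coverage_track].
#' @param annotation a [gene_annotation].
#' @param bins integer vector `c(utr5, cds, utr3)`.
#' @param genes optional gene ids to restrict to.
#' @return List with `profiles` (per-gene list from [gene_profile]),
#'   `median_profile` (per-bin median across genes, regions concatenated)
#'   and `region_means` (data.frame of per-gene mean normalized coverage
#'   per region).
#' @export
metagene_profiles <- function(track, annotation, bins = c(20L, 50L, 20L),
                              genes = NULL) {
  rows <- seq_len(nrow(annotation))
  if (!is.null(genes)) rows <- rows[annotation$gene_id %in% genes]
  profiles <- list()
  rm_rows <- list()
  for (k in rows) {
    pr <- gene_profile(track, annotation[k, ], bins)
    if (is.null(pr)) next
    id <- annotation$gene_id[k]
    profiles[[id]] <- pr
    rm_rows[[id]] <- data.frame(
      gene_id = id,
      utr5 = if (is.null(pr$utr5)) NA_real_ else mean(pr$utr5),
      cds = mean(pr$cds),
      utr3 = if (is.null(pr$utr3)) NA_real_ else mean(pr$utr3),
      stringsAsFactors = FALSE)
  }
  if (!length(profiles)) stop("no gene with nonzero CDS coverage")
  concat <- function(pr) c(pr$utr5, pr$cds, pr$utr3)
  lens <- vapply(profiles, function(pr) length(concat(pr)), 1L)
  full <- profiles[lens == max(lens)]
  med <- apply(do.call(rbind, lapply(full, concat)), 2, median)
  list(profiles = profiles,
       median_profile = med,
       region_means = do.call(rbind, c(rm_rows, list(make.row.names = FALSE))))
}

#' Compare per-region footprint coverage between conditions
#'
#' The per-gene statistic is its mean CDS-normalized coverage in the chosen
#' region; the two conditions are compared with a two-sided Wilcoxon
#' rank-sum test (default) or, when the same genes are present in both
#' conditions, optionally a paired signed-rank test.
#'
#' @param prof_a,prof_b results of [metagene_profiles] for the two
#'   conditions.
#' @param region `"utr5"`, `"cds"` or `"utr3"`.
#' @param paired use the signed-rank test on genes shared by both
#'   conditions.
#' @return List with `region`, `n`, `medians`, `statistic`, `pvalue`.
#' @export
aggregate_and_compare <- function(prof_a, prof_b, region = "utr5",
                                  paired = FALSE) {
  stopifnot(region %in% c("utr5", "cds", "utr3"))
  a <- prof_a$region_means; b <- prof_b$region_means
  xa <- a[[region]][!is.na(a[[region]])]
  xb <- b[[region]][!is.na(b[[region]])]
  if (paired) {
    shared <- intersect(a$gene_id[!is.na(a[[region]])],
                        b$gene_id[!is.na(b[[region]])])
    if (!length(shared)) stop("no shared genes for paired comparison")
    xa <- a[[region]][match(shared, a$gene_id)]
    xb <- b[[region]][match(shared, b$gene_id)]
    w <- wilcoxon_signedrank(xa, xb)
  } else {
    w <- wilcoxon_ranksum(xa, xb)
  }
  list(region = region, n = c(length(xa), length(xb)),
       medians = c(median(xa), median(xb)),
       statistic = w$statistic, pvalue = w$pvalue)
}
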