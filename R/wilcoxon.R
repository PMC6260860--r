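# Rank tests used by the UTR-structure and metagene comparisons.

# exact Mann-Whitney U null counts over u = 0..n*m via the classical
# recurrence N(u; n, m) = N(u - m; n - 1, m) + N(u; n, m - 1)
mw_distribution <- function(n, m) {
  memo <- new.env(parent = emptyenv())
  rec <- function(n, m) {
    key <- paste(n, m)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (n == 0 || m == 0) {
      out <- 1  # only u = 0
    } else {
      a <- rec(n - 1, m)  # counts over u = 0..(n-1)m
      b <- rec(n, m - 1)  # counts over u = 0..n(m-1)
      out <- numeric(n * m + 1)
      out[seq_along(b)] <- b
      out[m + seq_along(a)] <- out[m + seq_along(a)] + a
    }
    memo[[key]] <- out
    out
  }
  rec(n, m)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided test of a location shift between two samples.  When both
#' samples have at most `exact_max` observations and there are no ties, the
#' exact Mann-Whitney null distribution is used (count recurrence);
#' otherwise a normal approximation with tie correction and continuity
#' correction.  Identical samples give p = 1.
#'
#' @param x,y numeric samples.
#' @param exact_max largest per-group size for the exact path (default 25).
#' @return List with `statistic` (Mann-Whitney U of `x`), `pvalue`,
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_ranksum <- function(x, y, exact_max = 25) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (n <= exact_max && m <= exact_max && !ties) {
    cnt <- mw_distribution(n, m)
    tot <- sum(cnt)
    lo <- sum(cnt[seq_len(floor(u) + 1)]) / tot          # P(U <= u)
    hi <- sum(cnt[(floor(u) + 1):length(cnt)]) / tot     # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
    return(list(statistic = u, pvalue = p, method = "exact"))
  }
  N <- n + m
  t <- table(c(x, y))
  tie_term <- sum(t^3 - t) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(statistic = u, pvalue = 1, method = "normal"))
  num <- u - n * m / 2
  num <- num - sign(num) * 0.5   # continuity correction toward 0
  z <- num / sqrt(sigma2)
  list(statistic = u, pvalue = 2 * pnorm(-abs(z)), method = "normal")
}

#' Paired Wilcoxon signed-rank test (normal approximation)
#'
#' Two-sided signed-rank test on paired differences, dropping zeros, with
#' tie and continuity corrections.
#'
#' @param x,y paired numeric samples of equal length.
#' @return List with `statistic` (V), `pvalue`.
#' @export
wilcoxon_signedrank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, pvalue = 1))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  t <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(t^3 - t) / 48
  if (sigma2 <= 0) return(list(statistic = v, pvalue = 1))
  num <- v - mu
  num <- num - sign(num) * 0.5
  list(statistic = v, pvalue = 2 * pnorm(-abs(num) / sqrt(sigma2)))
}
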