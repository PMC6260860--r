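#' Count matrices with sample metadata
#'
#' A `count_matrix` couples a genes x samples matrix of raw (un-normalized)
#' non-negative integer counts with a sample table giving, for each library,
#' its growth `condition` (`heterotrophic` or `autotrophic`), `assay`
#' (`mRNA` or `RPF`) and `replicate` number.  `(condition, assay, replicate)`
#' must be unique across samples.  Normalized input is rejected: size-factor
#' estimation assumes raw counts.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample_id`, `condition`, `assay`,
#'   `replicate`, one row per column of `counts`, in column order.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (any(is.na(counts))) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts)))
    stop("counts must be raw integers; normalized input is not accepted")
  storage.mode(counts) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "assay", "replicate")
  if (!all(need %in% names(samples)))
    stop("samples must have columns ", paste(need, collapse = ", "))
  samples$replicate <- as.integer(samples$replicate)
  if (!all(samples$condition %in% c("heterotrophic", "autotrophic")))
    stop("condition must be 'heterotrophic' or 'autotrophic'")
  if (!all(samples$assay %in% c("mRNA", "RPF")))
    stop("assay must be 'mRNA' or 'RPF'")
  if (any(samples$replicate < 1L)) stop("replicate must be a positive integer")
  key <- paste(samples$condition, samples$assay, samples$replicate)
  if (anyDuplicated(key))
    stop("duplicated (condition, assay, replicate): ", key[duplicated(key)][1])
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id: ",
         samples$sample_id[duplicated(samples$sample_id)][1])
  if (!identical(colnames(counts), samples$sample_id))
    stop("column order of counts must match samples$sample_id")
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("  assays:", paste(sort(unique(x$samples$assay)), collapse = ", "),
      "| conditions:",
      paste(sort(unique(x$samples$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix to one assay and/or condition
#'
#' @param cm a `count_matrix`.
#' @param assay,condition optional values to keep.
#' @return A `count_matrix` with the selected columns.
#' @export
subset_samples <- function(cm, assay = NULL, condition = NULL) {
  keep <- rep(TRUE, nrow(cm$samples))
  if (!is.null(assay)) keep <- keep & cm$samples$assay %in% assay
  if (!is.null(condition)) keep <- keep & cm$samples$condition %in% condition
  if (!any(keep)) stop("no samples left after subsetting")
  count_matrix(cm$counts[, keep, drop = FALSE], cm$samples[keep, , drop = FALSE])
}

# canonical locale-independent sample order: condition (autotrophic,
# heterotrophic), assay (mRNA, RPF), replicate
order_samples <- function(s) {
  s[order(factor(s$condition, c("autotrophic", "heterotrophic")),
          factor(s$assay, c("mRNA", "RPF")), s$replicate), , drop = FALSE]
}

#' Per-base coverage track
#'
#' Holds per-base non-negative coverage over a contiguous 0-based interval of
#' one contig and strand.
#'
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param start 0-based start of the covered interval.
#' @param values numeric vector of per-base coverage (length = interval width).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(contig, strand, start, values) {
  stopifnot(length(contig) == 1, strand %in% c("+", "-"), length(start) == 1)
  values <- as.numeric(values)
  if (any(is.na(values)) || any(values < 0))
    stop("coverage values must be non-negative")
  structure(list(contig = contig, strand = strand,
                 start = as.integer(start), values = values),
            class = "coverage_track")
}

#' Extract per-base coverage over an interval
#'
#' Positions outside the track are treated as zero coverage.
#'
#' @param track a `coverage_track`.
#' @param start,end 0-based half-open interval.
#' @return numeric vector of length `end - start`.
#' @export
track_slice <- function(track, start, end) {
  stopifnot(end >= start)
  if (end == start) return(numeric(0))
  pos <- seq.int(start, end - 1L)
  idx <- pos - track$start + 1L
  out <- numeric(length(pos))
  ok <- idx >= 1L & idx <= length(track$values)
  out[ok] <- track$values[idx[ok]]
  out
}
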