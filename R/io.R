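#' Read a gene annotation
#'
#' Two dialects are supported.  `"gff3"` uses 1-based inclusive coordinates
#' and three feature types: `gene` (transcript span; attributes `ID`,
#' optional `operon_id`, `subunit_index` and comma-separated `terms`), `CDS`
#' (`Parent` = gene id) and single-base `TSS` (`Parent` = gene id).  An
#' optional `three_prime_UTR` feature sets the 3'UTR.  Genes without a TSS
#' feature get an empty 5'UTR and `has_tss = FALSE`; they are kept for count
#' analyses but excluded from UTR analyses.  `"bed"` is a BED-like
#' tab-separated dialect with 0-based half-open columns `contig, start, end,
#' gene_id, score, strand, cds_start, cds_end` and optional columns 9-11
#' `operon_id, subunit_index, terms` (`.` for missing); the transcript start
#' boundary is the TSS.
#'
#' @param path file to read.
#' @param dialect `"gff3"` (default) or `"bed"`.
#' @return A [gene_annotation] data.frame (internal coordinates 0-based
#'   half-open).
#' @export
read_annotation <- function(path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "gff3") read_annotation_gff3(path) else read_annotation_bed(path)
}

parse_gff3_attrs <- function(s) {
  out <- list()
  for (kv in strsplit(s, ";", fixed = TRUE)[[1]]) {
    kv <- trimws(kv)
    if (!nzchar(kv)) next
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    out[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  out
}

read_annotation_gff3 <- function(path) {
  lines <- readLines(path)
  recs <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9)
      stop("malformed GFF3 line ", i, ": expected 9 tab-separated fields")
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end))
      stop("malformed GFF3 line ", i, ": non-integer coordinates")
    recs[[length(recs) + 1L]] <- list(
      contig = f[1], type = f[3],
      start = start - 1L, end = end,  # to 0-based half-open
      strand = f[7], attrs = parse_gff3_attrs(f[9]), line = i)
  }
  genes <- Filter(function(r) r$type == "gene", recs)
  if (!length(genes)) stop("no gene features in ", path)
  ids <- vapply(genes, function(r) r$attrs$ID %||% stop(
    "malformed GFF3 line ", r$line, ": gene without ID attribute"), "")
  by_parent <- function(type) {
    xs <- Filter(function(r) r$type == type, recs)
    setNames(xs, vapply(xs, function(r) r$attrs$Parent %||% stop(
      "malformed GFF3 line ", r$line, ": ", type, " without Parent"), ""))
  }
  cds <- by_parent("CDS"); tss <- by_parent("TSS"); utr3 <- by_parent("three_prime_UTR")

  n <- length(genes)
  ann <- data.frame(gene_id = ids, contig = vapply(genes, `[[`, "", "contig"),
                    strand = vapply(genes, `[[`, "", "strand"),
                    stringsAsFactors = FALSE)
  ann$cds_start <- ann$cds_end <- ann$tss <- NA_integer_
  ann$utr3_start <- ann$utr3_end <- NA_integer_
  ann$operon_id <- NA_character_; ann$subunit_index <- NA_integer_
  ann$terms <- rep(list(character()), n)
  for (k in seq_len(n)) {
    id <- ids[k]
    if (is.null(cds[[id]])) stop("gene ", id, " has no CDS feature")
    ann$cds_start[k] <- cds[[id]]$start; ann$cds_end[k] <- cds[[id]]$end
    if (!is.null(tss[[id]])) ann$tss[k] <- tss[[id]]$start
    if (!is.null(utr3[[id]])) {
      ann$utr3_start[k] <- utr3[[id]]$start; ann$utr3_end[k] <- utr3[[id]]$end
    } else {
      ann$utr3_start[k] <- ann$utr3_end[k] <-
        if (ann$strand[k] == "+") ann$cds_end[k] else ann$cds_start[k]
    }
    a <- genes[[k]]$attrs
    if (!is.null(a$operon_id)) ann$operon_id[k] <- a$operon_id
    if (!is.null(a$subunit_index)) ann$subunit_index[k] <- as.integer(a$subunit_index)
    if (!is.null(a$terms) && nzchar(a$terms))
      ann$terms[[k]] <- strsplit(a$terms, ",", fixed = TRUE)[[1]]
  }
  ann$has_tss <- !is.na(ann$tss)
  ann <- derive_utr5(ann)
  validate_gene_annotation(ann)
}

derive_utr5 <- function(ann) {
  plus <- ann$strand == "+"
  ann$utr5_start <- ifelse(plus, ann$tss, ann$cds_end)
  ann$utr5_end <- ifelse(plus, ann$cds_start, ann$tss + 1L)
  ann$utr5_start[!ann$has_tss] <- ann$utr5_end[!ann$has_tss] <- NA_integer_
  ann$utr5_start <- as.integer(ann$utr5_start)
  ann$utr5_end <- as.integer(ann$utr5_end)
  ann
}

read_annotation_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(rows)
  if (!n) stop("no records in ", path)
  get <- function(r, j, i) {
    if (length(r) < 8) stop("malformed BED line ", i, ": expected >= 8 fields")
    if (j <= length(r)) r[j] else "."
  }
  ann <- data.frame(
    gene_id = vapply(seq_len(n), function(i) get(rows[[i]], 4, i), ""),
    contig = vapply(seq_len(n), function(i) get(rows[[i]], 1, i), ""),
    strand = vapply(seq_len(n), function(i) get(rows[[i]], 6, i), ""),
    stringsAsFactors = FALSE)
  int_col <- function(j) vapply(seq_len(n), function(i) {
    v <- suppressWarnings(as.integer(get(rows[[i]], j, i)))
    if (is.na(v)) stop("malformed BED line ", i, ": non-integer field ", j)
    v
  }, 1L)
  tx_start <- int_col(2); tx_end <- int_col(3)
  ann$cds_start <- int_col(7); ann$cds_end <- int_col(8)
  ann$tss <- ifelse(ann$strand == "+", tx_start, tx_end - 1L)
  ann$utr3_start <- ifelse(ann$strand == "+", ann$cds_end, tx_start)
  ann$utr3_end <- ifelse(ann$strand == "+", tx_end, ann$cds_start)
  opt <- function(j) vapply(seq_len(n), function(i)
    if (length(rows[[i]]) >= j) rows[[i]][j] else ".", "")
  o <- opt(9); s <- opt(10); tm <- opt(11)
  ann$operon_id <- ifelse(o == ".", NA_character_, o)
  ann$subunit_index <- ifelse(s == ".", NA_integer_, suppressWarnings(as.integer(s)))
  ann$terms <- lapply(seq_len(n), function(i)
    if (tm[i] == ".") character() else strsplit(tm[i], ",", fixed = TRUE)[[1]])
  ann$has_tss <- TRUE
  ann$utr3_start <- as.integer(ann$utr3_start); ann$utr3_end <- as.integer(ann$utr3_end)
  ann <- derive_utr5(ann)
  validate_gene_annotation(ann)
}

#' Write a gene annotation as GFF3
#'
#' Inverse of [read_annotation] for the `"gff3"` dialect; coordinates are
#' converted back to 1-based inclusive.
#'
#' @param ann a [gene_annotation].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (k in seq_len(nrow(ann))) {
    span <- range(c(ann$cds_start[k], ann$cds_end[k] - 1L,
                    if (ann$has_tss[k]) ann$tss[k],
                    if (ann$utr3_end[k] > ann$utr3_start[k])
                      c(ann$utr3_start[k], ann$utr3_end[k] - 1L)))
    attrs <- paste0("ID=", ann$gene_id[k])
    if (!is.na(ann$operon_id[k]))
      attrs <- paste0(attrs, ";operon_id=", ann$operon_id[k],
                      ";subunit_index=", ann$subunit_index[k])
    if (length(ann$terms[[k]]))
      attrs <- paste0(attrs, ";terms=", paste(ann$terms[[k]], collapse = ","))
    w <- function(type, s, e, at) writeLines(paste(
      ann$contig[k], "riboTE", type, s + 1L, e, ".", ann$strand[k], ".", at,
      sep = "\t"), con)
    w("gene", span[1], span[2] + 1L, attrs)
    w("CDS", ann$cds_start[k], ann$cds_end[k], paste0("Parent=", ann$gene_id[k]))
    if (ann$has_tss[k])
      w("TSS", ann$tss[k], ann$tss[k] + 1L, paste0("Parent=", ann$gene_id[k]))
    if (ann$utr3_end[k] > ann$utr3_start[k])
      w("three_prime_UTR", ann$utr3_start[k], ann$utr3_end[k],
        paste0("Parent=", ann$gene_id[k]))
  }
  invisible(path)
}

#' Read a count matrix with its sample metadata
#'
#' The counts file is a TSV with a `gene_id` column and one integer column
#' per sample; the metadata file is a TSV with columns `sample_id`,
#' `condition`, `assay`, `replicate`.  Samples are ordered deterministically
#' by (condition, assay, replicate); genes keep file order.
#'
#' @param path counts TSV.
#' @param metadata_path sample metadata TSV.
#' @return A [count_matrix].
#' @export
read_counts <- function(path, metadata_path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab)) stop("counts file needs a gene_id column")
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  sample_cols <- names(tab)[names(tab) != "gene_id"]
  if (anyDuplicated(sample_cols))
    stop("duplicated sample_id column: ", sample_cols[duplicated(sample_cols)][1])
  missing <- setdiff(sample_cols, meta$sample_id)
  if (length(missing))
    stop("sample in counts but absent from metadata: ", missing[1])
  meta <- meta[meta$sample_id %in% sample_cols, , drop = FALSE]
  meta <- order_samples(meta)
  rownames(meta) <- NULL
  m <- as.matrix(tab[, meta$sample_id, drop = FALSE])
  for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m))) {
    v <- suppressWarnings(as.numeric(m[i, j]))
    if (is.na(v) || v != round(v))
      stop("non-integer count at gene ", tab$gene_id[i],
           ", sample ", colnames(m)[j])
  }
  storage.mode(m) <- "integer"
  rownames(m) <- tab$gene_id
  count_matrix(m, meta)
}

#' Write a count matrix and its sample metadata
#'
#' @param cm a [count_matrix].
#' @param path counts TSV to write.
#' @param metadata_path sample metadata TSV to write.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, metadata_path) {
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$samples, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file
#'
#' Sequences are upper-cased and validated against the ACGTUN alphabet; `T`
#' and `U` are treated as equivalent downstream but the input alphabet is
#' preserved.
#'
#' @param path FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  for (nm in names(seqs)) {
    bad <- regexpr("[^ACGTUN]", seqs[[nm]])
    if (bad > 0)
      stop("invalid character '", substr(seqs[[nm]], bad, bad),
           "' at position ", bad, " of sequence ", nm)
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a bedGraph coverage file into a per-base track
#'
#' Intervals (0-based half-open) are expanded to per-base values; gaps are
#' zero-filled.  Overlapping intervals are an error.
#'
#' @param path bedGraph file (4 columns: contig, start, end, value).
#' @param strand strand to record on the returned track (bedGraph itself is
#'   unstranded).
#' @return A [coverage_track].
#' @export
read_bedgraph <- function(path, strand = "+") {
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("bedGraph needs 4 columns")
  names(tab)[1:4] <- c("contig", "start", "end", "value")
  if (length(unique(tab$contig)) != 1)
    stop("bedGraph must cover a single contig")
  tab <- tab[order(tab$start), , drop = FALSE]
  if (any(tab$end[-nrow(tab)] > tab$start[-1]))
    stop("overlapping bedGraph intervals")
  if (any(tab$value < 0)) stop("negative coverage value")
  lo <- min(tab$start); hi <- max(tab$end)
  values <- numeric(hi - lo)
  for (i in seq_len(nrow(tab)))
    values[(tab$start[i] - lo + 1L):(tab$end[i] - lo)] <- tab$value[i]
  coverage_track(tab$contig[1], strand, lo, values)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal coverage are collapsed into intervals; zero runs are
#' written too so the round trip is exact over the covered span.
#'
#' @param track a [coverage_track].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  v <- track$values
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1L))
  tab <- data.frame(contig = track$contig, start = track$start + starts,
                    end = track$start + ends, value = r$values)
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV with a provenance header
#'
#' The first line is a comment recording the pipeline version and, when
#' given, the configuration hash.  Missing values are written as `.`.
#'
#' @param tab data.frame to write.
#' @param path output file.
#' @param config_hash optional configuration hash string.
#' @return `path`, invisibly.
#' @export
write_tsv_results <- function(tab, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- paste0("# riboTE ", pipeline_version(),
                if (!is.null(config_hash)) paste0(" config_hash=", config_hash))
  writeLines(hdr, con)
  tab <- as.data.frame(tab)
  for (j in seq_along(tab)) {
    if (is.list(tab[[j]]))
      tab[[j]] <- vapply(tab[[j]], function(x)
        if (!length(x)) "." else paste(x, collapse = ","), "")
    tab[[j]][is.na(tab[[j]])] <- "."
  }
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
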