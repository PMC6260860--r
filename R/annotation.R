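#' Gene models
#'
#' A gene model records, for one gene, the CDS interval, the transcription
#' start site (TSS) and the derived 5'/3'UTR intervals, optional operon
#' membership with a subunit index, and a set of functional-term identifiers
#' (COG class letters, KEGG or GO ids).  All coordinates are 0-based,
#' half-open `[start, end)`; the TSS is a single 0-based position.
#'
#' A collection of gene models is held as a data.frame of class
#' `"gene_annotation"` with one row per gene and columns `gene_id`, `contig`,
#' `strand`, `cds_start`, `cds_end`, `tss`, `utr5_start`, `utr5_end`,
#' `utr3_start`, `utr3_end`, `operon_id`, `subunit_index`, `has_tss` and a
#' list-column `terms`.  Genes without a TSS record have `has_tss = FALSE`
#' and an empty 5'UTR; they stay in count-based analyses but are excluded
#' from UTR analyses.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param contig contig name per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param cds_start,cds_end CDS interval, 0-based half-open.
#' @param tss TSS position (0-based) or `NA` for genes without one.
#' @param utr3_length length of the 3'UTR in nt (0 for none).
#' @param operon_id operon identifier or `NA`.
#' @param subunit_index 1-based subunit position within the operon, `NA`
#'   when `operon_id` is `NA`.  Must be present exactly when `operon_id` is.
#' @param terms list of character vectors of functional-term ids (optional).
#' @return A `gene_annotation` data.frame.
#' @export
gene_annotation <- function(gene_id, contig, strand, cds_start, cds_end,
                            tss = NA_integer_, utr3_length = 0L,
                            operon_id = NA_character_,
                            subunit_index = NA_integer_,
                            terms = NULL) {
  n <- length(gene_id)
  ann <- data.frame(
    gene_id = as.character(gene_id),
    contig = rep_len(as.character(contig), n),
    strand = rep_len(as.character(strand), n),
    cds_start = as.integer(rep_len(cds_start, n)),
    cds_end = as.integer(rep_len(cds_end, n)),
    tss = as.integer(rep_len(tss, n)),
    stringsAsFactors = FALSE
  )
  utr3_length <- as.integer(rep_len(utr3_length, n))
  ann$operon_id <- rep_len(as.character(operon_id), n)
  ann$subunit_index <- as.integer(rep_len(subunit_index, n))
  ann$terms <- if (is.null(terms)) rep(list(character()), n) else terms
  ann$has_tss <- !is.na(ann$tss)

  # derived UTR intervals (0-based half-open, empty when length 0)
  ann$utr5_start <- ann$utr5_end <- NA_integer_
  plus <- ann$strand == "+"
  ann$utr5_start[plus] <- ann$tss[plus]
  ann$utr5_end[plus] <- ann$cds_start[plus]
  ann$utr5_start[!plus] <- ann$cds_end[!plus]
  ann$utr5_end[!plus] <- ann$tss[!plus] + 1L
  ann$utr5_start[!ann$has_tss] <- ann$utr5_end[!ann$has_tss] <- NA_integer_
  ann$utr3_start <- ifelse(plus, ann$cds_end, ann$cds_start - utr3_length)
  ann$utr3_end <- ifelse(plus, ann$cds_end + utr3_length, ann$cds_start)
  ann$utr3_start <- as.integer(ann$utr3_start)
  ann$utr3_end <- as.integer(ann$utr3_end)

  validate_gene_annotation(ann)
}

#' Validate a gene_annotation data.frame
#'
#' Checks the gene-model invariants: CDS start < end, TSS on the correct side
#' of the CDS for the strand, UTR interval consistency, and operon/subunit
#' pairing.
#'
#' @param ann a data.frame with the `gene_annotation` columns.
#' @return `ann`, with class `c("gene_annotation", "data.frame")`.
#' @export
validate_gene_annotation <- function(ann) {
  stopifnot(is.data.frame(ann))
  if (anyDuplicated(ann$gene_id))
    stop("duplicated gene_id: ", ann$gene_id[duplicated(ann$gene_id)][1])
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  bad <- ann$cds_start >= ann$cds_end
  if (any(bad))
    stop("CDS start must be < end for gene ", ann$gene_id[which(bad)[1]])
  with_tss <- which(ann$has_tss)
  for (i in with_tss) {
    if (ann$strand[i] == "+" && ann$tss[i] > ann$cds_start[i])
      stop("TSS downstream of CDS start on + strand for gene ", ann$gene_id[i])
    if (ann$strand[i] == "-" && ann$tss[i] < ann$cds_end[i] - 1L)
      stop("TSS downstream of CDS end on - strand for gene ", ann$gene_id[i])
  }
  op <- !is.na(ann$operon_id)
  su <- !is.na(ann$subunit_index)
  if (any(op != su))
    stop("subunit_index must be present iff operon_id is (gene ",
         ann$gene_id[which(op != su)[1]], ")")
  if (any(ann$subunit_index[su] < 1L))
    stop("subunit_index must be a positive integer")
  canon <- c("gene_id", "contig", "strand", "cds_start", "cds_end", "tss",
             "has_tss", "utr5_start", "utr5_end", "utr3_start", "utr3_end",
             "operon_id", "subunit_index", "terms")
  ann <- ann[, c(canon, setdiff(names(ann), canon)), drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' 5'UTR lengths of a gene annotation
#'
#' @param ann a `gene_annotation`.
#' @return integer vector, `NA` for genes without a TSS.  Length 0 marks a
#'   leaderless gene (TSS at the CDS boundary).
#' @export
utr5_length <- function(ann) {
  ifelse(ann$has_tss, ann$utr5_end - ann$utr5_start, NA_integer_)
}
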