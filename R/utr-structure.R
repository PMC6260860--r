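#' Extract 5'UTR sequences from a genome
#'
#' Strand-aware: minus-strand UTRs are reverse-complemented so all sequences
#' read 5' to 3', and DNA is transcribed to the RNA alphabet (T -> U).
#' Genes without a TSS or with a zero-length UTR are skipped.
#'
#' @param annotation a [gene_annotation].
#' @param genome named character vector of contig sequences (DNA or RNA
#'   alphabet), e.g. from [read_fasta].
#' @return Named character vector of RNA sequences.
#' @export
extract_utr5 <- function(annotation, genome) {
  out <- character(0)
  for (k in seq_len(nrow(annotation))) {
    if (!annotation$has_tss[k]) next
    a <- annotation$utr5_start[k]; b <- annotation$utr5_end[k]
    if (b <= a) next
    ct <- annotation$contig[k]
    if (!ct %in% names(genome)) stop("contig ", ct, " absent from genome")
    s <- toupper(substr(genome[[ct]], a + 1L, b))
    if (annotation$strand[k] == "-") s <- revcomp_dna(chartr("U", "T", s))
    out[annotation$gene_id[k]] <- chartr("T", "U", s)
  }
  out
}

fold_param_env <- new.env(parent = emptyenv())

#' Folding energy parameters
#'
#' The stacking table ships as a TSV with the package (6 x 6, rows = closing
#' pair, columns = inner pair, kcal/mol); values are adapted from published
#' nearest-neighbor stacking estimates.  Loop terms are linear: hairpin
#' `a + b u`, bulge/interior `a + b (u1+u2)`, multiloop
#' `a + b k + c u`.  An alternative stacking table (same layout) can be
#' substituted via `stack_table`.
#'
#' @param stack_table path to a stacking-energy TSV; default is the packaged
#'   table.
#' @param hairpin_a,hairpin_b,interior_a,interior_b,multi_a,multi_b,multi_c
#'   loop penalty coefficients (kcal/mol).
#' @param maxloop largest number of unpaired nt in a bulge/interior loop.
#' @return List with `stack` (6 x 6 matrix) and `par` (named numeric).
#' @export
fold_params <- function(stack_table = NULL,
                        hairpin_a = 4.0, hairpin_b = 0.2,
                        interior_a = 2.5, interior_b = 0.3,
                        multi_a = 3.4, multi_b = 0.4, multi_c = 0.1,
                        maxloop = 30) {
  if (is.null(stack_table))
    stack_table <- system.file("extdata", "stack_energies.tsv",
                               package = "riboTE", mustWork = TRUE)
  tab <- read.delim(stack_table, row.names = 1, check.names = FALSE)
  stack <- as.matrix(tab)
  ord <- c("AU", "UA", "GC", "CG", "GU", "UG")
  stopifnot(all(ord %in% rownames(stack)), all(ord %in% colnames(stack)))
  stack <- stack[ord, ord]
  list(stack = stack,
       par = c(hairpin_a = hairpin_a, hairpin_b = hairpin_b,
               interior_a = interior_a, interior_b = interior_b,
               multi_a = multi_a, multi_b = multi_b, multi_c = multi_c,
               maxloop = maxloop))
}

default_fold_params <- function() {
  if (is.null(fold_param_env$default))
    fold_param_env$default <- fold_params()
  fold_param_env$default
}

#' Minimum-free-energy fold of one RNA sequence
#'
#' Zuker-style dynamic programming under a simplified nearest-neighbor
#' model: stacking energies from the packaged table, linear hairpin,
#' bulge/interior and multiloop penalties, minimum hairpin loop of 3 nt,
#' pairs AU/UA/GC/CG/GU/UG, no pseudoknots.  The empty structure scores 0,
#' so the reported free energy is always <= 0, with 0 exactly when no pair
#' is formed.  Tie-breaking in the traceback is deterministic.
#'
#' @param sequence RNA (or DNA; T is read as U) string, length >= 1.
#' @param params energy parameters from [fold_params].
#' @return List with `sequence` (RNA alphabet), `structure` (dot-bracket),
#'   `delta_g` (kcal/mol), `n_pairs`, `length`, and `short` (TRUE for
#'   sequences under 8 nt, which are trivially unstructured).
#' @export
fold_mfe <- function(sequence, params = default_fold_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) >= 1)
  seq_rna <- chartr("T", "U", toupper(sequence))
  bad <- regexpr("[^ACGU]", seq_rna)
  if (bad > 0)
    stop("invalid character '", substr(seq_rna, bad, bad),
         "' at position ", bad)
  res <- .fold_mfe_cpp(seq_rna, params$stack, params$par)
  list(sequence = seq_rna,
       structure = res$structure,
       delta_g = res$energy,
       n_pairs = sum(strsplit(res$structure, "")[[1]] == "("),
       length = nchar(seq_rna),
       short = nchar(seq_rna) < 8)
}

#' Fold a set of 5'UTR sequences
#'
#' @param seqs named character vector of RNA sequences (e.g. from
#'   [extract_utr5]).
#' @param params energy parameters from [fold_params].
#' @return data.frame with `gene_id`, `length`, `delta_g`, `n_pairs`,
#'   `structure`, `short`.
#' @export
fold_utr5 <- function(seqs, params = default_fold_params()) {
  folds <- lapply(seqs, fold_mfe, params = params)
  data.frame(
    gene_id = names(seqs),
    length = vapply(folds, `[[`, 1L, "length"),
    delta_g = vapply(folds, `[[`, 1.0, "delta_g"),
    n_pairs = vapply(folds, `[[`, 1L, "n_pairs"),
    structure = vapply(folds, `[[`, "", "structure"),
    short = vapply(folds, `[[`, TRUE, "short"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare 5'UTR folding stability between TE classes
#'
#' Two-sided Wilcoxon rank-sum test of the folding free energies between
#' two TE classes (exact when both groups have <= 25 genes and no ties).
#'
#' @param folds result of [fold_utr5].
#' @param te result of [te_results] (provides `te_class`).
#' @param classes character(2): the TE classes to compare.
#' @return List with `classes`, `n`, `medians` (kcal/mol), `statistic`,
#'   `pvalue`, `method` and the per-class `delta_g` samples.
#' @export
compare_classes <- function(folds, te, classes = c("up", "down")) {
  m <- merge(folds[, c("gene_id", "delta_g")],
             te[, c("gene_id", "te_class")], by = "gene_id")
  g1 <- m$delta_g[m$te_class == classes[1]]
  g2 <- m$delta_g[m$te_class == classes[2]]
  if (!length(g1) || !length(g2))
    stop("empty TE class in comparison")
  w <- wilcoxon_ranksum(g1, g2)
  list(classes = classes, n = c(length(g1), length(g2)),
       medians = c(median(g1), median(g2)),
       statistic = w$statistic, pvalue = w$pvalue, method = w$method,
       samples = list(g1, g2))
}
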