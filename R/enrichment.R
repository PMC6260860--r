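#' Hypergeometric term enrichment
#'
#' For each functional term, tests whether the DEG set is enriched for
#' genes carrying the term: upper-tail hypergeometric p-value with
#' parameters k (DEGs with the term), K (universe genes with the term),
#' n (DEGs in the universe), N (universe size), BH-adjusted across terms.
#' The universe is the annotated genes of the supplied table (not the
#' genome), which avoids unannotated-gene bias.  Terms annotated to fewer
#' than `k_min` universe genes are excluded.
#'
#' @param deg_set character vector of gene ids.
#' @param gene2term data.frame with columns `gene_id`, `term_id` (one row
#'   per assignment), or a [gene_annotation] (its `terms` column is used).
#' @param k_min minimum universe genes per term (default 3).
#' @return data.frame with `term_id`, `k`, `K`, `n`, `N`, `pvalue`, `padj`,
#'   ordered by p-value.
#' @export
hypergeom_enrich <- function(deg_set, gene2term, k_min = 3) {
  g2t <- as_gene2term(gene2term)
  universe <- unique(g2t$gene_id)
  N <- length(universe)
  degs <- intersect(unique(deg_set), universe)
  n <- length(degs)
  terms <- split(g2t$gene_id, g2t$term_id)
  terms <- lapply(terms, unique)
  K <- lengths(terms)
  keep <- K >= k_min
  terms <- terms[keep]; K <- K[keep]
  if (!length(terms)) stop("no term with >= ", k_min, " annotated genes")
  k <- vapply(terms, function(gs) length(intersect(gs, degs)), 1L)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = names(terms), k = k, K = K, n = n, N = N,
                    pvalue = p, padj = benjamini_hochberg(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$pvalue, out$term_id), ]
}

as_gene2term <- function(x) {
  if (inherits(x, "gene_annotation")) {
    n <- lengths(x$terms)
    return(data.frame(gene_id = rep(x$gene_id, n),
                      term_id = unlist(x$terms, use.names = FALSE),
                      stringsAsFactors = FALSE))
  }
  x <- as.data.frame(x)
  if (!all(c("gene_id", "term_id") %in% names(x)))
    stop("gene2term needs columns gene_id, term_id")
  x[, c("gene_id", "term_id")]
}

#' Cohen's kappa between two binary membership vectors
#'
#' Chance-corrected agreement from the 2 x 2 confusion matrix.  When the
#' expected agreement is 1 (both vectors constant), kappa is defined as 1
#' for identical vectors and 0 otherwise.
#'
#' @param a,b logical vectors of equal length.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  N <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (1 - pe < 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Kappa matrix over enriched terms
#'
#' Pairwise Cohen's kappa between the terms' binary gene-membership vectors
#' restricted to the DEG universe.
#'
#' @param term_ids terms to compare.
#' @param gene2term assignment table or [gene_annotation].
#' @param deg_set DEG gene ids defining the membership universe.
#' @return Symmetric matrix with unit diagonal.
#' @export
kappa_matrix <- function(term_ids, gene2term, deg_set) {
  g2t <- as_gene2term(gene2term)
  degs <- sort(unique(deg_set))   # the DEG universe; unannotated DEGs count
                                  # as non-members of every term
  memb <- vapply(term_ids, function(t)
    degs %in% g2t$gene_id[g2t$term_id == t], logical(length(degs)))
  k <- length(term_ids)
  K <- diag(1, k)
  dimnames(K) <- list(term_ids, term_ids)
  if (k >= 2) for (i in 1:(k - 1)) for (j in (i + 1):k)
    K[i, j] <- K[j, i] <- cohen_kappa(memb[, i], memb[, j])
  K
}

#' Group enriched terms by kappa score
#'
#' Builds a graph with an edge wherever the pairwise kappa reaches the
#' threshold.  Groups are the connected components of that graph after
#' removing articulation terms (terms whose removal disconnects their
#' component); each articulation term is then assigned to every adjacent
#' subgroup — its first assignment is primary, the rest secondary,
#' mirroring terms shared by two groups.  Graphs without articulation
#' points reduce to plain connected components.  Singleton terms form their
#' own groups.
#'
#' @param kappa symmetric kappa matrix from [kappa_matrix].
#' @param kappa_threshold edge threshold (default 0.4).
#' @return data.frame with `term_id`, `group`, `secondary_groups`
#'   (comma-separated, empty for most terms).
#' @export
kappa_cluster <- function(kappa, kappa_threshold = 0.4) {
  terms <- rownames(kappa)
  adj <- kappa >= kappa_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  arts <- names(igraph::articulation_points(g))
  g_core <- igraph::delete_vertices(g, arts)
  comp <- igraph::components(g_core)$membership
  # stable group numbering by first term in each component
  first <- tapply(seq_along(comp), comp, min)
  renum <- setNames(rank(first), names(first))
  group <- setNames(rep(NA_integer_, length(terms)), terms)
  group[names(comp)] <- as.integer(renum[as.character(comp)])
  sec <- setNames(rep("", length(terms)), terms)
  next_group <- max(c(0L, group), na.rm = TRUE)
  for (a in arts) {
    nb <- terms[adj[a, ]]
    gs <- sort(unique(group[nb[!nb %in% arts]]))
    gs <- gs[!is.na(gs)]
    if (!length(gs)) { next_group <- next_group + 1L; group[a] <- next_group; next }
    group[a] <- gs[1]
    if (length(gs) > 1) sec[a] <- paste(gs[-1], collapse = ",")
  }
  data.frame(term_id = terms, group = unname(group[terms]),
             secondary_groups = unname(sec[terms]),
             stringsAsFactors = FALSE, row.names = NULL)
}
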