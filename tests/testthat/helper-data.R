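# Shared fixture builders.

# minimal 2-condition x 2-assay x nrep sample table
sample_table <- function(nrep = 2) {
  s <- expand.grid(replicate = seq_len(nrep),
                   assay = c("mRNA", "RPF"),
                   condition = c("autotrophic", "heterotrophic"),
                   stringsAsFactors = FALSE)
  s <- s[order(factor(s$condition, c("autotrophic", "heterotrophic")),
               factor(s$assay, c("mRNA", "RPF")), s$replicate), ]
  s$sample_id <- paste(substr(s$condition, 1, 4), s$assay, s$replicate, sep = "_")
  rownames(s) <- NULL
  s[, c("sample_id", "condition", "assay", "replicate")]
}

# count matrix with specified per-cell means (het/auto x mRNA/RPF), exact
# counts equal to the means (no noise) unless noise function given
cm_from_means <- function(mh, ma, rh, ra, nrep = 2) {
  n <- length(mh)
  s <- sample_table(nrep)
  m <- matrix(0L, n, nrow(s),
              dimnames = list(sprintf("g%03d", seq_len(n)), s$sample_id))
  for (j in seq_len(nrow(s))) {
    mu <- if (s$condition[j] == "heterotrophic") {
      if (s$assay[j] == "mRNA") mh else rh
    } else {
      if (s$assay[j] == "mRNA") ma else ra
    }
    m[, j] <- as.integer(round(mu))
  }
  count_matrix(m, s)
}

# two-group (one assay) count matrix from explicit columns
cm_mrna_only_groups <- function(het_cols, auto_cols) {
  n <- nrow(het_cols)
  k1 <- ncol(het_cols); k2 <- ncol(auto_cols)
  s <- data.frame(
    sample_id = c(paste0("auto_mRNA_", seq_len(k2)),
                  paste0("het_mRNA_", seq_len(k1))),
    condition = c(rep("autotrophic", k2), rep("heterotrophic", k1)),
    assay = "mRNA",
    replicate = c(seq_len(k2), seq_len(k1)),
    stringsAsFactors = FALSE)
  m <- cbind(auto_cols, het_cols)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n)), s$sample_id)
  count_matrix(m, s)
}
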