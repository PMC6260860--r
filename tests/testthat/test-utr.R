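test_that("5'UTR extraction is strand-aware and transcribes to RNA", {
  ann <- gene_annotation("gp", "c1", "+", cds_start = 4, cds_end = 10, tss = 0)
  genome <- c(c1 = "ACGTAACGTA")
  expect_equal(unname(extract_utr5(ann, genome)["gp"]), "ACGU")

  # minus-strand mirror of the same UTR: reverse complement at the other end
  ann2 <- gene_annotation("gm", "c1", "-", cds_start = 0, cds_end = 6, tss = 9)
  genome2 <- c(c1 = paste0("ACGTAA", "ACGT"))  # [6,10) = ACGT; revcomp = ACGT
  expect_equal(unname(extract_utr5(ann2, genome2)["gm"]), "ACGU")

  # leaderless genes yield no sequence
  ann3 <- gene_annotation("gl", "c1", "+", cds_start = 4, cds_end = 10, tss = 4)
  expect_length(extract_utr5(ann3, genome), 0)
})

test_that("fold_mfe handles trivial and hand-evaluated cases", {
  f <- fold_mfe("AAAAAA")
  expect_equal(f$delta_g, 0)
  expect_equal(f$structure, "......")
  expect_equal(f$n_pairs, 0)

  # GC stem of 3 closing a 4-nt loop: two GC/GC stacks + hairpin penalty,
  # summed by hand from the shipped parameter table
  pars <- fold_params()
  expected <- 2 * pars$stack["GC", "GC"] +
    pars$par[["hairpin_a"]] + 4 * pars$par[["hairpin_b"]]
  f2 <- fold_mfe("GGGAAAACCC")
  expect_equal(f2$delta_g, unname(expected))
  expect_equal(f2$structure, "(((....)))")

  expect_error(fold_mfe("ACGX"), "invalid character 'X' at position 4")
  expect_true(fold_mfe("ACGUACG")$short)
})

test_that("the DP optimum equals exhaustive enumeration on short sequences", {
  pars <- fold_params()
  set.seed(7)
  for (r in 1:150) {
    s <- random_rna(sample(5:12, 1))
    expect_equal(fold_mfe(s)$delta_g, oracle_mfe(s, pars), tolerance = 1e-9,
                 label = s)
  }
})

test_that("the reported structure is valid and achieves the reported energy", {
  pars <- fold_params()
  set.seed(9)
  for (r in 1:40) {
    s <- random_rna(sample(8:40, 1))
    f <- fold_mfe(s)
    db <- strsplit(f$structure, "")[[1]]
    expect_equal(sum(db == "("), sum(db == ")"))
    # parse pairs and score with the independent evaluator
    stack <- integer(0); pairs <- list()
    for (i in seq_along(db)) {
      if (db[i] == "(") stack <- c(stack, i)
      if (db[i] == ")") {
        pairs[[length(pairs) + 1]] <- c(stack[length(stack)], i)
        stack <- stack[-length(stack)]
      }
    }
    e <- if (length(pairs)) oracle_energy(f$sequence, pairs, pars) else 0
    expect_equal(f$delta_g, e, tolerance = 1e-6)
    expect_equal(f$delta_g == 0, length(pairs) == 0)
  }
})

test_that("free energy never increases when the sequence is extended", {
  set.seed(11)
  for (r in 1:15) {
    s <- random_rna(sample(10:25, 1))
    ext <- paste0(s, random_rna(sample(3:10, 1)))
    expect_lte(fold_mfe(ext)$delta_g, fold_mfe(s)$delta_g + 1e-9)
  }
})

test_that("Wilcoxon rank-sum: fixed points, oracle and wilcox.test agreement", {
  # identical samples: p = 1
  x <- c(1, 2, 3, 4)
  expect_equal(wilcoxon_ranksum(x, x)$pvalue, 1)

  # strong shift is highly significant
  set.seed(13)
  a <- rnorm(30, 0, 1); b <- rnorm(30, -5, 1)
  expect_lt(wilcoxon_ranksum(a, b)$pvalue, 1e-4)

  # exact path equals full permutation enumeration at n = (5, 5)
  set.seed(17)
  for (r in 1:10) {
    x <- round(rnorm(5), 6); y <- round(rnorm(5, 0.5), 6)
    w <- wilcoxon_ranksum(x, y)
    expect_equal(w$method, "exact")
    pooled <- c(x, y)
    idx <- utils::combn(10, 5)
    us <- apply(idx, 2, function(ii)
      sum(rank(pooled)[ii]) - 5 * 6 / 2)
    u_obs <- sum(rank(pooled)[1:5]) - 15
    p_enum <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
    expect_equal(w$pvalue, p_enum, tolerance = 1e-12)
    # and the established implementation agrees on the exact path
    expect_equal(w$pvalue, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("TE classes are separated by their folding energies", {
  # class B = class A shifted by -5 kcal/mol
  set.seed(19)
  a <- -runif(30, 0, 4)
  b <- a - 5
  folds <- data.frame(gene_id = paste0("g", 1:60), delta_g = c(a, b))
  te <- data.frame(gene_id = paste0("g", 1:60),
                   te_class = rep(c("up", "down"), each = 30))
  cc <- compare_classes(folds, te)
  expect_lt(cc$pvalue, 1e-4)
  expect_equal(cc$medians[1] - cc$medians[2], 5, tolerance = 1e-9)

  # identical per-class samples: p = 1
  folds2 <- data.frame(gene_id = paste0("g", 1:20), delta_g = rep(a[1:10], 2))
  te2 <- data.frame(gene_id = paste0("g", 1:20),
                    te_class = rep(c("up", "down"), each = 10))
  expect_equal(compare_classes(folds2, te2)$pvalue, 1)
})
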