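test_that("count simulation is reproducible and respects the null model", {
  cfg <- sim_config(n_genes = 50, seed = 123)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)

  # different seed differs
  c2 <- simulate_counts(sim_config(n_genes = 50, seed = 124))
  expect_false(identical(a$counts$counts, c2$counts$counts))

  # null model, near-Poisson, many replicates: group means near q
  cfg0 <- sim_config(n_genes = 200, n_replicates = 20, seed = 3,
                     frac_de = 0, frac_te = 0, dispersion = 1e-13,
                     base_mean_log_range = c(6, 8))
  sim0 <- simulate_counts(cfg0)
  s <- sim0$counts$samples
  for (cell in split(seq_len(nrow(s)), paste(s$condition, s$assay))) {
    m <- rowMeans(sim0$counts$counts[, cell])
    mu <- sim0$truth$q * 2^(sim0$truth$gamma *
                              (s$assay[cell[1]] == "RPF"))
    se <- sqrt(mu / length(cell))
    expect_true(mean(abs(m - mu) <= 3 * se) > 0.95)
  }
})

test_that("replication is required", {
  expect_error(sim_config(n_replicates = 1), "n_replicates")
})

test_that("latent effect sizes carry the buffering correlation", {
  cfg <- sim_config(n_genes = 2000, frac_de = 0.3, frac_te = 0.3,
                    buffering_rho = -0.5, seed = 42)
  sim <- simulate_counts(cfg)
  r_lat <- cor(sim$truth$beta_latent, sim$truth$delta_latent)
  expect_lt(abs(r_lat - (-0.5)), 0.1)
  both <- sim$truth$is_de & sim$truth$is_te
  expect_lt(abs(cor(sim$truth$beta[both], sim$truth$delta[both]) - (-0.5)), 0.1)
})

test_that("simulated annotation has valid operon pairs and UTR lengths", {
  cfg <- sim_config(n_genes = 60, n_operons = 10, seed = 7,
                    utr5_length_range = c(25L, 80L))
  ann <- simulate_annotation(cfg)
  expect_s3_class(ann, "gene_annotation")
  ops <- table(ann$operon_id)
  expect_length(ops, 10)
  expect_true(all(ops == 2))
  for (o in names(ops)) {
    pair <- which(ann$operon_id == o)
    expect_equal(diff(pair), 1L)  # adjacent genes
    expect_equal(sort(ann$subunit_index[pair]), 1:2)
  }
  lens <- utr5_length(ann)
  expect_true(all(lens >= 25 & lens <= 80))
})

test_that("planted hairpins are found by the folding engine", {
  cfg <- sim_config(n_genes = 80, n_operons = 0, seed = 11, frac_te = 0.6,
                    lfc_te_sd = 2, hairpin_stem_range = c(8L, 8L))
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  utr <- simulate_utr_sequences(cfg, ann, sim$truth)
  planted <- names(utr$stem_len)[utr$stem_len == 8]
  expect_gte(length(planted), 3)
  expect_true(all(utr$stem_len %in% c(0L, 8L)))
  folds <- fold_utr5(utr$utr5[planted])
  expect_true(all(folds$n_pairs >= 8))
})

test_that("UTR sequences differ across seeds but not across calls", {
  cfg1 <- sim_config(n_genes = 20, n_operons = 0, seed = 1)
  cfg2 <- sim_config(n_genes = 20, n_operons = 0, seed = 2)
  ann1 <- simulate_annotation(cfg1)
  sim1 <- simulate_counts(cfg1, ann1)
  u_a <- simulate_utr_sequences(cfg1, ann1, sim1$truth)
  u_b <- simulate_utr_sequences(cfg1, ann1, sim1$truth)
  expect_identical(u_a$utr5, u_b$utr5)
  ann2 <- simulate_annotation(cfg2)
  sim2 <- simulate_counts(cfg2, ann2)
  u_c <- simulate_utr_sequences(cfg2, ann2, sim2$truth)
  expect_false(identical(unname(u_a$utr5[1]), unname(u_c$utr5[1])))
})

test_that("planted UTRs are recoverable from the simulated genome", {
  cfg <- sim_config(n_genes = 30, n_operons = 5, seed = 21)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  utr <- simulate_utr_sequences(cfg, ann, sim$truth)
  extracted <- extract_utr5(ann, utr$genome)
  expect_equal(extracted[names(utr$utr5)], utr$utr5)
})

test_that("coverage follows the Poisson region rates", {
  cfg <- sim_config(n_genes = 40, n_operons = 0, seed = 31,
                    base_mean_log_range = c(8, 10), coverage_scale = 0.05)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)

  # u = 0: no 5'UTR coverage at all
  tr0 <- simulate_coverage(cfg, ann, sim$truth, "heterotrophic", u = 0)
  utr_cov <- unlist(lapply(seq_len(nrow(ann)), function(k)
    track_slice(tr0, ann$utr5_start[k], ann$utr5_end[k])))
  expect_true(all(utr_cov == 0))

  # u = 1: mean UTR/CDS ratio close to 1
  tr1 <- simulate_coverage(cfg, ann, sim$truth, "heterotrophic", u = 1)
  ratios <- vapply(seq_len(nrow(ann)), function(k) {
    u <- mean(track_slice(tr1, ann$utr5_start[k], ann$utr5_end[k]))
    cds <- mean(track_slice(tr1, ann$cds_start[k], ann$cds_end[k]))
    u / cds
  }, 1.0)
  expect_lt(abs(mean(ratios, na.rm = TRUE) - 1), 0.1)

  # determinism
  tr2 <- simulate_coverage(cfg, ann, sim$truth, "heterotrophic", u = 1)
  expect_identical(tr1$values, tr2$values)
})
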