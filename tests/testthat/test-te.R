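test_that("TE point estimates follow the RPF/mRNA ratio arithmetic", {
  cm <- cm_from_means(mh = c(100, 100), ma = c(100, 100),
                      rh = c(100, 50), ra = c(100, 200))
  te <- compute_te(cm, rep(1, 8))
  expect_equal(te$te_het, c(1, 0.5))
  expect_equal(te$te_auto, c(1, 2))
  expect_equal(te$te_log2fc, c(0, 2))

  # genes under the mRNA floor are excluded and flagged
  cm2 <- cm_from_means(mh = c(100, 0.4), ma = c(100, 0.4),
                       rh = c(50, 10), ra = c(50, 10))
  te2 <- compute_te(cm2, rep(1, 8), mrna_floor = 1)
  expect_false(te2$excluded[1])
  expect_true(te2$excluded[2])
  expect_true(is.na(te2$te_log2fc[2]))

  # missing assay errors
  cmr <- subset_samples(cm, assay = "mRNA")
  expect_error(compute_te(cmr, rep(1, 4)), "missing assay")
})

test_that("te_log2fc equals RPF log2FC minus mRNA log2FC", {
  cfg <- sim_config(n_genes = 200, seed = 15, frac_de = 0.3, frac_te = 0.3,
                    base_mean_log_range = c(5, 9), dispersion = 0.05)
  sim <- simulate_counts(cfg)
  sf <- estimate_size_factors(sim$counts)
  te <- compute_te(sim$counts, sf, mrna_floor = 0)
  de_m <- nb_wald_test(sim$counts, sf,
                       setNames(sim$truth$alpha, sim$truth$gene_id),
                       assay = "mRNA")
  de_r <- nb_wald_test(sim$counts, sf,
                       setNames(sim$truth$alpha, sim$truth$gene_id),
                       assay = "RPF")
  # ratio-of-means identity holds exactly on the point estimates
  expect_equal(te$te_log2fc,
               log2(te$rpf_auto / te$rpf_het) - log2(te$mrna_auto / te$mrna_het),
               tolerance = 1e-9)
  # and tracks the difference of the per-assay Wald estimates closely
  expect_lt(median(abs(te$te_log2fc - (de_r$log2fc - de_m$log2fc))), 0.1)
})

test_that("TE is invariant to a common library scaling", {
  cfg <- sim_config(n_genes = 100, seed = 19, dispersion = 0.05)
  sim <- simulate_counts(cfg)
  sf1 <- estimate_size_factors(sim$counts)
  te1 <- compute_te(sim$counts, sf1, mrna_floor = 0)
  cm2 <- count_matrix(sim$counts$counts * 3L, sim$counts$samples)
  te2 <- compute_te(cm2, estimate_size_factors(cm2), mrna_floor = 0)
  # genes with a zero cell mean take the pseudo-count, which is not scale
  # free; the ratio estimate on expressed genes is exactly invariant
  pos <- te1$mrna_het > 0 & te1$mrna_auto > 0 &
    te1$rpf_het > 0 & te1$rpf_auto > 0
  expect_equal(te2$te_log2fc[pos], te1$te_log2fc[pos], tolerance = 1e-9)
})

test_that("planted TE effects are recovered with small bias", {
  cfg <- sim_config(n_genes = 500, seed = 23, frac_de = 0.3, frac_te = 0.4,
                    lfc_te_sd = 1.5, base_mean_log_range = c(7, 10),
                    dispersion = 0.05)
  sim <- simulate_counts(cfg)
  sf <- estimate_size_factors(sim$counts)
  te <- te_results(sim$counts, sf,
                   setNames(sim$truth$alpha, sim$truth$gene_id))
  err <- te$te_log2fc - sim$truth$delta
  expect_lt(abs(median(err, na.rm = TRUE)), 0.1)
})

test_that("the interaction test has power and resists buffering confounds", {
  # strong condition effect in BOTH assays, delta = 0: mostly non-significant
  set.seed(27)
  n <- 200
  mk <- function(mu) matrix(rnbinom(2 * n, mu = mu, size = 1 / 0.05), n, 2)
  cm <- cm_from_means(mh = rep(1, n), ma = rep(1, n),
                      rh = rep(1, n), ra = rep(1, n))  # shape only
  m <- cbind(mk(4000), mk(4000), mk(500), mk(500))  # auto mRNA, RPF; het mRNA, RPF
  dimnames(m) <- dimnames(cm$counts)
  cm <- count_matrix(m, cm$samples)
  tt <- te_interaction_test(cm, rep(1, 8), setNames(rep(0.05, n), rownames(m)))
  expect_gte(mean(tt$pvalue > 0.05), 0.9)

  # planted delta = 2 at high mean: overwhelmingly significant after BH
  m2 <- cbind(mk(1000), mk(4000), mk(1000), mk(1000))
  dimnames(m2) <- dimnames(cm$counts)
  cm2 <- count_matrix(m2, cm$samples)
  tt2 <- te_interaction_test(cm2, rep(1, 8), setNames(rep(0.05, n), rownames(m2)))
  expect_gte(mean(tt2$padj < 0.05), 0.9)
  expect_lt(abs(median(tt2$te_log2fc_mle) - 2), 0.2)
})

test_that("buffering correlation behaves at the fixed points", {
  de <- data.frame(gene_id = paste0("g", 1:50), log2fc = rnorm(50))
  te <- data.frame(gene_id = paste0("g", 1:50), te_log2fc = -de$log2fc)
  expect_equal(buffering_correlation(de, te)$rho, -1)

  cfg <- sim_config(n_genes = 2000, seed = 33, frac_de = 1, frac_te = 1,
                    buffering_rho = 0, dispersion = 0.02,
                    base_mean_log_range = c(7, 10))
  sim <- simulate_counts(cfg)
  sf <- estimate_size_factors(sim$counts)
  dem <- nb_wald_test(sim$counts, sf,
                      setNames(sim$truth$alpha, sim$truth$gene_id))
  tem <- compute_te(sim$counts, sf)
  bc <- buffering_correlation(dem, tem)
  expect_lt(abs(bc$rho), 0.1)
})

test_that("reporter relative TE reproduces the beta-galactosidase worked case", {
  meas <- data.frame(
    construct_id = c("c1647", "c1650", "c1491", "x"),
    mrna_fc = c(1.01, 20.91, 2.75, 1.0),
    protein_fc = c(0.62, 0.99, 3.90, 1.0))
  out <- reporter_relative_te(meas)
  expect_equal(out$relative_te, c(0.61, 0.05, 1.42, 1.00))
  expect_error(reporter_relative_te(
    data.frame(construct_id = "bad", mrna_fc = 0, protein_fc = 1)),
    "positive")
})
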