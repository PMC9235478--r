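test_that("the generator is deterministic given (seed, replicate)", {
  d <- sim_design(m_total = 2000, seed = 5)
  a <- simulate_panel(d, 3)
  b <- simulate_panel(d, 3)
  expect_identical(a$panel$Z, b$panel$Z)
  expect_identical(a$truth, b$truth)
  c1 <- simulate_panel(d, 4)
  expect_false(identical(a$panel$Z, c1$panel$Z))
  expect_identical(simulate_null_permuted(d, 2), simulate_null_permuted(d, 2))
})

test_that("a noise-only panel reproduces the target correlation and unit variances", {
  d <- sim_design(m_total = 50000, rho = 0.8, frac_specific_per_trait = 0,
                  frac_pleiotropic = 0, seed = 6)
  sim <- simulate_panel(d, 1)
  expect_true(all(sim$truth$class == "null"))
  S <- crossprod(sim$panel$Z) / nrow(sim$panel$Z)
  expect_lt(abs(cov2cor(S)[1, 2] - 0.8), 0.02)
  expect_lt(max(abs(diag(S) - 1)), 0.02)
})

test_that("class sizes and effect patterns follow the design", {
  d <- sim_design(m_total = 10000, p = 3, rho = 0.2,
                  effects = effect_dist("constant", value = 6), seed = 7)
  sim <- simulate_panel(d, 1)
  expect_equal(sum(sim$truth$class == "specific"), 3000)
  expect_equal(sum(sim$truth$class == "pleiotropic"), 1000)
  eff <- as.matrix(sim$truth[, c("eff_1", "eff_2", "eff_3")])
  spec <- sim$truth$class == "specific"
  expect_true(all(rowSums(eff[spec, ] != 0) == 1))
  expect_true(all(rowSums(eff[sim$truth$class == "pleiotropic", ] != 0) == 3))
  expect_true(all(eff[sim$truth$class == "null", ] == 0))
  # class label consistent with the zero pattern of the effect vector
  expect_true(all(eff[cbind(which(spec), sim$truth$trait[spec])] != 0))
})

test_that("constant-magnitude specific SNPs have the expected mean |z| on the affected trait", {
  d <- sim_design(m_total = 50000, rho = 0, p = 2,
                  effects = effect_dist("constant", value = 6), seed = 8)
  sim <- simulate_panel(d, 1)
  spec1 <- sim$truth$class == "specific" & sim$truth$trait == 1
  spec1[is.na(spec1)] <- FALSE
  expect_gte(sum(spec1), 4999)
  # |z| ~ |N(+-6, 1)|, so E|z| = 6 up to a negligible reflection term
  expect_lt(abs(mean(abs(sim$panel$Z[spec1, 1])) - 6), 0.05)
})

test_that("the permuted-null experiment is calibrated at the nominal 0.05 level", {
  d <- sim_design(m_total = 50000, rho = 0.8, n_replicates = 2, seed = 9)
  panel <- simulate_null_permuted(d, 1)
  model <- estimate_null_covariance(panel)
  polar <- to_polar(zca_cor_whiten(panel, model))
  p_r <- chi_sf(polar$r, 2)
  expect_gt(mean(p_r < 0.05), 0.04)
  expect_lt(mean(p_r < 0.05), 0.06)
  ks <- suppressWarnings(stats::ks.test(p_r, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("fpr_experiment summarises per-replicate fractions and shrinks with panel size", {
  d_small <- sim_design(m_total = 4000, rho = 0.5, n_replicates = 30, seed = 10)
  d_large <- sim_design(m_total = 16000, rho = 0.5, n_replicates = 30, seed = 10)
  r_small <- fpr_experiment(d_small, "permuted")
  r_large <- fpr_experiment(d_large, "permuted")
  expect_equal(length(r_small$per_replicate), 30)
  expect_lt(abs(r_small$mean - 0.05), 0.01)
  expect_lt(abs(r_large$mean - 0.05), 0.01)
  # binomial scaling: quadrupling m roughly halves the replicate SD
  expect_lt(r_large$sd, r_small$sd)
  ratio <- r_small$sd / r_large$sd
  expect_gt(ratio, 1.2); expect_lt(ratio, 3.3)
})

test_that("with sparse strong effects the pipeline separates pleiotropic from specific SNPs", {
  d <- sim_design(m_total = 20000, rho = 0, frac_specific_per_trait = 0.01,
                  frac_pleiotropic = 0.01,
                  effects = effect_dist("constant", value = 6), seed = 11)
  sim <- simulate_panel(d, 1)
  model <- estimate_null_covariance(sim$panel)
  res <- two_stage_select(to_polar(zca_cor_whiten(sim$panel, model)),
                          builtin_kappa_curve(2))
  pleio <- sim$truth$class == "pleiotropic"
  spec <- sim$truth$class == "specific"
  expect_gt(mean(res$shared_flag[pleio]), 0.8)
  expect_lt(mean(res$shared_flag[spec]), 0.1)
})

test_that("invalid designs are rejected", {
  expect_error(sim_design(m_total = 100), "m_total")
  expect_error(sim_design(frac_specific_per_trait = 0.4, frac_pleiotropic = 0.3),
               "sum to < 1")
  expect_error(sim_design(rho = 1), "rho")
})

test_that("simulated summary-statistic files round trip through the readers", {
  d <- sim_design(m_total = 1000, seed = 12)
  sim <- simulate_panel(d, 1)
  prefix <- tempfile()
  paths <- write_sim_sumstats(sim, prefix)
  scans <- lapply(seq_along(paths), function(k)
    read_sumstats(paths[k], sprintf("trait%d", k)))
  panel <- harmonize_and_merge(scans)
  expect_equal(nrow(panel$Z), 1000)
  expect_identical(panel$Z[, 1], unname(sim$panel$Z[, 1]))
})
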