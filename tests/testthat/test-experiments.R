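settings_fast <- mcmc_settings(n_steps = 4e4, convergence_window = 50,
                               convergence_slope_tol = 1e-5)

test_that("ensembles are seeded reproducibly and aggregate correctly", {
  p <- params_for_gamma(1)
  e1 <- run_ensemble(p, settings_fast, n_replicates = 3, master_seed = 7,
                     n = 12)
  e2 <- run_ensemble(p, settings_fast, n_replicates = 3, master_seed = 7,
                     n = 12)
  expect_identical(e1$replicates, e2$replicates)
  expect_identical(e1$replicates$seed, c(7L, 8L, 9L))
  expect_equal(e1$mean, mean(e1$replicates$mismatch))
  # single replicate: mean is that value, SEM undefined
  e3 <- run_ensemble(p, settings_fast, n_replicates = 1, master_seed = 3,
                     n = 12)
  expect_identical(e3$mean, e3$replicates$mismatch[1])
  expect_true(is.na(e3$sem))
  expect_error(run_ensemble(p, settings_fast, n_replicates = 0),
               "n_replicates")
})

test_that("no-adhesion ensembles equal the initial-condition mismatch", {
  # gamma = 0 single-type: equilibrium preserves the symmetric state, so
  # the steady-state mean stays near the initial mismatch on the same seeds
  p0 <- params_for_gamma(0)
  init <- initial_mismatch_ensemble(12, "all-T", n_replicates = 8,
                                    master_seed = 60)
  eq <- run_ensemble(p0, mcmc_settings(n_steps = 5e4), n_replicates = 8,
                     master_seed = 60, pattern = "all-T", n = 12)
  expect_lt(abs(eq$mean - init$mean),
            3 * sqrt(eq$sem^2 + init$sem^2) + 0.02)
})

test_that("size scaling vanishes at zero length variance", {
  lp0 <- length_params(T = c(5, 0), S = c(4, 0))
  tab <- sweep_size(c(2, 6, 12), n_replicates = 2, master_seed = 1, lp = lp0)
  expect_equal(tab$mean, c(0, 0, 0))
  expect_error(sweep_size(c(1, 6)), "n values")
})

test_that("two-cell size scaling matches an independent resampling oracle", {
  # independent route: plain-R rejection sampler + grid-overlap mismatch
  lp <- length_params(T = c(4, 0.4), S = c(6, 1.2))
  set.seed(71)
  oracle <- replicate(300, {
    L1 <- rnorm(2, 4, 0.4)
    while (any(L1 <= 0)) L1 <- rnorm(2, 4, 0.4)
    repeat {
      L2 <- rnorm(2, 4, 0.4)
      while (any(L2 <= 0)) L2 <- rnorm(2, 4, 0.4)
      if (abs(sum(L2) - sum(L1)) < mean(L1) * 1e-3) break
    }
    L2 <- L2 * sum(L1) / sum(L2)
    cfg <- toy_config(L1, L2)
    grid_tissue_mismatch(cfg, h = 5e-4)
  })
  pkg <- initial_mismatch_ensemble(2, "all-T", n_replicates = 300,
                                   master_seed = 72, lp = lp)
  se <- sqrt(var(oracle) / 300 + pkg$sem^2)
  expect_lt(abs(mean(oracle) - pkg$mean), 3 * se)
})

test_that("genotypes map onto gamma as the adhesion logic dictates", {
  wt <- genotype_to_params("WT", 0.25, 0.25)
  expect_identical(wt$gamma, 0.5)
  expect_identical(wt$pattern, "TTTTSS")
  expect_identical(genotype_to_params("svp_null")$gamma, 0)
  expect_identical(genotype_to_params("svp_null")$pattern, "all-T")
  expect_identical(genotype_to_params("double_null")$gamma, 0)
  expect_identical(genotype_to_params("fas3_null", 0.3, 0.2)$gamma, 0.2)
  expect_identical(genotype_to_params("tenm_null", 0.3, 0.2)$gamma, 0.3)
  expect_identical(genotype_to_params("svp_gal4_fas3_oe", 0.3, 0.2)$gamma,
                   0.2)
  expect_identical(genotype_to_params("svp_gal4_fas3_rnai", 0.3, 0.2)$gamma,
                   0.5)
  # additivity: gamma(WT) = gamma(fas3_null) + gamma(tenm_null), exactly
  expect_identical(wt$gamma,
                   genotype_to_params("fas3_null")$gamma +
                     genotype_to_params("tenm_null")$gamma)
  expect_error(genotype_to_params("nonsense"), "unknown genotype")
  expect_error(genotype_to_params("WT", -1, 0.2), ">= 0")
  # constructed eps triple realizes gamma
  expect_equal(adhesion_gamma(wt$params), 0.5)
})

test_that("gamma inference inverts the master curve with clamping flags", {
  curve <- structure(
    data.frame(gamma = c(0, 0.5, 1, 2),
               mean = c(0.30, 0.15, 0.10, 0.08),
               sem = c(0.01, 0.005, 0.004, 0.003)),
    class = c("gamma_curve", "data.frame"))
  # round-trip at a grid node
  expect_equal(infer_gamma(0.10, curve)$gamma, 1)
  # bracketing between nodes
  est <- infer_gamma(0.12, curve)
  expect_gt(est$gamma, 0.5)
  expect_lt(est$gamma, 1)
  # at or above the gamma = 0 level
  expect_identical(infer_gamma(0.30, curve)$gamma, 0)
  expect_identical(infer_gamma(0.35, curve)$flag, "clamped_at_zero")
  # below the plateau: lower bound at the grid edge
  lowest <- infer_gamma(0.01, curve)
  expect_identical(lowest$flag, "lower_bound")
  expect_identical(lowest$gamma, 2)
  # interval brackets the point estimate
  m <- 0.12
  est2 <- infer_gamma(m, curve, mismatch_sem = 0.01)
  expect_lte(est2$lower, est2$gamma)
  expect_gte(est2$upper, est2$gamma)
  expect_error(infer_gamma(0.1, curve[0, ]), "empty master curve")
})

test_that("noisy curves are monotone-regularized before inversion", {
  curve <- structure(
    data.frame(gamma = c(0, 0.5, 1, 2),
               mean = c(0.30, 0.12, 0.13, 0.08),  # non-monotone wiggle
               sem = rep(0.01, 4)),
    class = c("gamma_curve", "data.frame"))
  est <- infer_gamma(0.125, curve)
  expect_true(est$flag == "ok")
  expect_gte(est$gamma, 0.5)
  expect_lte(est$gamma, 2)
})

test_that("boundary offsets and defect patterns behave", {
  lp0 <- length_params(T = c(5, 0), S = c(4, 0))
  cfg <- deposit_rows(make_pattern("TTSS", 4), params = lp0)
  expect_identical(type_boundaries(cfg, 1), 10)
  bo <- boundary_offsets(cfg)
  expect_identical(bo$offsets, 0)
  expect_true(bo$matched)
  # differing patterns, equal N: offsets measured in order
  lp5 <- length_params(T = c(5, 0), S = c(5, 0))
  cfg2 <- deposit_rows(make_pattern("TTSS", 4), make_pattern("TSSS", 4),
                       params = lp5)
  bo2 <- boundary_offsets(cfg2)
  expect_identical(length(bo2$offsets), 1L)
  expect_identical(bo2$offsets, 5)  # row1 T|S at 10, row2 at 5
  # unequal cell counts are an infeasible defect
  expect_error(deposit_rows(make_pattern("TTTTSS", 10),
                            make_pattern("TTTTSS", 12)), "same cell count")
})

test_that("defect equilibration aligns type boundaries when gamma > 0", {
  s <- mcmc_settings(n_steps = 2e5, convergence_window = 200,
                     convergence_slope_tol = 1e-6)
  de <- defect_experiment("TTTTSS", "TTTSSS", params_for_gamma(2),
                          settings = s, n_replicates = 6, master_seed = 91,
                          n = 12)
  # on common seeds the mean boundary offset shrinks after equilibration
  expect_lt(mean(de$replicates$offset_final),
            mean(de$replicates$offset_initial))
  # identical patterns reduce to the plain ensemble readout
  de0 <- defect_experiment("TTTTSS", "TTTTSS", params_for_gamma(2),
                           settings = s, n_replicates = 2, master_seed = 5,
                           n = 12)
  expect_true(all(is.finite(de0$replicates$mismatch_final)))
})
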