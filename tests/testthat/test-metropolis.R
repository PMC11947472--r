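test_that("proposals pick interior vertices uniformly with Gaussian steps", {
  set.seed(1)
  cfg2 <- toy_config(c(1, 1), c(1, 1))
  for (k in 1:50) {
    mv <- propose_move(cfg2, 0.05)
    expect_identical(mv$i, 2L)  # N = 2: only the middle vertex
    expect_true(mv$row %in% c(1L, 2L))
  }
  expect_error(propose_move(toy_config(1, 1), 0.05), "no movable vertex")

  set.seed(2)
  cfg <- random_config(6, seed = 2)
  draws <- replicate(20000, {
    mv <- propose_move(cfg, 0.05)
    (mv$row - 1L) * 5L + (mv$i - 1L)
  })
  counts <- table(factor(draws, levels = c(1:5, 6:10)))
  # each of the 2(N-1) = 10 interior vertices at frequency 1/10 +/- 3 sigma
  p0 <- 1 / 10
  sigma <- sqrt(p0 * (1 - p0) / 20000)
  expect_true(all(abs(counts / 20000 - p0) < 3.5 * sigma))

  set.seed(3)
  dx <- replicate(50000, propose_move(cfg, 0.05)$dx)
  expect_lt(abs(mean(dx)), 3 * 0.05 / sqrt(50000))
  expect_lt(abs(sd(dx) / 0.05 - 1), 0.02)
})

test_that("forbidden moves are exactly the flips and in-row overlaps", {
  cfg <- toy_config(c(2, 1, 3), c(2, 1, 3))
  # vertex 2 bounds left cell length 2, right cell length 1
  expect_true(move_allowed(cfg, 1, 2, 0))
  expect_false(move_allowed(cfg, 1, 2, 1.5))   # beyond right cell
  expect_true(move_allowed(cfg, 1, 2, 1))      # to exactly zero length
  expect_true(move_allowed(cfg, 1, 2, -1.5))   # within left cell
  expect_false(move_allowed(cfg, 1, 2, -2.5))  # beyond left cell
  expect_true(move_allowed(cfg, 1, 3, -1))
})

test_that("acceptance probability implements the Metropolis rule", {
  expect_identical(acceptance_probability(-3, 0.1), 1)
  expect_identical(acceptance_probability(0, 0.1), 1)
  expect_equal(acceptance_probability(0.1, 0.1), exp(-1))
  expect_equal(acceptance_probability(1e6, 0.1), 0)
  expect_error(acceptance_probability(1, 0), "E0 must be > 0")
})

test_that("single steps preserve invariants and reject correctly", {
  set.seed(31)
  cfg <- random_config(6, seed = 31)
  p <- adhesion_params(1, 1, 0, 1)
  span <- max(cfg$x1)
  for (k in 1:200) {
    st <- mc_step(cfg, p, deltaX = 0.3, E0 = 0.1)
    if (!st$accepted) expect_identical(st$config, cfg)
    cfg <- st$config
    expect_identical(cfg$x1[1], 0)
    expect_identical(max(cfg$x1), span)
    expect_identical(max(cfg$x2), span)
    expect_true(all(diff(cfg$x1) >= 0))
    expect_true(all(diff(cfg$x2) >= 0))
  }
})

test_that("the compiled sampler is reproducible and conserves geometry", {
  set.seed(5)
  cfg <- deposit_rows(make_pattern("TTTTSS", 12))
  p <- params_for_gamma(1)
  s <- mcmc_settings(n_steps = 2e4, seed = 77, record_every = 100)
  t1 <- run_metropolis(cfg, p, s)
  t2 <- run_metropolis(cfg, p, s)
  expect_identical(t1$mismatch, t2$mismatch)
  expect_identical(t1$final_config$x1, t2$final_config$x1)
  fc <- t1$final_config
  expect_identical(max(fc$x1), max(cfg$x1))  # exact span conservation
  expect_identical(fc$x1[1], cfg$x1[1])
  expect_true(all(diff(fc$x1) >= 0))
  expect_true(all(t1$mismatch >= 0 & t1$mismatch <= 1))
  # recorded energy is the true total energy of the evolving state
  expect_equal(tail(t1$energy, 1), total_energy(fc, p), tolerance = 1e-9)
})

test_that("compiled and reference samplers agree move by move", {
  # same RNG stream: the C++ loop draws (row, vertex, dx[, accept]) in the
  # same order as propose_move + mc_step
  set.seed(8)
  cfg <- deposit_rows(make_pattern("TTTTSS", 6))
  p <- adhesion_params(0.8, 0.5, 0.1, 1)
  set.seed(55)
  ref <- cfg
  for (k in 1:500) ref <- mc_step(ref, p, deltaX = 0.1, E0 = 0.1)$config
  set.seed(55)
  out <- run_metropolis(cfg, p, mcmc_settings(deltaX = 0.1, E0 = 0.1,
                                              n_steps = 500,
                                              record_every = 500))
  expect_equal(out$final_config$x1, ref$x1, tolerance = 1e-12)
  expect_equal(out$final_config$x2, ref$x2, tolerance = 1e-12)
})

test_that("greedy descent emerges in the small-temperature limit", {
  set.seed(13)
  cfg <- deposit_rows(make_pattern("TTTTSS", 12))
  p <- params_for_gamma(2)
  tr <- run_metropolis(cfg, p, mcmc_settings(E0 = 1e-12, n_steps = 5e4,
                                             convergence_slope_tol = 0))
  # energy can only decrease (up to recording granularity)
  expect_true(all(diff(tr$energy) < 1e-9))
})

test_that("sampled moments match exact Boltzmann moments on a 2-DOF system", {
  L0a <- c(1.0, 1.2)
  L0b <- c(1.1, 1.1)
  span <- sum(L0a)
  cfg <- toy_config(L0a, L0b, c("S", "T"), c("S", "T"))
  p <- adhesion_params(1, 1, 0, 1)
  E0 <- 0.1
  Efun <- function(u, v) {
    (u - L0a[1])^2 + (span - u - L0a[2])^2 +
      (v - L0b[1])^2 + (span - v - L0b[2])^2 -
      (pmin(u, v) + (span - pmax(u, v)))
  }
  fine <- seq(5e-4, span - 5e-4, by = 1e-3)
  g <- expand.grid(u = fine, v = fine)
  w <- exp(-(Efun(g$u, g$v) - min(Efun(g$u, g$v))) / E0)
  w <- w / sum(w)
  exact <- c(mu = sum(w * g$u), sd = sqrt(sum(w * g$u^2) - sum(w * g$u)^2))
  set.seed(7)
  tr <- run_metropolis(cfg, p,
                       mcmc_settings(deltaX = sqrt(E0), E0 = E0,
                                     n_steps = 2e5, record_every = 10,
                                     convergence_slope_tol = 0),
                       record_positions = TRUE)
  u <- tr$positions1[-seq_len(4000), 2]
  expect_equal(mean(u), exact["mu"], tolerance = 0.01, ignore_attr = TRUE)
  expect_equal(sd(u), exact["sd"], tolerance = 0.05, ignore_attr = TRUE)
})

test_that("acceptance rate is non-increasing in the proposal scale", {
  set.seed(17)
  cfg <- deposit_rows(make_pattern("TTTTSS", 12))
  p <- params_for_gamma(1)
  rates <- vapply(c(0.02, 0.1, 0.5, 2), function(dX) {
    run_metropolis(cfg, p, mcmc_settings(deltaX = dX, n_steps = 3e4,
                                         seed = 9,
                                         convergence_slope_tol = 0))$acceptance_rate
  }, numeric(1))
  expect_true(all(diff(rates) <= 0.01))  # non-increasing within MC noise
})

test_that("steady-state summaries handle constant and short series", {
  traj <- list(mismatch = rep(0.3, 50))
  ss <- steady_state_mismatch(traj, 1)
  expect_identical(ss$mean, 0.3)
  expect_identical(ss$sem, 0)
  expect_equal(steady_state_mismatch(list(mismatch = c(0.2, 0.4)), 1)$mean,
               0.3)
  expect_error(steady_state_mismatch(list(mismatch = numeric(0))),
               "insufficient data")
})

test_that("steady-state SEM scales like 1/sqrt(n) for iid series", {
  set.seed(23)
  x <- rnorm(4000, 0.2, 0.01)
  s_full <- steady_state_mismatch(list(mismatch = x), 1)
  s_quarter <- steady_state_mismatch(list(mismatch = x[1:1000]), 1)
  expect_equal(s_quarter$sem / s_full$sem, 2, tolerance = 0.25)
})
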