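test_that("vertex force matches the closed form", {
  # left cell L=2 (L0=1), right cell L=1 (L0=1), K=100, tensions zero:
  # F = 100*log(1/1) - 100*log(2/1) = -69.31 pN (restores rest length)
  cfg <- toy_config(c(2, 1), c(2, 1), L0_1 = c(1, 1), L0_2 = c(2, 1))
  vp <- vertex_params(T_SS = 0, T_TT = 0, T_ST = 0, K = 100)
  expect_equal(vertex_force(cfg, 1, 2, vp), -100 * log(2), tolerance = 1e-12)
  # at rest with uniform tension everywhere, every force vanishes
  cfg0 <- random_config(6, seed = 41)
  vpu <- vertex_params(T_SS = -5, T_TT = -5, T_ST = -5, K = 100)
  for (i in 2:6) {
    expect_equal(vertex_force(cfg0, 1, i, vpu), 0, tolerance = 1e-10)
    expect_equal(vertex_force(cfg0, 2, i, vpu), 0, tolerance = 1e-10)
  }
  # degenerate geometry errors
  bad <- toy_config(c(0, 2), c(1, 1), L0_1 = c(1, 1), L0_2 = c(1, 1))
  expect_error(vertex_force(bad, 1, 2, vp), "degenerate")
})

test_that("negative tension pulls vertices to extend favorable contacts", {
  # row1 S|T boundary at 2, row2 at 3: between them the interface is S-T.
  # With T_SS = T_TT = -t0, T_ST = 0, row 1's boundary vertex should be
  # pulled right (extending its S-S contact), row 2's left.
  cfg <- toy_config(c(2, 3), c(3, 2), c("S", "T"), c("S", "T"))
  vp <- vertex_params(t0 = 100, K = 100)
  expect_gt(vertex_force(cfg, 1, 2, vp), 0)
  expect_lt(vertex_force(cfg, 2, 2, vp), 0)
})

test_that("the integrator matches the reference Euler step", {
  set.seed(43)
  cfg <- deposit_rows(make_pattern("TTTTSS", 8))
  cfg$x1[4] <- cfg$x1[4] + 0.3  # off-equilibrium start
  vp <- vertex_params(t0 = 500, K = 100, dt = 0.01, t_end = 0.01)
  ref <- euler_step(cfg, vp)
  out <- run_dynamics(cfg, vp, record_every = 1)
  expect_equal(out$final_config$x1, ref$x1, tolerance = 1e-12)
  expect_equal(out$final_config$x2, ref$x2, tolerance = 1e-12)
})

test_that("Euler steps are linear in force and friction", {
  set.seed(44)
  cfg <- deposit_rows(make_pattern("TTTTSS", 8))
  cfg$x2[3] <- cfg$x2[3] - 0.2
  vp <- vertex_params(t0 = 200, K = 100, dt = 0.01)
  d1 <- euler_step(cfg, vp)$x1 - cfg$x1
  vp2 <- vp
  vp2$xi <- 2 * vp$xi
  d2 <- euler_step(cfg, vp2)$x1 - cfg$x1
  expect_lt(max(abs(d1 - 2 * d2)), 1e-12)
  # zero tensions at rest: identity
  cfg0 <- random_config(6, seed = 45)
  vp0 <- vertex_params(T_SS = 0, T_TT = 0, T_ST = 0, K = 100)
  expect_equal(euler_step(cfg0, vp0)$x1, cfg0$x1, tolerance = 1e-12)
})

test_that("dynamics conserve span and ordering and stay in bounds", {
  set.seed(46)
  cfg <- deposit_rows(make_pattern("TTTTSS", 24))
  vp <- vertex_params(t0 = 2000, K = 100, t_end = 60)
  tr <- run_dynamics(cfg, vp)
  fc <- tr$final_config
  expect_identical(max(fc$x1), max(cfg$x1))
  expect_identical(max(fc$x2), max(cfg$x2))
  expect_true(all(diff(fc$x1) >= 0))
  expect_true(all(diff(fc$x2) >= 0))
  expect_true(all(tr$mismatch >= 0 & tr$mismatch <= 1))
  expect_identical(tr$time[1], 0)
  expect_true(all(diff(tr$time) > 0))
  # determinism (no RNG involved)
  tr2 <- run_dynamics(cfg, vp)
  expect_identical(tr$mismatch, tr2$mismatch)
})

test_that("halving dt changes the final mismatch only marginally", {
  set.seed(47)
  cfg <- deposit_rows(make_pattern("TTTTSS", 12))
  vp1 <- vertex_params(t0 = 1000, K = 100, dt = 0.01, t_end = 30)
  vp2 <- vertex_params(t0 = 1000, K = 100, dt = 0.005, t_end = 30)
  m1 <- tail(run_dynamics(cfg, vp1, record_every = 100)$mismatch, 1)
  m2 <- tail(run_dynamics(cfg, vp2, record_every = 200)$mismatch, 1)
  expect_lt(abs(m1 - m2), 1e-3)
})

test_that("per-type and per-row stiffness are resolved per cell", {
  set.seed(48)
  cfg <- deposit_rows(make_pattern("TTTTSS", 6))
  vp <- vertex_params(t0 = 100, K = c(S = 50, T = 200))
  # per-type K enters the elastic term of the matching cell
  cfg$x1[2] <- cfg$x1[2] + 0.3
  f <- vertex_force(cfg, 1, 2, vp)
  Ll <- cfg$x1[2] - cfg$x1[1]
  Lr <- cfg$x1[3] - cfg$x1[2]
  expect_equal(f, 200 * log(Lr / cfg$L0_1[2]) - 200 * log(Ll / cfg$L0_1[1]),
               tolerance = 1e-10)
  vp_rows <- vertex_params(t0 = 100, K = list(row1 = 100, row2 = 400),
                           t_end = 1)
  expect_silent(run_dynamics(cfg, vp_rows))
})

test_that("time to minimal mismatch handles plateaus and censoring", {
  expect_equal(
    time_to_min_mismatch(list(time = 0:10, mismatch = rep(0.2, 11)))$time, 0)
  # monotone decay ending at its minimum is censored
  tm <- time_to_min_mismatch(list(time = 0:10,
                                  mismatch = seq(1, 0.5, length.out = 11)),
                             tol_fraction = 0)
  expect_identical(tm$time, 10L)
  expect_true(tm$censored)
  # exponential decay: analytic crossing of the 1.05x asymptote level
  tt <- seq(0, 50, by = 0.01)
  a <- 0.1
  b <- 0.4
  tau <- 5
  m <- a + b * exp(-tt / tau)
  # trace minimum is m(50) ~ a; threshold 1.05 * min
  thr <- 1.05 * min(m)
  t_analytic <- -tau * log((thr - a) / b)
  got <- time_to_min_mismatch(list(time = tt, mismatch = m), 0.05)
  expect_equal(got$time, t_analytic, tolerance = 0.02)
  expect_error(time_to_min_mismatch(list(time = numeric(0),
                                         mismatch = numeric(0))), "empty")
})
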