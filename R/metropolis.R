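# Metropolis Monte-Carlo equilibration of a tissue configuration.
#
# One step is one proposal: a uniformly chosen interior vertex (2(N-1)
# candidates) is displaced by a Gaussian amount of standard deviation
# deltaX; moves that would flip a cell or overlap cells within a row are
# forbidden (acceptance probability 0); otherwise the move is accepted with
# probability min(1, exp(-dE/E0)).

#' Settings of the Metropolis sampler
#'
#' @param deltaX Proposal standard deviation (um). Default 0.05.
#' @param E0 Effective temperature (energy units). `NULL` (default) resolves
#'   at run time to `0.1 * K * 1 um^2`, i.e. E0/K = 0.1 um^2.
#' @param n_steps Proposal budget (hard cap). Default 2e6.
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @param record_every Record the trajectory every this many proposals;
#'   `NULL` resolves to `2 * (N - 1)` (about one sweep).
#' @param convergence_window Number of consecutive records used for the
#'   steady-state slope test.
#' @param convergence_slope_tol Absolute slope (mismatch per record) below
#'   which the chain is declared converged.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(deltaX = 0.05, E0 = NULL, n_steps = 2e6,
                          seed = NULL, record_every = NULL,
                          convergence_window = 1000,
                          convergence_slope_tol = 1e-6) {
  if (deltaX <= 0) stop("deltaX must be > 0")
  if (!is.null(E0) && E0 <= 0) stop("E0 must be > 0")
  if (n_steps < 1) stop("n_steps must be >= 1")
  structure(list(deltaX = deltaX, E0 = E0, n_steps = n_steps, seed = seed,
                 record_every = record_every,
                 convergence_window = convergence_window,
                 convergence_slope_tol = convergence_slope_tol),
            class = "mcmc_settings")
}

#' Propose a single vertex move
#'
#' Uniform choice among the `2 * (N - 1)` interior vertices (end vertices
#' are pinned and never proposed) and a Gaussian displacement.
#'
#' @param cfg A `tissue_config` with N >= 2.
#' @param deltaX Proposal standard deviation (um).
#' @return `list(row, i, dx)` with `i` in 2..N.
#' @export
propose_move <- function(cfg, deltaX = 0.05) {
  n <- n_cells(cfg)
  if (n < 2) stop("no movable vertex: need at least 2 cells per row")
  list(row = if (runif(1) < 0.5) 1L else 2L,
       i = 2L + min(as.integer(runif(1) * (n - 1)), n - 2L),
       dx = rnorm(1, 0, deltaX))
}

#' Is a vertex move allowed?
#'
#' Vertex `i` bounds cell `i - 1` on its left and cell `i` on its right.
#' Forbidden: `dx > 0` beyond the right cell's length, or `dx < 0` beyond
#' the left cell's length (strict inequalities: a move to exactly zero
#' length is allowed).
#'
#' @inheritParams apply_move
#' @return Logical.
#' @export
move_allowed <- function(cfg, row, i, dx) {
  n <- n_cells(cfg)
  if (i < 2 || i > n) stop("vertex must be interior (2..N)")
  x <- if (row == 1) cfg$x1 else cfg$x2
  L_right <- x[i + 1] - x[i]
  L_left <- x[i] - x[i - 1]
  !((dx > 0 && dx > L_right) || (dx < 0 && abs(dx) > L_left))
}

#' Metropolis acceptance probability
#'
#' `min(1, exp(-dE / E0))`.
#'
#' @param dE Energy change of the proposed move.
#' @param E0 Effective temperature (> 0).
#' @return Probability in `(0, 1]`.
#' @export
acceptance_probability <- function(dE, E0) {
  if (E0 <= 0) stop("E0 must be > 0")
  pmin(1, exp(-dE / E0))
}

#' One Metropolis step (reference implementation)
#'
#' Pure-R propose/evaluate/accept-reject cycle, used for small-system tests;
#' [run_metropolis()] uses the compiled sampler.
#'
#' @param cfg A `tissue_config`.
#' @param params An `adhesion_params` object.
#' @param deltaX Proposal standard deviation (um).
#' @param E0 Effective temperature.
#' @return `list(config, accepted, move, dE)`; on rejection the
#'   configuration is returned unchanged.
#' @export
mc_step <- function(cfg, params, deltaX = 0.05, E0 = 0.1 * params$K) {
  mv <- propose_move(cfg, deltaX)
  if (!move_allowed(cfg, mv$row, mv$i, mv$dx))
    return(list(config = cfg, accepted = FALSE, move = mv, dE = NA_real_))
  dE <- delta_energy(cfg, mv$row, mv$i, mv$dx, params)
  if (runif(1) < acceptance_probability(dE, E0))
    return(list(config = apply_move(cfg, mv$row, mv$i, mv$dx),
                accepted = TRUE, move = mv, dE = dE))
  list(config = cfg, accepted = FALSE, move = mv, dE = dE)
}

# Internal: OLS slope of y against record index.
.window_slope <- function(y) {
  x <- seq_along(y)
  x <- x - mean(x)
  sum(x * (y - mean(y))) / sum(x * x)
}

#' Run the Metropolis sampler
#'
#' Executes up to `n_steps` proposals, recording tissue mismatch and total
#' energy every `record_every` proposals (step 0 included). The chain stops
#' early once the absolute OLS slope of the mismatch over the last
#' `convergence_window` records falls below `convergence_slope_tol`
#' (checked after at least two windows have accumulated).
#'
#' @param config A `tissue_config`.
#' @param params An `adhesion_params` object.
#' @param settings An [mcmc_settings()] object.
#' @param record_positions Record full vertex trajectories (small systems
#'   only; used by sampling-accuracy tests).
#' @return An object of class `mcmc_trajectory`: list with `step`,
#'   `mismatch`, `energy` records, `acceptance_rate`, `converged`,
#'   `n_steps_run`, `final_config`, and the resolved `settings`.
#' @export
run_metropolis <- function(config, params, settings = mcmc_settings(),
                           record_positions = FALSE) {
  validate_config(config)
  n <- n_cells(config)
  E0 <- if (is.null(settings$E0)) 0.1 * params$K else settings$E0
  record_every <- if (is.null(settings$record_every)) 2L * (n - 1L) else
    as.integer(settings$record_every)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  t1 <- .type_codes(config$types1)
  t2 <- .type_codes(config$types2)
  eps <- .eps_matrix(params)
  chunk_records <- max(settings$convergence_window, 250L)
  chunk_steps <- chunk_records * record_every

  x1 <- config$x1; x2 <- config$x2
  step <- numeric(0); mis <- numeric(0); en <- numeric(0)
  pos1 <- NULL; pos2 <- NULL
  accepted <- 0; done <- 0; converged <- FALSE
  repeat {
    todo <- min(chunk_steps, settings$n_steps - done)
    if (todo <= 0) break
    res <- cpp_mcmc_run(x1, x2, t1, t2, config$L0_1, config$L0_2, eps,
                        params$K, E0, settings$deltaX, todo, record_every,
                        record_positions)
    keep <- if (done == 0) seq_along(res$step) else -1L  # drop repeated step-0
    step <- c(step, done + res$step[keep])
    mis <- c(mis, res$mismatch[keep])
    en <- c(en, res$energy[keep])
    if (record_positions) {
      pos1 <- rbind(pos1, res$pos1[keep, , drop = FALSE])
      pos2 <- rbind(pos2, res$pos2[keep, , drop = FALSE])
    }
    accepted <- accepted + res$accepted
    done <- done + res$n_steps
    x1 <- res$x1; x2 <- res$x2
    w <- settings$convergence_window
    if (length(mis) >= 2 * w &&
        abs(.window_slope(tail(mis, w))) < settings$convergence_slope_tol) {
      converged <- TRUE
      break
    }
    if (done >= settings$n_steps) break
  }
  final <- config
  final$x1 <- x1
  final$x2 <- x2
  structure(list(step = step, mismatch = mis, energy = en,
                 acceptance_rate = accepted / done, converged = converged,
                 n_steps_run = done,
                 record_every = record_every, E0 = E0, params = params,
                 final_config = final, positions1 = pos1, positions2 = pos2),
            class = "mcmc_trajectory")
}

#' @export
print.mcmc_trajectory <- function(x, ...) {
  cat(sprintf(
    "<mcmc_trajectory> %g proposals (%s), acceptance %.3f, final mismatch %.4f\n",
    x$n_steps_run, if (x$converged) "converged" else "step cap reached",
    x$acceptance_rate, tail(x$mismatch, 1)))
  invisible(x)
}

#' Steady-state mismatch of a trajectory
#'
#' Mean and SEM of the tissue mismatch over the final `tail_fraction` of the
#' recorded samples. The SEM is corrected for autocorrelation: the effective
#' sample size divides n by the integrated autocorrelation time estimated
#' from the initial positive run of the autocorrelation function.
#'
#' @param trajectory An `mcmc_trajectory`.
#' @param tail_fraction Fraction (0, 1] of records used.
#' @return `list(mean, sem, n_effective)`.
#' @export
steady_state_mismatch <- function(trajectory, tail_fraction = 0.5) {
  m <- trajectory$mismatch
  k <- max(1L, floor(length(m) * tail_fraction))
  if (k < 1 || length(m) < 1) stop("insufficient data: empty trajectory")
  v <- tail(m, k)
  if (length(v) == 1L) return(list(mean = v, sem = 0, n_effective = 1))
  if (sd(v) == 0) return(list(mean = mean(v), sem = 0, n_effective = length(v)))
  rho <- acf(v, lag.max = min(200L, length(v) - 1L), plot = FALSE,
             demean = TRUE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1)]
  tau <- 1 + 2 * sum(rho)
  n_eff <- max(1, length(v) / max(1, tau))
  list(mean = mean(v), sem = sd(v) / sqrt(n_eff), n_effective = n_eff)
}
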