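# Ensemble orchestration: replicated simulations over seeds and parameter
# grids, reproducing the model's in-silico study battery.
#
# Replicate k of an ensemble uses seed master_seed + k - 1 for everything
# random in that replicate (geometry deposition and the Metropolis chain),
# so ensembles are reproducible bit-for-bit from the master seed.

.rep_seed <- function(master_seed, k) as.integer(master_seed + k - 1L)

#' Run an ensemble of equilibrations
#'
#' Deposits an independent geometry per replicate, equilibrates it with the
#' Metropolis sampler, and aggregates the steady-state tissue mismatches.
#'
#' @param params An `adhesion_params` object.
#' @param settings An [mcmc_settings()] object (its `seed` field is ignored;
#'   replicate seeds derive from `master_seed`).
#' @param n_replicates Number of simulated embryos. Default 30.
#' @param master_seed Base seed for replicate derivation.
#' @param pattern Pattern spec for both rows (see [make_pattern()]).
#' @param n Cells per row. Default 52.
#' @param lp A [length_params()] object.
#' @param tail_fraction Tail fraction used by [steady_state_mismatch()].
#' @param keep_configs Keep the final configuration of each replicate
#'   (needed for spatial profiles).
#' @return An object of class `ensemble_result`: list with `replicates`
#'   (data.frame `seed`, `mismatch`, `sem`, `converged`), `mean`, `sem`
#'   (SEM of replicate means; `NA` for a single replicate), `gamma`,
#'   `params`, and optionally `configs`.
#' @export
run_ensemble <- function(params, settings = mcmc_settings(),
                         n_replicates = 30, master_seed = 1,
                         pattern = "TTTTSS", n = 52,
                         lp = length_params(), tail_fraction = 0.5,
                         keep_configs = FALSE) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  labels <- make_pattern(pattern, n)
  vals <- numeric(n_replicates)
  sems <- numeric(n_replicates)
  conv <- logical(n_replicates)
  seeds <- integer(n_replicates)
  configs <- if (keep_configs) vector("list", n_replicates) else NULL
  for (k in seq_len(n_replicates)) {
    seeds[k] <- .rep_seed(master_seed, k)
    set.seed(seeds[k])
    cfg <- deposit_rows(labels, labels, lp)
    s <- settings
    s$seed <- NULL  # replicate RNG stream already seeded
    traj <- run_metropolis(cfg, params, s)
    ss <- steady_state_mismatch(traj, tail_fraction)
    vals[k] <- ss$mean
    sems[k] <- ss$sem
    conv[k] <- traj$converged
    if (keep_configs) configs[[k]] <- traj$final_config
  }
  structure(list(
    replicates = data.frame(seed = seeds, mismatch = vals, sem = sems,
                            converged = conv),
    mean = mean(vals),
    sem = if (n_replicates > 1) sd(vals) / sqrt(n_replicates) else NA_real_,
    gamma = adhesion_gamma(params), params = params,
    n_replicates = n_replicates, configs = configs),
    class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "<ensemble_result> n=%d, gamma=%g um: mismatch %.4f +/- %.4f (SEM)\n",
    x$n_replicates, x$gamma, x$mean,
    if (is.na(x$sem)) 0 else x$sem))
  invisible(x)
}

#' Initial-condition mismatch ensemble (no adhesion, no equilibration)
#'
#' With all adhesion energies zero the cells stay at their deposited rest
#' lengths, so the mismatch of the initial condition is the readout.
#'
#' @inheritParams run_ensemble
#' @return List with `replicates` (data.frame `seed`, `mismatch`), `mean`,
#'   `sem`, and optionally `configs`.
#' @export
initial_mismatch_ensemble <- function(n, pattern = "all-T",
                                      n_replicates = 30, master_seed = 1,
                                      lp = length_params(),
                                      keep_configs = FALSE) {
  labels <- make_pattern(pattern, n)
  vals <- numeric(n_replicates)
  seeds <- integer(n_replicates)
  configs <- if (keep_configs) vector("list", n_replicates) else NULL
  for (k in seq_len(n_replicates)) {
    seeds[k] <- .rep_seed(master_seed, k)
    set.seed(seeds[k])
    cfg <- deposit_rows(labels, labels, lp)
    vals[k] <- tissue_mismatch(cfg)
    if (keep_configs) configs[[k]] <- cfg
  }
  list(replicates = data.frame(seed = seeds, mismatch = vals),
       mean = mean(vals),
       sem = if (n_replicates > 1) sd(vals) / sqrt(n_replicates) else NA_real_,
       configs = configs)
}

#' Size scaling of the no-adhesion mismatch
#'
#' Single-type rows of increasing cell number, no adhesion: the initial
#' mismatch grows with system size as the cumulative cell-length disorder
#' between the pinned ends grows like a Brownian bridge.
#'
#' @param n_values Cell counts to evaluate.
#' @param type Single type used for all cells (`"T"` or `"S"`).
#' @inheritParams run_ensemble
#' @return data.frame with `n`, `mean`, `sem`.
#' @export
sweep_size <- function(n_values = c(6, 12, 24, 52), type = "T",
                       n_replicates = 30, master_seed = 1,
                       lp = length_params()) {
  if (any(n_values < 2)) stop("all n values must be >= 2")
  out <- lapply(seq_along(n_values), function(j) {
    ens <- initial_mismatch_ensemble(
      n = n_values[j], pattern = paste0("all-", type),
      n_replicates = n_replicates,
      master_seed = master_seed + (j - 1) * n_replicates, lp = lp)
    data.frame(n = n_values[j], mean = ens$mean, sem = ens$sem)
  })
  do.call(rbind, out)
}

#' Mismatch master curve over gamma
#'
#' One equilibration ensemble per gamma value; the resulting curve of
#' steady-state mismatch against gamma is the master curve onto which
#' genotypes are mapped. Any (eps_SS, eps_TT, eps_ST) family may be used
#' via `split` and `eps_ST`; families with equal gamma collapse.
#'
#' @param gammas Gamma grid (um), >= 0.
#' @param K Compressibility.
#' @param split,eps_ST Passed to [params_for_gamma()].
#' @inheritParams run_ensemble
#' @return An object of class `gamma_curve`: data.frame with `gamma`,
#'   `eps_SS`, `eps_TT`, `eps_ST`, `K`, `mean`, `sem`, `n_replicates`.
#' @export
sweep_gamma <- function(gammas = c(0, 0.25, 0.5, 1, 2), K = 1,
                        split = 0.5, eps_ST = 0,
                        settings = mcmc_settings(), n_replicates = 30,
                        master_seed = 1, pattern = "TTTTSS", n = 52,
                        lp = length_params()) {
  if (!length(gammas)) stop("gamma grid must be non-empty")
  out <- lapply(seq_along(gammas), function(j) {
    p <- params_for_gamma(gammas[j], K = K, split = split, eps_ST = eps_ST)
    ens <- run_ensemble(p, settings, n_replicates,
                        master_seed + (j - 1) * n_replicates,
                        pattern, n, lp)
    data.frame(gamma = gammas[j], eps_SS = p$eps_SS, eps_TT = p$eps_TT,
               eps_ST = p$eps_ST, K = K, mean = ens$mean, sem = ens$sem,
               n_replicates = n_replicates)
  })
  structure(do.call(rbind, out), class = c("gamma_curve", "data.frame"))
}

#' Steady-state mismatch across effective temperatures
#'
#' At fixed adhesion parameters, sweeps the effective temperature E0. As
#' E0/K grows the adhesion bias becomes irrelevant and the mismatch rises
#' toward the no-adhesion level.
#'
#' @param E0_values Effective temperatures (> 0).
#' @inheritParams run_ensemble
#' @return data.frame with `E0`, `mean`, `sem`.
#' @export
sweep_temperature <- function(E0_values, params,
                              settings = mcmc_settings(), n_replicates = 30,
                              master_seed = 1, pattern = "TTTTSS", n = 52,
                              lp = length_params()) {
  if (any(E0_values <= 0)) stop("all E0 values must be > 0")
  out <- lapply(seq_along(E0_values), function(j) {
    s <- settings
    s$E0 <- E0_values[j]
    ens <- run_ensemble(params, s, n_replicates,
                        master_seed + (j - 1) * n_replicates, pattern, n, lp)
    data.frame(E0 = E0_values[j], mean = ens$mean, sem = ens$sem)
  })
  do.call(rbind, out)
}

#' Sweep cell stiffness in the dynamic vertex model
#'
#' Per stiffness value, integrates an ensemble of vertex-dynamics runs and
#' reports the final mismatch and the time to minimal mismatch, with
#' horizon-censoring flags. `mode = "global"` applies each K to all cells;
#' `mode = "asymmetric"` keeps row 1 at `K_fixed` and varies row 2's K.
#'
#' @param K_values Stiffness grid (> 0).
#' @param mode `"global"` or `"asymmetric"`.
#' @param vp A [vertex_params()] object (its `K` field is overridden).
#' @param K_fixed Fixed row-1 stiffness in asymmetric mode.
#' @param tol_fraction Passed to [time_to_min_mismatch()].
#' @inheritParams run_ensemble
#' @return data.frame with `K`, `mean_initial`, `mean_final`, `sem_final`,
#'   `mean_time_to_min`, `frac_censored`.
#' @export
sweep_stiffness <- function(K_values, mode = c("global", "asymmetric"),
                            vp = vertex_params(t0 = 2000, t_end = 60),
                            K_fixed = 100, n_replicates = 30, master_seed = 1,
                            pattern = "TTTTSS", n = 52, lp = length_params(),
                            tol_fraction = 0.05) {
  mode <- match.arg(mode)
  if (any(K_values <= 0)) stop("all K values must be > 0")
  labels <- make_pattern(pattern, n)
  out <- lapply(seq_along(K_values), function(j) {
    vpj <- vp
    vpj$K <- if (mode == "global") K_values[j] else
      list(row1 = K_fixed, row2 = K_values[j])
    init <- numeric(n_replicates)
    fin <- numeric(n_replicates)
    ttm <- numeric(n_replicates)
    cens <- logical(n_replicates)
    for (k in seq_len(n_replicates)) {
      set.seed(.rep_seed(master_seed + (j - 1) * n_replicates, k))
      cfg <- deposit_rows(labels, labels, lp)
      tr <- run_dynamics(cfg, vpj)
      init[k] <- tr$mismatch[1]
      fin[k] <- tail(tr$mismatch, 1)
      tm <- time_to_min_mismatch(tr, tol_fraction)
      ttm[k] <- tm$time
      cens[k] <- tm$censored
    }
    data.frame(K = K_values[j], mean_initial = mean(init),
               mean_final = mean(fin),
               sem_final = if (n_replicates > 1)
                 sd(fin) / sqrt(n_replicates) else NA_real_,
               mean_time_to_min = mean(ttm),
               frac_censored = mean(cens))
  })
  do.call(rbind, out)
}
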