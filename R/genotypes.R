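# Mapping genotypes onto the model's gamma axis and inferring gamma from
# measured mismatch via the master curve.
#
# The wild-type gamma decomposes into additive contributions of the two
# adhesion systems (Fas3, expressed highly in T/Tin-like cells; Ten-m in
# S/Svp-like cells): gamma_WT = gamma_Fas3 + gamma_Tenm. Mutants removing
# the type pattern itself (svp null) or both adhesion systems (double null)
# have gamma = 0; single adhesion mutants retain the other system's
# contribution; uniform Fas3 overexpression in S cells erases the Fas3
# differential (gamma = gamma_Tenm); Fas3 RNAi in S cells mainly lowers the
# already-low heterotypic term, leaving gamma near wild type.

.genotypes <- c("WT", "svp_null", "fas3_null", "tenm_null", "double_null",
                "svp_gal4_fas3_oe", "svp_gal4_fas3_rnai")

#' Map a genotype onto pattern, gamma and adhesion parameters
#'
#' @param genotype One of `"WT"`, `"svp_null"`, `"fas3_null"`,
#'   `"tenm_null"`, `"double_null"`, `"svp_gal4_fas3_oe"`,
#'   `"svp_gal4_fas3_rnai"`.
#' @param gamma_fas3,gamma_tenm Component contributions to gamma (um, >= 0).
#'   Defaults sum to the wild-type-like 0.5 um with equal shares.
#' @param K Compressibility used to construct the eps triple.
#' @param pattern Pattern used for patterned genotypes.
#' @return List with `genotype`, `pattern`, `gamma`, and `params` (an
#'   `adhesion_params` with `eps_ST = 0` and gamma*K split equally between
#'   `eps_SS` and `eps_TT`).
#' @export
genotype_to_params <- function(genotype, gamma_fas3 = 0.25,
                               gamma_tenm = 0.25, K = 1,
                               pattern = "TTTTSS") {
  if (!genotype %in% .genotypes)
    stop("unknown genotype: ", genotype, " (expected one of ",
         paste(.genotypes, collapse = ", "), ")")
  if (gamma_fas3 < 0 || gamma_tenm < 0)
    stop("component gamma values must be >= 0")
  gamma <- switch(genotype,
                  WT = gamma_fas3 + gamma_tenm,
                  svp_null = 0,
                  double_null = 0,
                  fas3_null = gamma_tenm,
                  tenm_null = gamma_fas3,
                  svp_gal4_fas3_oe = gamma_tenm,
                  svp_gal4_fas3_rnai = gamma_fas3 + gamma_tenm)
  pat <- if (genotype == "svp_null") "all-T" else pattern
  list(genotype = genotype, pattern = pat, gamma = gamma,
       params = params_for_gamma(gamma, K = K))
}

# Internal: monotone (non-increasing) regularization of a gamma curve and
# its inverse interpolation. Raw Monte-Carlo noise can break monotonicity,
# which would make the inversion ill-defined.
.monotone_curve <- function(curve) {
  ord <- order(curve$gamma)
  g <- curve$gamma[ord]
  m <- curve$mean[ord]
  fit <- -isoreg(g, -m)$yf  # non-increasing fit
  list(gamma = g, fit = fit, sem = curve$sem[ord])
}

.invert_curve <- function(mc, m) {
  # returns gamma at mismatch m on the monotone curve, with clamping flags
  if (m >= mc$fit[1]) return(list(gamma = 0, flag = "clamped_at_zero"))
  if (m <= mc$fit[length(mc$fit)])
    return(list(gamma = mc$gamma[length(mc$gamma)], flag = "lower_bound"))
  # strictly decreasing representative for approx(): drop flat repeats,
  # then reverse so the interpolation abscissa is increasing
  keep <- c(TRUE, diff(mc$fit) < 0)
  g <- approx(x = rev(mc$fit[keep]), y = rev(mc$gamma[keep]), xout = m,
              ties = "ordered")$y
  list(gamma = g, flag = "ok")
}

#' Infer gamma from a measured mismatch via the master curve
#'
#' Monotone-regularizes the master curve (isotonic non-increasing fit) and
#' inverts it at the measured mismatch. The uncertainty interval combines
#' the measurement SEM with the curve's local SEM and is propagated through
#' the inverse map. Mismatch above the gamma = 0 level clamps to gamma = 0;
#' mismatch below the plateau returns the largest grid gamma as a lower
#' bound (the curve is flat there, so only a bound is identifiable).
#'
#' @param mismatch Measured (or simulated) mismatch value.
#' @param curve A `gamma_curve` from [sweep_gamma()] (columns `gamma`,
#'   `mean`, `sem`).
#' @param mismatch_sem SEM of the measured mismatch (default 0).
#' @return List with `gamma`, `lower`, `upper`, `flag`.
#' @export
infer_gamma <- function(mismatch, curve, mismatch_sem = 0) {
  if (is.null(curve) || !nrow(curve)) stop("empty master curve")
  mc <- .monotone_curve(curve)
  est <- .invert_curve(mc, mismatch)
  sem_local <- approx(mc$gamma, mc$sem, xout = max(min(est$gamma,
                      max(mc$gamma)), min(mc$gamma)), rule = 2)$y
  err <- sqrt(mismatch_sem^2 + sem_local^2)
  lo <- .invert_curve(mc, mismatch + err)$gamma
  hi <- .invert_curve(mc, mismatch - err)$gamma
  list(gamma = est$gamma, lower = min(lo, hi), upper = max(lo, hi),
       flag = est$flag)
}

#' Positions of type boundaries in a row
#'
#' @param cfg A `tissue_config`.
#' @param row Row index (1 or 2).
#' @return Numeric vector of vertex positions where the cell type changes.
#' @export
type_boundaries <- function(cfg, row = 1) {
  ty <- if (row == 1) cfg$types1 else cfg$types2
  x <- if (row == 1) cfg$x1 else cfg$x2
  idx <- which(ty[-1] != ty[-length(ty)]) + 1L
  x[idx]
}

#' Alignment offsets of the type boundaries across rows
#'
#' Matches the rows' type-boundary vertices in order and reports the
#' absolute offsets. Rows with differing boundary counts (possible in
#' defect patterns) are matched up to the shorter count and flagged.
#'
#' @param cfg A `tissue_config`.
#' @return List with `offsets` (um), `mean_offset`, `matched` (logical:
#'   equal boundary counts in the two rows).
#' @export
boundary_offsets <- function(cfg) {
  b1 <- type_boundaries(cfg, 1)
  b2 <- type_boundaries(cfg, 2)
  k <- min(length(b1), length(b2))
  offs <- if (k) abs(b1[seq_len(k)] - b2[seq_len(k)]) else numeric(0)
  list(offsets = offs,
       mean_offset = if (k) mean(offs) else NA_real_,
       matched = length(b1) == length(b2))
}

#' Equilibrate rows with mismatched cell-type patterns
#'
#' The two rows may carry different patterns (equal cell counts; sister
#' pairing stays by index), emulating cell-specification defects. Reports
#' the tissue mismatch and the type-boundary alignment offsets before and
#' after equilibration on common seeds.
#'
#' @param pattern_row1,pattern_row2 Pattern specs of equal total cell count.
#' @inheritParams run_ensemble
#' @return List with `replicates` (data.frame `seed`, `mismatch_initial`,
#'   `mismatch_final`, `offset_initial`, `offset_final`), ensemble `mean`
#'   and `sem` of the final mismatch.
#' @export
defect_experiment <- function(pattern_row1, pattern_row2, params,
                              settings = mcmc_settings(), n_replicates = 30,
                              master_seed = 1, n = 52,
                              lp = length_params()) {
  l1 <- make_pattern(pattern_row1, n)
  l2 <- make_pattern(pattern_row2, n)
  if (length(l1) != length(l2))
    stop("infeasible pattern: rows must have equal cell counts")
  res <- data.frame(seed = integer(n_replicates),
                    mismatch_initial = numeric(n_replicates),
                    mismatch_final = numeric(n_replicates),
                    offset_initial = numeric(n_replicates),
                    offset_final = numeric(n_replicates))
  for (k in seq_len(n_replicates)) {
    res$seed[k] <- .rep_seed(master_seed, k)
    set.seed(res$seed[k])
    cfg <- deposit_rows(l1, l2, lp)
    res$mismatch_initial[k] <- tissue_mismatch(cfg)
    res$offset_initial[k] <- boundary_offsets(cfg)$mean_offset
    s <- settings
    s$seed <- NULL
    traj <- run_metropolis(cfg, params, s)
    res$mismatch_final[k] <- steady_state_mismatch(traj)$mean
    res$offset_final[k] <- boundary_offsets(traj$final_config)$mean_offset
  }
  list(replicates = res, mean = mean(res$mismatch_final),
       sem = if (n_replicates > 1)
         sd(res$mismatch_final) / sqrt(n_replicates) else NA_real_)
}
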