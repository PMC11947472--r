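# Overdamped dynamic vertex model of the same two-row geometry.
#
# Each interior vertex moves with velocity F/xi, where F combines the
# interfacial tensions of the two segments flanking the vertex along the
# shared midline (negative tension extends a favorable contact) and
# logarithmic elastic restoring forces of the two cells sharing the vertex:
#   xi * dx_i/dt = (T_right - T_left) + K_right*log(L_right/L0_right)
#                                     - K_left*log(L_left/L0_left).
# The logarithmic form matches the linear one for small deformations but
# avoids artifacts at large compression. Integration is explicit Euler with
# synchronous updates; the dynamics are deterministic.

#' Parameters of the dynamic vertex model
#'
#' Tensions are per interface type (pN; negative extends the contact);
#' `t0` is a shorthand for the homotypic-adhesion family
#' `T_SS = T_TT = -t0`, `T_ST = 0`. The elastic coefficient may be a single
#' number, a named per-type vector `c(S = , T = )`, or a
#' `list(row1 = , row2 = )` of per-cell vectors (resolved against the
#' configuration at run time).
#'
#' @param t0 Optional homotypic tension magnitude (pN); overrides
#'   `T_SS`/`T_TT`.
#' @param T_SS,T_TT,T_ST Interfacial tensions (pN).
#' @param K Elastic coefficient(s) (pN).
#' @param xi Friction (pN min/um), > 0.
#' @param dt Timestep (min), > 0. Default 0.01.
#' @param t_end Integration horizon (min). Default 600.
#' @return An object of class `vertex_params`.
#' @export
vertex_params <- function(t0 = NULL, T_SS = -1000, T_TT = -1000, T_ST = 0,
                          K = 100, xi = 1000, dt = 0.01, t_end = 600) {
  if (!is.null(t0)) {
    T_SS <- -t0
    T_TT <- -t0
    T_ST <- 0
  }
  if (xi <= 0) stop("xi must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (t_end <= 0) stop("t_end must be > 0")
  kv <- if (is.list(K)) unlist(K) else K
  if (any(kv <= 0)) stop("K must be > 0")
  structure(list(T_SS = T_SS, T_TT = T_TT, T_ST = T_ST, K = K, xi = xi,
                 dt = dt, t_end = t_end),
            class = "vertex_params")
}

.tension_matrix <- function(vp) .pair_matrix(vp$T_SS, vp$T_TT, vp$T_ST)

# Resolve K into per-cell vectors for both rows.
.per_cell_K <- function(vp, cfg) {
  n <- n_cells(cfg)
  K <- vp$K
  if (is.list(K)) {
    k1 <- rep_len(as.numeric(K$row1), n)
    k2 <- rep_len(as.numeric(K$row2), n)
  } else if (!is.null(names(K))) {
    k1 <- unname(K[cfg$types1])
    k2 <- unname(K[cfg$types2])
    if (anyNA(k1) || anyNA(k2))
      stop("per-type K must name every type present (S, T)")
  } else {
    k1 <- rep(K, n)
    k2 <- rep(K, n)
  }
  list(row1 = k1, row2 = k2)
}

#' Force on a single vertex (reference implementation)
#'
#' Pure-R evaluation of the force law; the integrator uses the compiled
#' equivalent. Tension segments flanking the vertex are typed by the own-row
#' cell on that side and the opposing-row cell covering the point just to
#' that side of the vertex.
#'
#' @param cfg A `tissue_config`.
#' @param row Row index (1 or 2).
#' @param i Vertex index 2..N (interior).
#' @param vp A [vertex_params()] object.
#' @return Force (pN); positive pushes the vertex rightward.
#' @export
vertex_force <- function(cfg, row, i, vp) {
  n <- n_cells(cfg)
  if (i < 2 || i > n) stop("vertex must be interior (2..N)")
  x <- if (row == 1) cfg$x1 else cfg$x2
  xo <- if (row == 1) cfg$x2 else cfg$x1
  ty <- if (row == 1) cfg$types1 else cfg$types2
  tyo <- if (row == 1) cfg$types2 else cfg$types1
  L0 <- if (row == 1) cfg$L0_1 else cfg$L0_2
  Kc <- .per_cell_K(vp, cfg)[[row]]
  p <- x[i]
  L_left <- x[i] - x[i - 1]
  L_right <- x[i + 1] - x[i]
  if (L_left <= 0 || L_right <= 0)
    stop("degenerate geometry: non-positive cell length")
  Tm <- .tension_matrix(vp)
  code <- function(lbl) .type_codes(lbl) + 1L
  j_left <- min(max(sum(xo < p), 1L), n)        # opposing cell just left of p
  j_right <- min(max(sum(xo <= p), 1L), n)      # opposing cell just right
  T_left <- Tm[code(ty[i - 1]), code(tyo[j_left])]
  T_right <- Tm[code(ty[i]), code(tyo[j_right])]
  (T_right - T_left) +
    Kc[i] * log(L_right / L0[i]) - Kc[i - 1] * log(L_left / L0[i - 1])
}

#' One explicit-Euler step (reference implementation)
#'
#' Synchronous update of all interior vertices from the pre-step state:
#' `x <- x + (dt / xi) * F`. Ends stay pinned. Steps that would push a cell
#' below `len_floor` are clamped to half the available slack (both ends of
#' a cell can move within one step).
#'
#' @param cfg A `tissue_config`.
#' @param vp A [vertex_params()] object.
#' @param len_floor Minimal permitted cell length (um).
#' @return The advanced `tissue_config`.
#' @export
euler_step <- function(cfg, vp, len_floor = 1e-6) {
  n <- n_cells(cfg)
  new <- cfg
  for (row in 1:2) {
    x <- if (row == 1) cfg$x1 else cfg$x2
    dx <- numeric(n + 1)
    for (i in 2:n) {
      d <- (vp$dt / vp$xi) * vertex_force(cfg, row, i, vp)
      L_left <- x[i] - x[i - 1]
      L_right <- x[i + 1] - x[i]
      if (abs(d) > max(L_left, L_right))
        stop("unstable step: |dx| exceeds adjacent cell length; reduce dt")
      d <- min(max(d, -max(0, L_left - len_floor) / 2),
               max(0, L_right - len_floor) / 2)
      dx[i] <- d
    }
    if (row == 1) new$x1 <- x + dx else new$x2 <- x + dx
  }
  new
}

#' Integrate the vertex dynamics
#'
#' Runs the compiled explicit-Euler integrator to `t_end`, recording the
#' tissue mismatch every `record_every` steps (t = 0 included).
#'
#' @param cfg A `tissue_config`.
#' @param vp A [vertex_params()] object.
#' @param record_every Record interval in steps. Default 100 (1 min at the
#'   default dt).
#' @return An object of class `dynamics_trace`: list with `time` (min),
#'   `mismatch`, `final_config`, `n_clamped`.
#' @export
run_dynamics <- function(cfg, vp, record_every = 100L) {
  validate_config(cfg)
  ks <- .per_cell_K(vp, cfg)
  n_steps <- ceiling(vp$t_end / vp$dt)
  res <- cpp_dynamics_run(cfg$x1, cfg$x2,
                          .type_codes(cfg$types1), .type_codes(cfg$types2),
                          cfg$L0_1, cfg$L0_2, .tension_matrix(vp),
                          ks$row1, ks$row2, vp$xi, vp$dt, n_steps,
                          as.integer(record_every))
  final <- cfg
  final$x1 <- res$x1
  final$x2 <- res$x2
  structure(list(time = res$time, mismatch = res$mismatch,
                 final_config = final, n_clamped = res$n_clamped,
                 params = vp),
            class = "dynamics_trace")
}

#' @export
print.dynamics_trace <- function(x, ...) {
  cat(sprintf(
    "<dynamics_trace> t in [0, %g] min, mismatch %.4f -> %.4f\n",
    tail(x$time, 1), x$mismatch[1], tail(x$mismatch, 1)))
  invisible(x)
}

#' Time to reach minimal mismatch
#'
#' First recorded time at which the mismatch is within `tol_fraction` of the
#' trace minimum; flagged as horizon-censored when the minimum sits at the
#' end of the trace (the dynamics may not have converged).
#'
#' @param trace A `dynamics_trace` (or list with `time` and `mismatch`).
#' @param tol_fraction Relative tolerance above the minimum.
#' @return `list(time, censored)`.
#' @export
time_to_min_mismatch <- function(trace, tol_fraction = 0.05) {
  m <- trace$mismatch
  if (!length(m)) stop("empty trace")
  thr <- (1 + tol_fraction) * min(m)
  idx <- which(m <= thr)[1]
  list(time = trace$time[idx],
       censored = which.min(m) == length(m))
}
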