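# Energy bookkeeping for the equilibrium model: interface segmentation,
# elastic and adhesion energies, incremental energy changes, and the gamma
# order parameter.
#
# Sign convention: adhesion is favorable, E_adh = -sum(eps * contact length)
# with eps >= 0, so a larger same-type eps rewards same-type contact and a
# larger gamma favors matching.

#' Adhesion and compressibility parameters of the equilibrium model
#'
#' @param eps_SS,eps_TT,eps_ST Adhesion energy per unit length (E/um) of
#'   S-S, T-T and S-T interface segments (favorable-adhesion convention).
#' @param K Cell compressibility (E/um^2), > 0.
#' @return An object of class `adhesion_params`.
#' @examples
#' p <- adhesion_params(eps_SS = 1, eps_TT = 1, eps_ST = 0, K = 1)
#' adhesion_gamma(p)  # 2 um
#' @export
adhesion_params <- function(eps_SS = 0, eps_TT = 0, eps_ST = 0, K = 1) {
  vals <- c(eps_SS = eps_SS, eps_TT = eps_TT, eps_ST = eps_ST, K = K)
  if (!all(is.finite(vals))) stop("adhesion parameters must be finite")
  if (K <= 0) stop("invalid parameter: K must be > 0")
  structure(as.list(vals), class = "adhesion_params")
}

#' @export
print.adhesion_params <- function(x, ...) {
  cat(sprintf(
    "<adhesion_params> eps_SS=%g eps_TT=%g eps_ST=%g K=%g (gamma=%g um)\n",
    x$eps_SS, x$eps_TT, x$eps_ST, x$K, adhesion_gamma(x)))
  invisible(x)
}

.eps_matrix <- function(params) .pair_matrix(params$eps_SS, params$eps_TT,
                                             params$eps_ST)

#' Interface segmentation of a configuration
#'
#' Concatenates and sorts the vertices of both rows; each positive-length
#' segment between consecutive breakpoints is typed by the pair of cells
#' (one per row) covering it. Segments tile the span without gaps.
#'
#' @param cfg A `tissue_config`.
#' @return data.frame with columns `start`, `end`, `pair_type`
#'   (`"SS"`, `"ST"` or `"TT"`).
#' @export
interface_segments <- function(cfg) {
  bp <- sort(c(cfg$x1, cfg$x2))
  len <- diff(bp)
  keep <- len > 0
  start <- bp[-length(bp)][keep]
  end <- bp[-1][keep]
  mid <- (start + end) / 2
  n <- n_cells(cfg)
  c1 <- pmin(pmax(findInterval(mid, cfg$x1), 1L), n)
  c2 <- pmin(pmax(findInterval(mid, cfg$x2), 1L), n)
  pair <- paste0(pmin(cfg$types1[c1], cfg$types2[c2]),
                 pmax(cfg$types1[c1], cfg$types2[c2]))
  data.frame(start = start, end = end, pair_type = pair)
}

#' Total elastic energy
#'
#' Sum over both rows of `K * (L - L0)^2` per cell.
#'
#' @param cfg A `tissue_config`.
#' @param K Compressibility (> 0), or an `adhesion_params` object.
#' @return Elastic energy (>= 0; 0 iff every cell is at rest length).
#' @export
elastic_energy <- function(cfg, K = 1) {
  if (inherits(K, "adhesion_params")) K <- K$K
  if (K <= 0) stop("K must be > 0")
  sum(K * (diff(cfg$x1) - cfg$L0_1)^2) + sum(K * (diff(cfg$x2) - cfg$L0_2)^2)
}

#' Total adhesion energy
#'
#' `-sum(eps(pair_type) * segment length)` over the interface segments.
#'
#' @param cfg A `tissue_config`.
#' @param params An `adhesion_params` object.
#' @return Adhesion energy (<= 0 for non-negative eps).
#' @export
adhesion_energy <- function(cfg, params) {
  seg <- interface_segments(cfg)
  eps <- c(SS = params$eps_SS, ST = params$eps_ST, TT = params$eps_TT)
  -sum(eps[seg$pair_type] * (seg$end - seg$start))
}

#' Total energy (elastic + adhesion)
#'
#' @inheritParams adhesion_energy
#' @return Total energy.
#' @export
total_energy <- function(cfg, params) {
  elastic_energy(cfg, params$K) + adhesion_energy(cfg, params)
}

#' Apply a single vertex move
#'
#' @param cfg A `tissue_config`.
#' @param row Row index (1 or 2).
#' @param i Vertex index 2..N (interior; ends are pinned).
#' @param dx Displacement (um).
#' @return The moved `tissue_config`.
#' @export
apply_move <- function(cfg, row, i, dx) {
  n <- n_cells(cfg)
  if (i < 2 || i > n) stop("vertex must be interior (2..N)")
  if (row == 1) cfg$x1[i] <- cfg$x1[i] + dx
  else if (row == 2) cfg$x2[i] <- cfg$x2[i] + dx
  else stop("row must be 1 or 2")
  cfg
}

#' Energy change of a single vertex move
#'
#' `E(after) - E(before)` for an allowed move. The incremental method
#' (default, used by the sampler) recomputes only the two flanking cells and
#' the interface segments inside the window the move can affect; the full
#' method recomputes both total energies and serves as the reference.
#'
#' @inheritParams apply_move
#' @param params An `adhesion_params` object.
#' @param method `"incremental"` or `"full"`.
#' @return Energy difference.
#' @export
delta_energy <- function(cfg, row, i, dx, params,
                         method = c("incremental", "full")) {
  method <- match.arg(method)
  if (!move_allowed(cfg, row, i, dx))
    stop("move is not allowed (would flip or overlap cells)")
  if (method == "incremental") {
    return(cpp_delta_energy(cfg$x1, cfg$x2,
                            .type_codes(cfg$types1), .type_codes(cfg$types2),
                            cfg$L0_1, cfg$L0_2, .eps_matrix(params),
                            params$K, as.integer(row), as.integer(i), dx))
  }
  total_energy(apply_move(cfg, row, i, dx), params) - total_energy(cfg, params)
}

#' The gamma order parameter
#'
#' `gamma = ((eps_TT - eps_ST) + (eps_SS - eps_ST)) / K`, in um: the typical
#' length change that the adhesion differences can impose on a single cell
#' against its compressibility. `gamma = 0` means heterotypic contact costs
#' nothing; equilibrium mismatch decreases with gamma.
#'
#' @param params An `adhesion_params` object (or a list with the same
#'   fields).
#' @return gamma (um).
#' @export
adhesion_gamma <- function(params) {
  if (is.null(params$K) || params$K <= 0)
    stop("invalid parameter: K must be > 0")
  ((params$eps_TT - params$eps_ST) + (params$eps_SS - params$eps_ST)) / params$K
}

#' Adhesion parameters realizing a given gamma
#'
#' Splits `gamma * K` between `eps_SS` and `eps_TT` (equally by default)
#' with `eps_ST` as an offset; any split realizes the same gamma.
#'
#' @param gamma Target gamma (um), >= 0.
#' @param K Compressibility.
#' @param split Fraction of `gamma * K` assigned to `eps_SS`.
#' @param eps_ST Heterotypic adhesion energy per unit length.
#' @return An `adhesion_params` object with `adhesion_gamma(.) == gamma`.
#' @export
params_for_gamma <- function(gamma, K = 1, split = 0.5, eps_ST = 0) {
  if (gamma < 0) stop("gamma must be >= 0")
  adhesion_params(eps_SS = split * gamma * K + eps_ST,
                  eps_TT = (1 - split) * gamma * K + eps_ST,
                  eps_ST = eps_ST, K = K)
}
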