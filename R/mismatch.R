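# The cell-matching mismatch metric and its spatial profiles.
#
# A cell's mismatch is the fraction of its leading-edge length not
# overlapping its sister (same index, opposite row): m = (L - L_overlap)/L,
# in [0, 1]. The tissue mismatch averages the sister-pair means over all
# columns.

#' Overlap length of two intervals
#'
#' @param cell_i,cell_j Numeric `c(start, end)` intervals with
#'   `start <= end`.
#' @return Non-negative overlap length; 0 for disjoint intervals.
#' @export
overlap_length <- function(cell_i, cell_j) {
  if (cell_i[1] > cell_i[2] || cell_j[1] > cell_j[2])
    stop("invalid interval: start > end")
  max(0, min(cell_i[2], cell_j[2]) - max(cell_i[1], cell_j[1]))
}

# Internal vectorized mismatch per row; zero-length cells take the limit
# value 1 (their overlap is necessarily 0).
.row_mismatch <- function(cfg) {
  n <- n_cells(cfg)
  a1 <- cfg$x1[-(n + 1)]; b1 <- cfg$x1[-1]
  a2 <- cfg$x2[-(n + 1)]; b2 <- cfg$x2[-1]
  ov <- pmax(0, pmin(b1, b2) - pmax(a1, a2))
  L1 <- b1 - a1
  L2 <- b2 - a2
  list(m1 = ifelse(L1 > 0, (L1 - ov) / L1, 1),
       m2 = ifelse(L2 > 0, (L2 - ov) / L2, 1))
}

#' Mismatch ratio of a single cell
#'
#' @param cfg A `tissue_config`.
#' @param row Row index, 1 or 2.
#' @param i Cell index, 1..N.
#' @return Mismatch in `[0, 1]`; `NA` with a warning for a zero-length cell
#'   (the ratio is 0/0 there; ensemble averages use the limit value 1).
#' @export
cell_mismatch <- function(cfg, row, i) {
  n <- n_cells(cfg)
  if (i < 1 || i > n) stop("cell index out of range")
  x <- if (row == 1) cfg$x1 else if (row == 2) cfg$x2 else stop("row must be 1 or 2")
  L <- x[i + 1] - x[i]
  if (L <= 0) {
    warning("zero-length cell: mismatch undefined (0/0)")
    return(NA_real_)
  }
  sister <- if (row == 1) cfg$x2 else cfg$x1
  ov <- overlap_length(c(x[i], x[i + 1]), c(sister[i], sister[i + 1]))
  min(1, max(0, (L - ov) / L))
}

#' Sister-averaged mismatch of column i
#'
#' Arithmetic mean of the two sisters' mismatch ratios.
#'
#' @inheritParams cell_mismatch
#' @return Pair mismatch in `[0, 1]`.
#' @export
pair_mismatch <- function(cfg, i) {
  n <- n_cells(cfg)
  if (i < 1 || i > n) stop("cell index out of range")
  m <- .row_mismatch(cfg)
  (m$m1[i] + m$m2[i]) / 2
}

#' Tissue mismatch
#'
#' Mean of the sister-pair mismatches over all columns; 0 for a perfectly
#' mirrored configuration, 1 when no cell touches its sister.
#'
#' @param cfg A `tissue_config`.
#' @return Tissue mismatch in `[0, 1]`.
#' @export
tissue_mismatch <- function(cfg) {
  m <- .row_mismatch(cfg)
  mean((m$m1 + m$m2) / 2)
}

# Internal: boundary/interior role of each position of a repeating unit
# (cyclic neighbours, since the unit tiles the row).
.unit_roles <- function(unit) {
  u <- length(unit)
  left <- unit[c(u, seq_len(u - 1))]
  right <- unit[c(seq_len(u - 1) + 1, 1)]
  ifelse(unit != left | unit != right, "boundary", "interior")
}

#' Spatial mismatch profile over the repeating pattern unit
#'
#' Pools the sister-pair mismatches of an ensemble of configurations by
#' position within the repeating unit (over unit repeats and replicates) and
#' returns mean, SEM and pooled count per position. Incomplete trailing units
#' are excluded. Positions are annotated with their type and with a
#' boundary/interior role (a position is "boundary" if a cyclic neighbour in
#' the unit has a different type).
#'
#' @param configs A `tissue_config` or list of them sharing one pattern.
#' @param unit Repeating unit, e.g. `"TTTTSS"` (string or label vector).
#' @param by `"position"` (default) for one record per unit position, or
#'   `"type"` to pool all S and all T positions.
#' @return A data.frame with columns `position`, `type`, `role`,
#'   `mean_mismatch`, `sem`, `n`.
#' @export
spatial_profile <- function(configs, unit, by = c("position", "type")) {
  by <- match.arg(by)
  if (inherits(configs, "tissue_config")) configs <- list(configs)
  if (!length(configs)) stop("no configurations supplied")
  unit <- make_pattern(unit, if (is.character(unit) && length(unit) == 1L &&
                                 !unit %in% c("all-S", "all-T"))
                                 nchar(unit) else length(unit))
  u <- length(unit)
  n <- n_cells(configs[[1]])
  expected <- rep_len(unit, n)
  vals <- vector("list", length(configs))
  for (k in seq_along(configs)) {
    cfg <- configs[[k]]
    if (n_cells(cfg) != n || !identical(cfg$types1, expected))
      stop("all configurations must share the same pattern and cell count")
    m <- .row_mismatch(cfg)
    vals[[k]] <- (m$m1 + m$m2) / 2
  }
  n_complete <- (n %/% u) * u
  if (n_complete == 0) stop("row shorter than one full pattern unit")
  pm <- do.call(rbind, lapply(vals, function(v) v[seq_len(n_complete)]))
  pos <- rep(seq_len(u), times = n_complete / u)
  roles <- .unit_roles(unit)
  key <- if (by == "position") pos else unit[pos]
  groups <- if (by == "position") seq_len(u) else sort(unique(unit))
  out <- lapply(groups, function(g) {
    v <- as.vector(pm[, key == g, drop = FALSE])
    data.frame(
      position = if (by == "position") g else NA_integer_,
      type = if (by == "position") unit[g] else g,
      role = if (by == "position") roles[g] else
        if (all(roles[unit == g] == "boundary")) "boundary" else "mixed",
      mean_mismatch = mean(v),
      sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
      n = length(v))
  })
  do.call(rbind, out)
}
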