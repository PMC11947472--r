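# Cell-type patterns, rest-length sampling and random sequential deposition
# of the two facing rows.

#' Build a cell-type label sequence from a repeating unit
#'
#' Tiles a repeating unit of type labels from the left and truncates it at
#' `n_cells`. The default wild-type-like unit is four T (Tin-like) cells
#' followed by two S (Svp-like) cells.
#'
#' @param pattern_spec A string of labels (e.g. `"TTTTSS"`), one of the tokens
#'   `"all-S"` / `"all-T"`, or a character vector of labels.
#' @param n_cells Number of cells in the row (>= 1).
#' @return Character vector of `n_cells` labels in `{"S", "T"}`.
#' @examples
#' make_pattern("TTTTSS", 6)
#' table(make_pattern("TTTTSS", 52))  # 36 T, 16 S
#' @export
make_pattern <- function(pattern_spec, n_cells) {
  if (length(n_cells) != 1L || !is.finite(n_cells) || n_cells < 1)
    stop("n_cells must be a single integer >= 1")
  n_cells <- as.integer(n_cells)
  if (length(pattern_spec) == 1L && is.character(pattern_spec)) {
    unit <- switch(pattern_spec,
                   "all-S" = "S",
                   "all-T" = "T",
                   strsplit(pattern_spec, "")[[1]])
  } else {
    unit <- as.character(pattern_spec)
  }
  if (length(unit) == 0L) stop("invalid pattern: empty pattern_spec")
  bad <- setdiff(unique(unit), c("S", "T"))
  if (length(bad))
    stop("invalid pattern: unknown label(s) ", paste(bad, collapse = ", "))
  rep_len(unit, n_cells)
}

#' Per-type rest-length distribution parameters
#'
#' Mean and standard deviation (um) of the Gaussian rest-length (leading-edge
#' length) distribution of each cell type. The defaults are placeholder
#' values, not experimentally canonical: the T type gets a 10% coefficient of
#' variation and the S type a larger one (20%), reflecting the larger
#' geometric variability of Svp-like cells.
#'
#' @param T,S Numeric vectors `c(mean, sd)` in um; `mean > 0`, `sd >= 0`.
#' @return An object of class `length_params`: a named list of `c(mean, sd)`.
#' @export
length_params <- function(T = c(4, 0.4), S = c(6, 1.2)) {
  out <- list(S = as.numeric(S), T = as.numeric(T))
  for (lab in names(out)) {
    p <- out[[lab]]
    if (length(p) != 2L || !all(is.finite(p)))
      stop("length parameters for type ", lab, " must be c(mean, sd)")
    if (p[1] <= 0) stop("mean rest length for type ", lab, " must be > 0")
    if (p[2] < 0) stop("rest-length sd for type ", lab, " must be >= 0")
    names(out[[lab]]) <- c("mean", "sd")
  }
  structure(out, class = "length_params")
}

#' Sample rest lengths for a row of labelled cells
#'
#' One draw per cell from the type-specific Gaussian, truncated to be
#' strictly positive by redrawing non-positive values (redrawing, rather than
#' clipping, avoids an atom at zero). Reproducible under [set.seed()].
#'
#' @param labels Character vector of type labels.
#' @param params A [length_params()] object covering every label present.
#' @return Numeric vector of rest lengths (um), same length as `labels`.
#' @export
sample_rest_lengths <- function(labels, params = length_params()) {
  n <- length(labels)
  if (n == 0L) return(numeric(0))
  missing <- setdiff(unique(labels), names(params))
  if (length(missing))
    stop("no length parameters for type(s): ", paste(missing, collapse = ", "))
  means <- vapply(params, `[[`, numeric(1), "mean")[labels]
  sds <- vapply(params, `[[`, numeric(1), "sd")[labels]
  out <- rnorm(n, means, sds)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), means[bad], sds[bad])
    bad <- bad[out[bad] <= 0]
  }
  unname(out)
}

#' Construct a two-row tissue configuration
#'
#' Low-level constructor; most users should call [deposit_rows()]. Validates
#' the invariants of the state shared by both simulators: vertices
#' non-decreasing within each row, equal cell counts, and pinned (equal)
#' first and last vertices across rows.
#'
#' @param x1,x2 Numeric vertex positions, length N+1, non-decreasing.
#' @param types1,types2 Character type labels, length N.
#' @param L0_1,L0_2 Rest lengths (um), length N, strictly positive.
#' @return An object of class `tissue_config`.
#' @export
tissue_config <- function(x1, x2, types1, types2, L0_1, L0_2) {
  cfg <- structure(
    list(x1 = as.numeric(x1), x2 = as.numeric(x2),
         types1 = as.character(types1), types2 = as.character(types2),
         L0_1 = as.numeric(L0_1), L0_2 = as.numeric(L0_2)),
    class = "tissue_config")
  validate_config(cfg)
  cfg
}

#' Validate a tissue configuration
#'
#' @param cfg A `tissue_config` object.
#' @param tol Absolute tolerance for the pinned-end equality check.
#' @return `cfg`, invisibly; errors on violated invariants.
#' @export
validate_config <- function(cfg, tol = 1e-9) {
  n <- length(cfg$types1)
  if (length(cfg$types2) != n) stop("rows must have the same cell count")
  if (length(cfg$x1) != n + 1 || length(cfg$x2) != n + 1)
    stop("vertex vectors must have length N+1")
  if (length(cfg$L0_1) != n || length(cfg$L0_2) != n)
    stop("rest-length vectors must have length N")
  if (any(diff(cfg$x1) < 0) || any(diff(cfg$x2) < 0))
    stop("vertices must be non-decreasing within each row")
  if (abs(cfg$x1[1] - cfg$x2[1]) > tol ||
      abs(cfg$x1[n + 1] - cfg$x2[n + 1]) > tol)
    stop("end vertices must coincide across rows (pinned ends)")
  if (any(cfg$L0_1 <= 0) || any(cfg$L0_2 <= 0))
    stop("rest lengths must be strictly positive")
  .type_codes(c(cfg$types1, cfg$types2))
  invisible(cfg)
}

#' @export
print.tissue_config <- function(x, ...) {
  n <- length(x$types1)
  cat("<tissue_config> ", n, " cells per row, span [",
      format(x$x1[1]), ", ", format(x$x1[n + 1]), "] um\n", sep = "")
  cat("  row 1: ", paste(x$types1, collapse = ""), "\n", sep = "")
  cat("  row 2: ", paste(x$types2, collapse = ""), "\n", sep = "")
  cat("  tissue mismatch: ", format(tissue_mismatch(x), digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Number of cells per row
#' @param cfg A `tissue_config`.
#' @return Integer cell count N.
#' @export
n_cells <- function(cfg) length(cfg$types1)

#' Build an initial configuration by random sequential deposition
#'
#' Row-1 rest lengths are sampled once from the type-specific Gaussians;
#' row-2 rest lengths are resampled until the two row totals agree within
#' `mu * 1e-3`, where `mu` is the smaller of the type-specific mean sampled
#' lengths of row 1. Accepted row-2 lengths are then rescaled by the ratio of
#' totals so the pinned end vertices coincide exactly. Cells start at their
#' rest lengths: vertices are the cumulative sums of the rest lengths from a
#' common origin at 0.
#'
#' @param labels_row1,labels_row2 Type label vectors of equal length (row 2
#'   defaults to row 1's labels, i.e. identically patterned rows).
#' @param params A [length_params()] object.
#' @param max_attempts Maximum number of row-2 resampling attempts.
#' @return A `tissue_config`.
#' @export
deposit_rows <- function(labels_row1, labels_row2 = labels_row1,
                         params = length_params(), max_attempts = 10000000L) {
  if (length(labels_row1) != length(labels_row2))
    stop("both rows must have the same cell count")
  if (max_attempts < 1) stop("max_attempts must be >= 1")
  L1 <- sample_rest_lengths(labels_row1, params)
  mu <- min(tapply(L1, labels_row1, mean))
  tol <- mu * 1e-3
  total1 <- sum(L1)
  n <- length(labels_row2)
  means <- vapply(params, `[[`, numeric(1), "mean")[labels_row2]
  sds <- vapply(params, `[[`, numeric(1), "sd")[labels_row2]
  best <- Inf
  L2 <- NULL
  tried <- 0L
  block <- 2000L
  while (tried < max_attempts) {
    b <- min(block, max_attempts - tried)
    cand <- matrix(rnorm(b * n, rep(means, each = b), rep(sds, each = b)),
                   nrow = b)
    bad <- which(cand <= 0)  # truncation by redraw, vectorized
    while (length(bad)) {
      cand[bad] <- rnorm(length(bad),
                         rep(means, each = b)[bad], rep(sds, each = b)[bad])
      bad <- bad[cand[bad] <= 0]
    }
    res <- abs(rowSums(cand) - total1)
    hit <- which(res < tol)
    if (length(hit)) {
      L2 <- cand[hit[1], ]
      break
    }
    if (min(res) < best) best <- min(res)
    tried <- tried + b
  }
  if (is.null(L2))
    stop(sprintf(
      "row deposition failed: |total(row2) - total(row1)| = %.3g > %.3g after %d attempts",
      best, tol, max_attempts))
  L2 <- L2 * (total1 / sum(L2))  # exact end pinning
  tissue_config(x1 = c(0, cumsum(L1)), x2 = c(0, cumsum(L2)),
                types1 = labels_row1, types2 = labels_row2,
                L0_1 = L1, L0_2 = L2)
}

#' Read measured leading-edge lengths and build a configuration
#'
#' Replaces Gaussian sampling by user-measured lengths. The CSV must have
#' columns `row` (1 or 2), `index`, `type` and `length_um`. Row 2 lengths are
#' rescaled so row totals match exactly (pinned ends).
#'
#' @param path CSV file path.
#' @return A `tissue_config`.
#' @export
config_from_lengths_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("row", "index", "type", "length_um")
  if (!all(need %in% names(d)))
    stop("lengths CSV must have columns: ", paste(need, collapse = ", "))
  d <- d[order(d$row, d$index), ]
  d1 <- d[d$row == 1, ]
  d2 <- d[d$row == 2, ]
  if (nrow(d1) != nrow(d2) || nrow(d1) == 0)
    stop("rows 1 and 2 must have the same, positive number of cells")
  L1 <- d1$length_um
  L2 <- d2$length_um * (sum(d1$length_um) / sum(d2$length_um))
  tissue_config(x1 = c(0, cumsum(L1)), x2 = c(0, cumsum(L2)),
                types1 = d1$type, types2 = d2$type, L0_1 = L1, L0_2 = L2)
}
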