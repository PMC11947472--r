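# Shared fixtures and independent oracles for the test suite.

# Deterministic two-row configuration from explicit cell lengths (rest
# lengths equal the realized lengths unless given separately).
toy_config <- function(L1, L2, types1 = rep("T", length(L1)),
                       types2 = rep("T", length(L2)),
                       L0_1 = L1, L0_2 = L2) {
  tissue_config(x1 = c(0, cumsum(L1)), x2 = c(0, cumsum(L2)),
                types1 = types1, types2 = types2, L0_1 = L0_1, L0_2 = L0_2)
}

# Brute-force interval overlap on a fine grid (independent of the
# closed-form min/max rule): counts grid points falling in both intervals.
grid_overlap <- function(a, b, h = 1e-4) {
  lo <- min(a[1], b[1])
  hi <- max(a[2], b[2])
  if (hi <= lo) return(0)
  x <- seq(lo + h / 2, hi - h / 2, by = h)
  sum(x >= a[1] & x <= a[2] & x >= b[1] & x <= b[2]) * h
}

# Brute-force tissue mismatch via grid_overlap, straight from the
# definition (fraction of each cell not overlapping its sister).
grid_tissue_mismatch <- function(cfg, h = 1e-4) {
  n <- length(cfg$types1)
  vals <- vapply(seq_len(n), function(i) {
    top <- c(cfg$x1[i], cfg$x1[i + 1])
    bot <- c(cfg$x2[i], cfg$x2[i + 1])
    ov <- grid_overlap(top, bot, h)
    m1 <- (diff(top) - ov) / diff(top)
    m2 <- (diff(bot) - ov) / diff(bot)
    (m1 + m2) / 2
  }, numeric(1))
  mean(vals)
}

# Segment-enumeration adhesion oracle: total adhesion energy as the sum of
# eps-weighted pairwise overlaps of all cells of row 1 with all cells of
# row 2 (each interface point lies in exactly one cell per row, so the sum
# of pairwise overlaps equals the segment tiling).
pairwise_adhesion_energy <- function(cfg, params) {
  n <- length(cfg$types1)
  eps <- matrix(c(params$eps_SS, params$eps_ST, params$eps_ST, params$eps_TT),
                2, 2, dimnames = list(c("S", "T"), c("S", "T")))
  E <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ov <- max(0, min(cfg$x1[i + 1], cfg$x2[j + 1]) -
                   max(cfg$x1[i], cfg$x2[j]))
      E <- E - eps[cfg$types1[i], cfg$types2[j]] * ov
    }
  }
  E
}

# A small random valid configuration for property tests.
random_config <- function(n = 8, seed = NULL, pattern = "TTTTSS",
                          lp = length_params()) {
  if (!is.null(seed)) set.seed(seed)
  deposit_rows(make_pattern(pattern, n), params = lp)
}
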