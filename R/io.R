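# Configuration files, artifact writers and run manifests.
#
# Interchange formats: YAML configs in, CSV artifacts out (UTF-8, '.'
# decimal), plus a JSON run manifest carrying everything needed to replay a
# run bit-identically (package version, master seed, full parameter dump).

.config_keys <- c(
  "n_cells", "pattern", "eps_SS", "eps_TT", "eps_ST", "K", "E0", "deltaX",
  "n_steps", "record_every", "seed", "n_replicates",
  "mean_T", "sd_T", "mean_S", "sd_S",
  "t0", "T_SS", "T_TT", "T_ST", "K_vertex", "xi", "dt", "t_end",
  "lengths_csv")

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected (typo safety); missing keys are filled with
#' package defaults and recorded in `$defaults_used`. Derived quantities
#' (gamma) are computed from the validated values.
#'
#' @param path Path to a YAML file.
#' @return List with `params` (`adhesion_params`), `vertex` (`vertex_params`),
#'   `settings` (`mcmc_settings`), `lp` (`length_params`), `pattern`,
#'   `n_cells`, `seed`, `n_replicates`, `gamma`, `lengths_csv`,
#'   `defaults_used`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(
    n_cells = 52L, pattern = "TTTTSS", eps_SS = 0, eps_TT = 0, eps_ST = 0,
    K = 1, E0 = NULL, deltaX = 0.05, n_steps = 2e6, record_every = NULL,
    seed = 1L, n_replicates = 30L,
    mean_T = 4, sd_T = 0.4, mean_S = 6, sd_S = 1.2,
    t0 = NULL, T_SS = -1000, T_TT = -1000, T_ST = 0, K_vertex = 100,
    xi = 1000, dt = 0.01, t_end = 600, lengths_csv = NULL)
  defaults_used <- setdiff(names(defaults), names(raw))
  cfg <- modifyList(defaults, raw, keep.null = TRUE)
  if (cfg$K <= 0) stop("validation error: K must be > 0")
  if (cfg$dt <= 0) stop("validation error: dt must be > 0")
  if (cfg$deltaX <= 0) stop("validation error: deltaX must be > 0")
  if (!is.null(cfg$E0) && cfg$E0 <= 0) stop("validation error: E0 must be > 0")
  params <- adhesion_params(cfg$eps_SS, cfg$eps_TT, cfg$eps_ST, cfg$K)
  list(params = params,
       vertex = vertex_params(t0 = cfg$t0, T_SS = cfg$T_SS, T_TT = cfg$T_TT,
                              T_ST = cfg$T_ST, K = cfg$K_vertex, xi = cfg$xi,
                              dt = cfg$dt, t_end = cfg$t_end),
       settings = mcmc_settings(deltaX = cfg$deltaX, E0 = cfg$E0,
                                n_steps = cfg$n_steps,
                                record_every = cfg$record_every),
       lp = length_params(T = c(cfg$mean_T, cfg$sd_T),
                          S = c(cfg$mean_S, cfg$sd_S)),
       pattern = cfg$pattern, n_cells = as.integer(cfg$n_cells),
       seed = as.integer(cfg$seed),
       n_replicates = as.integer(cfg$n_replicates),
       gamma = adhesion_gamma(params),
       lengths_csv = cfg$lengths_csv,
       defaults_used = defaults_used)
}

#' Tissue configuration as a data frame
#'
#' One record per cell: `row`, `index`, `type`, `x_left`, `x_right`, `L0`.
#' The inverse of [config_from_df()].
#'
#' @param cfg A `tissue_config`.
#' @return data.frame.
#' @export
config_to_df <- function(cfg) {
  n <- n_cells(cfg)
  rbind(
    data.frame(row = 1L, index = seq_len(n), type = cfg$types1,
               x_left = cfg$x1[-(n + 1)], x_right = cfg$x1[-1],
               L0 = cfg$L0_1),
    data.frame(row = 2L, index = seq_len(n), type = cfg$types2,
               x_left = cfg$x2[-(n + 1)], x_right = cfg$x2[-1],
               L0 = cfg$L0_2))
}

#' Rebuild a tissue configuration from its data-frame form
#'
#' @param d data.frame as produced by [config_to_df()].
#' @return A `tissue_config`.
#' @export
config_from_df <- function(d) {
  d <- d[order(d$row, d$index), ]
  d1 <- d[d$row == 1, ]
  d2 <- d[d$row == 2, ]
  tissue_config(x1 = c(d1$x_left[1], d1$x_right),
                x2 = c(d2$x_left[1], d2$x_right),
                types1 = d1$type, types2 = d2$type,
                L0_1 = d1$L0, L0_2 = d2$L0)
}

#' Build a run manifest
#'
#' @param seed Master seed of the run.
#' @param params Named list (or parameter object) dumped verbatim.
#' @param converged Logical convergence flag(s).
#' @param inputs Optional character vector of input file paths; their MD5
#'   hashes are recorded.
#' @return List suitable for [write_outputs()].
#' @export
run_manifest <- function(seed, params, converged = TRUE, inputs = character()) {
  list(tool = "cellmatch",
       version = as.character(packageVersion("cellmatch")),
       seed = seed,
       parameters = unclass(params),
       converged = converged,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       input_hashes = if (length(inputs))
         as.list(tools::md5sum(inputs)) else list())
}

#' Write run artifacts
#'
#' Writes any data.frame elements of `result` as `<prefix>_<name>.csv` and
#' the element `manifest` (see [run_manifest()]) as `<prefix>_manifest.json`.
#' CSVs round-trip exactly at full double precision.
#'
#' @param result Named list of data.frames plus an optional `manifest`.
#' @param prefix Output path prefix (directories are created).
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(result, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in names(result)) {
    obj <- result[[nm]]
    if (is.data.frame(obj)) {
      f <- paste0(prefix, "_", nm, ".csv")
      ok <- tryCatch({
        write.csv(format(obj, digits = 17, trim = TRUE, scientific = FALSE),
                  f, row.names = FALSE, quote = FALSE)
        TRUE
      }, error = function(e)
        stop("failed writing ", f, ": ", conditionMessage(e)))
      written <- c(written, f)
    } else if (nm == "manifest") {
      f <- paste0(prefix, "_manifest.json")
      jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      written <- c(written, f)
    }
  }
  invisible(written)
}

#' Trajectory records as a data frame
#'
#' @param traj An `mcmc_trajectory` or `dynamics_trace`.
#' @return data.frame (`step`/`time_min`, `tissue_mismatch`, and
#'   `total_energy` for MCMC trajectories).
#' @export
trajectory_to_df <- function(traj) {
  if (inherits(traj, "mcmc_trajectory"))
    return(data.frame(step = traj$step, tissue_mismatch = traj$mismatch,
                      total_energy = traj$energy))
  data.frame(time_min = traj$time, tissue_mismatch = traj$mismatch)
}
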