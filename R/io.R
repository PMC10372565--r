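# Configuration and trajectory persistence. Configs are flat YAML key-value
# files; trajectories are plain CSV (diff-able, no schema dependency), one
# row per cell per stored frame. All lengths are in micrometres, angles in
# radians, times in MCS (100 MCS = 1.5 simulated minutes).

config_keys <- function() {
  c("T", "delta_r", "delta_phi", "delta_a", "delta_b", "A_pref", "AR_pref",
    "k_A", "k_AR", "k_core", "eps0", "rc_maj", "rc_min", "k_move", "mu",
    "nu", "tau_pol", "tau_flip_prob", "flip_period", "alpha", "L",
    "mcs_to_min", "move_mix", "rho_init", "rho_f", "n_init",
    "terminal_count", "r0", "relax_time", "division_period",
    "daughter_factor", "division_mode", "polarity_update", "skin",
    "n_feeler_rings", "n_feeler_points",
    # pattern and run keys
    "ridge", "ridge_spacing", "ridge_width", "ridge_k_r",
    "ridge_center_x", "ridge_center_y",
    "seed", "snapshot_stride", "out_dir")
}

#' Load a run configuration
#'
#' Reads a flat YAML key-value file. Omitted keys take the published default
#' values (an empty file is the default run); unknown keys are rejected with
#' the offending key named, as are invariant violations (via the
#' [model_params()] / [ridge_pattern()] validators).
#'
#' @param path file path.
#' @return list of class `run_config` with elements `params`
#'   ([model_params()]), `pattern` ([ridge_pattern()] or NULL), `seed`,
#'   `snapshot_stride`, `out_dir`.
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path) && file.size(path) > 0)
    yaml::read_yaml(path) else list()
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_keys())
  if (length(unknown) > 0)
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  as_run_config(raw)
}

as_run_config <- function(raw) {
  par_names <- intersect(names(raw), names(formals(model_params)))
  params <- do.call(model_params, raw[par_names])
  ridge_on <- if (is.null(raw$ridge)) TRUE else isTRUE(raw$ridge)
  pattern <- NULL
  if (ridge_on) {
    pattern <- ridge_pattern(
      L = params$L,
      center = c(if (is.null(raw$ridge_center_x)) params$L / 2 else raw$ridge_center_x,
                 if (is.null(raw$ridge_center_y)) params$L / 2 else raw$ridge_center_y),
      spacing = if (is.null(raw$ridge_spacing)) 60 else raw$ridge_spacing,
      width = if (is.null(raw$ridge_width)) 4 else raw$ridge_width,
      k_r = if (is.null(raw$ridge_k_r)) 120 else raw$ridge_k_r)
  }
  structure(list(params = params, pattern = pattern,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
                 snapshot_stride = raw$snapshot_stride,
                 out_dir = if (is.null(raw$out_dir)) "." else raw$out_dir,
                 raw = raw),
            class = "run_config")
}

#' Write a run configuration
#'
#' Serializes the effective configuration (every key, including defaults that
#' were not set explicitly) so that `load_config(write_config(x, p))`
#' reproduces `x`.
#'
#' @param config a `run_config` from [load_config()] or [as_run_config()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  p <- config$params
  out <- p[c("T", "delta_r", "delta_phi", "delta_a", "delta_b", "A_pref",
             "AR_pref", "k_A", "k_AR", "k_core", "eps0", "rc_maj", "rc_min",
             "k_move", "mu", "nu", "tau_pol", "tau_flip_prob", "flip_period",
             "alpha", "L", "mcs_to_min", "move_mix", "rho_init", "rho_f",
             "n_init", "terminal_count", "r0", "relax_time",
             "division_period", "daughter_factor", "division_mode",
             "polarity_update", "skin", "n_feeler_rings", "n_feeler_points")]
  if (!is.null(config$pattern)) {
    out$ridge <- TRUE
    out$ridge_spacing <- config$pattern$spacing
    out$ridge_width <- config$pattern$width
    out$ridge_k_r <- config$pattern$k_r
    out$ridge_center_x <- config$pattern$center[1]
    out$ridge_center_y <- config$pattern$center[2]
  } else out$ridge <- FALSE
  out$seed <- config$seed
  if (!is.null(config$snapshot_stride))
    out$snapshot_stride <- config$snapshot_stride
  out$out_dir <- config$out_dir
  writeLines(yaml::as.yaml(out, precision = 15), path)
  invisible(path)
}

trajectory_header <- "# spindlemc trajectory: lengths um, angles rad, times MCS (100 MCS = 1.5 min)"

#' Write / read a trajectory
#'
#' Trajectories are stacked frames in plain CSV (comma, UTF-8, header row,
#' one comment line with units), one row per cell per frame, columns `mcs`,
#' `id`, `parent_id`, `x`, `y`, `a`, `b`, `phi`, `px`, `py`. Numeric fields
#' round-trip to better than 1e-12 relative error (15 significant digits);
#' integer fields round-trip exactly.
#'
#' @param trajectory data frame of stacked frames (see [as_trajectory()]).
#' @param path file path.
#' @return `write_trajectory`: `path`, invisibly. `read_trajectory`: the
#'   trajectory data frame.
#' @export
write_trajectory <- function(trajectory, path) {
  need <- c("mcs", "id", "parent_id", "x", "y", "a", "b", "phi", "px", "py")
  miss <- setdiff(need, names(trajectory))
  if (length(miss) > 0)
    stop("write_trajectory: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(trajectory_header, con)
  close(con)
  data.table::fwrite(trajectory[, need], path, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1 else 0
  d <- data.table::fread(path, skip = skip, header = TRUE,
                         data.table = FALSE)
  need <- c("mcs", "id", "parent_id", "x", "y", "a", "b", "phi", "px", "py")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("read_trajectory: malformed header, missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  d$mcs <- as.integer(d$mcs)
  d$id <- as.integer(d$id)
  d$parent_id <- as.integer(d$parent_id)
  for (col in c("x", "y", "a", "b", "phi", "px", "py"))
    d[[col]] <- as.numeric(d[[col]]) # fread may guess integer
  d
}

#' Snapshot MCS values for a run
#'
#' Helper applying the stride policy: frames every `stride` MCS plus the
#' final frame; a stride longer than the run yields the initial and final
#' frames only.
#'
#' @param n_mcs run length.
#' @param stride frame stride, MCS.
#' @return integer vector of MCS values.
#' @export
snapshot_schedule <- function(n_mcs, stride) {
  if (is.null(stride) || stride >= n_mcs) return(unique(c(0L, as.integer(n_mcs))))
  sort(unique(c(0L, seq(stride, n_mcs, by = stride), as.integer(n_mcs))))
}
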