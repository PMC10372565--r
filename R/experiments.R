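# Replicate experiments: batches of scaled-down runs with pinned seeds, and
# the per-run defect metrics used to probe density accumulation at the +1
# core, depletion at the -1 corner, and ridge-crossing suppression.

#' Run a batch of defect-pattern growth simulations
#'
#' Runs one full growth simulation per seed (relaxation then one division per
#' period up to the terminal count) on the standard ring pattern. Seeds are
#' pinned per replicate index, so comparing two arms (say `alpha = 0` vs
#' `alpha = 2`) with the same `seeds` vector compares trajectories with
#' identical initial conditions and random streams.
#'
#' @param seeds integer vector of seeds (one run per seed).
#' @param alpha division shape sensitivity.
#' @param k_r ridge strength.
#' @param L box side, micrometres.
#' @param k_move motility strength.
#' @param division_mode `"shape_dependent"` or `"uniform_random"`.
#' @param snapshot_counts optional cell counts at which to store frames (each
#'   is converted to its scheduled MCS; a second frame `velocity_window` MCS
#'   later is stored too, so window displacements can be computed).
#' @param velocity_window window for displacement measurements, MCS.
#' @param ... further overrides passed to [model_params()].
#' @return list of `monolayer_sim` objects, one per seed.
#' @export
defect_experiment <- function(seeds, alpha = 2, k_r = 120, L = 600,
                              k_move = 1,
                              division_mode = "shape_dependent",
                              snapshot_counts = NULL,
                              velocity_window = 4000, ...) {
  params <- model_params(L = L, alpha = alpha, k_move = k_move,
                         division_mode = division_mode, ...)
  pattern <- ridge_pattern(L = L, k_r = k_r)
  lapply(seeds, function(s) {
    snaps <- integer(0)
    if (!is.null(snapshot_counts)) {
      at <- vapply(snapshot_counts, mcs_at_count, integer(1),
                   params = params)
      snaps <- c(at, at + velocity_window)
    }
    simulate_monolayer(params, pattern, seed = s, snapshot_at = snaps)
  })
}

#' Per-run defect metrics
#'
#' Summarizes one finished run: normalized density deviation in the innermost
#' 60 um ring around the +1 core and around the -1 corner (whole-box average
#' normalization), mean aspect ratio in the inner ring, the on/off-ridge
#' density ratio, and the alignment RMSD near the +1 core.
#'
#' @param sim a `monolayer_sim`.
#' @param rmsd_radius radius (um) around the +1 core used for the RMSD.
#' @param cells optionally, a specific frame (defaults to the final state).
#' @return one-row data.frame.
#' @export
defect_metrics <- function(sim, rmsd_radius = 150, cells = NULL) {
  if (is.null(cells)) cells <- sim$state$cells
  pat <- sim$pattern
  L <- sim$params$L
  bw <- pat$spacing
  prof_plus <- radial_profile(cells, pat$center, L, "density",
                              bin_width = bw, max_radius = L / 2)
  prof_minus <- radial_profile(cells, c(0, 0), L, "density",
                               bin_width = bw, max_radius = L / 2)
  data.frame(
    seed = if (is.null(sim$seed)) NA_integer_ else sim$seed,
    n = nrow(cells),
    density = nrow(cells) / (L / 1000)^2,
    inner_dev_plus = prof_plus$value[1],
    inner_dev_minus = prof_minus$value[1],
    inner_ar_plus = inner_ring_mean_ar(cells, pat),
    ridge_ratio = on_off_ridge_ratio(cells, pat),
    rmsd_plus = alignment_rmsd(cells, "+1", pat$center, L,
                               max_radius = rmsd_radius)$rmsd)
}
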