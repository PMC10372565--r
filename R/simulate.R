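#' Simulate a proliferating monolayer on a ridged substrate
#'
#' The main entry point: seeds small circular cells, relaxes them without
#' division, then grows the monolayer by one division per division period
#' until the terminal cell count, all under Metropolis Monte Carlo dynamics
#' with Gay-Berne cell-cell interactions, ridge-overlap penalties, and
#' polarity-driven motility. By default the run covers the full growth
#' schedule (for the default parameters: 10 h relaxation + one division per
#' 1.5 min from 100 to 3000 cells, about 82.5 simulated hours).
#'
#' @param params a [model_params()] object.
#' @param pattern a [ridge_pattern()] object, or NULL for a plain substrate.
#'   Defaults to the standard ring pattern for the box in `params`.
#' @param seed integer seed for the whole trajectory (passed to `set.seed`).
#' @param n_mcs total Monte Carlo steps; default runs the full growth
#'   schedule (`relax_mcs + division_period * (terminal_count - n_init)`).
#' @param snapshot_at integer vector of absolute MCS values at which to store
#'   frames (the final state is always stored).
#' @param snapshot_stride optionally store a frame every `snapshot_stride`
#'   MCS.
#' @return an object of class `monolayer_sim`: list with `state` (final
#'   `sim_state`), `frames` (named list of data frames, one per stored MCS),
#'   `divisions` (division-event log), `log` (per-1000-MCS acceptance and
#'   polarity summaries), `params`, `pattern`, `seed`, `n_mcs`.
#' @seealso [alignment_rmsd()], [radial_profile()], [on_off_ridge_ratio()]
#'   for the analysis suite; [run_mcs()] for stepping a state manually.
#' @export
#' @examples
#' p <- model_params(L = 300, relax_time = 0.25, n_init = 6,
#'                   terminal_count = 12)
#' sim <- simulate_monolayer(p, seed = 1)
#' sim
simulate_monolayer <- function(params = model_params(),
                               pattern = ridge_pattern(L = params$L),
                               seed = NULL,
                               n_mcs = NULL,
                               snapshot_at = integer(0),
                               snapshot_stride = NULL) {
  if (!is.null(pattern) && !isTRUE(all.equal(pattern$L, params$L)))
    stop("simulate_monolayer: pattern and params disagree on the box side L",
         call. = FALSE)
  if (is.null(n_mcs))
    n_mcs <- params$relax_mcs +
      params$division_period * max(0, params$terminal_count - params$n_init)
  state <- initialize_state(params, pattern, seed = seed)
  snaps <- as.integer(snapshot_at)
  if (!is.null(snapshot_stride))
    snaps <- c(snaps, snapshot_schedule(n_mcs, snapshot_stride))
  snaps <- sort(unique(c(snaps, n_mcs)))
  if (any(snaps == 0))
    state$frames <- c(state$frames,
                      stats::setNames(list(cbind(mcs = 0L, state$cells)), "0"))
  state <- run_mcs(state, n_mcs, snapshot_at = snaps)
  structure(list(state = state, frames = state$frames,
                 divisions = state$divisions, log = state$log,
                 params = params, pattern = pattern, seed = seed,
                 n_mcs = n_mcs),
            class = "monolayer_sim")
}

#' Convert MCS to simulated hours
#' @param mcs Monte Carlo steps.
#' @param params a [model_params()] object (uses its `mcs_to_min`).
#' @return numeric hours.
#' @export
mcs_to_hours <- function(mcs, params = model_params()) {
  mcs * params$mcs_to_min / 60
}

#' MCS at which the growth schedule reaches a given cell count
#'
#' Under the deterministic schedule (one division per period after the
#' relaxation phase), the monolayer holds `n` cells from
#' `relax_mcs + division_period * (n - n_init - 1)` onwards.
#'
#' @param n target cell count (> `n_init`).
#' @param params a [model_params()] object.
#' @return integer MCS.
#' @export
mcs_at_count <- function(n, params) {
  if (n <= params$n_init) return(0L)
  as.integer(params$relax_mcs +
               params$division_period * (n - params$n_init - 1))
}

#' @export
print.monolayer_sim <- function(x, ...) {
  st <- x$state
  cat(sprintf("Monolayer simulation: %d cells after %d MCS (%.1f simulated h)\n",
              nrow(st$cells), st$mcs, mcs_to_hours(st$mcs, x$params)))
  cat(sprintf("  box %g x %g um, density %.0f cells/mm^2\n", x$params$L,
              x$params$L, nrow(st$cells) / (x$params$L / 1000)^2))
  if (!is.null(x$pattern))
    cat(sprintf("  ridges: %d rings, spacing %g um, k_r = %g\n",
                x$pattern$n_rings, x$pattern$spacing, x$pattern$k_r))
  cat(sprintf("  %d frames stored, %d divisions, seed %s\n",
              length(x$frames),
              if (is.null(x$divisions)) 0L else nrow(x$divisions),
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' @export
summary.monolayer_sim <- function(object, ...) {
  st <- object$state
  cl <- st$cells
  p <- object$params
  out <- list(
    n_cells = nrow(cl),
    mcs = st$mcs,
    hours = mcs_to_hours(st$mcs, p),
    density = nrow(cl) / (p$L / 1000)^2,
    mean_area = mean(cell_area(cl)),
    mean_ar = mean(cell_ar(cl)),
    mean_polarity = mean(sqrt(cl$px^2 + cl$py^2)),
    acceptance = if (!is.null(object$log)) {
      tot <- colSums(object$log[, 3:10, drop = FALSE])
      stats::setNames(tot[5:8] / pmax(tot[1:4], 1),
                      c("displace", "rotate", "resize_a", "resize_b"))
    } else NULL
  )
  class(out) <- "summary.monolayer_sim"
  out
}

#' @export
print.summary.monolayer_sim <- function(x, ...) {
  cat(sprintf("%d cells at %.0f cells/mm^2 after %.1f simulated h (%d MCS)\n",
              x$n_cells, x$density, x$hours, x$mcs))
  cat(sprintf("mean area %.0f um^2, mean AR %.2f, mean |p| %.3f um\n",
              x$mean_area, x$mean_ar, x$mean_polarity))
  if (!is.null(x$acceptance)) {
    cat("acceptance fractions: ",
        paste(sprintf("%s %.2f", names(x$acceptance), x$acceptance),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Plot a monolayer snapshot
#'
#' Draws every cell as its ellipse, colored by orientation modulo pi, with
#' the ridge rings overlaid.
#'
#' @param x a `monolayer_sim`.
#' @param frame which stored frame to draw (default the final state).
#' @param n_vertices polygon resolution per ellipse.
#' @param ... passed to `plot`.
#' @export
plot.monolayer_sim <- function(x, frame = NULL, n_vertices = 40, ...) {
  cl <- if (is.null(frame)) x$state$cells else x$frames[[frame]]
  L <- x$params$L
  graphics::plot(NA, xlim = c(0, L), ylim = c(0, L), asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  if (!is.null(x$pattern)) {
    th <- seq(0, 2 * pi, length.out = 181)
    for (r in x$pattern$radii)
      graphics::lines(x$pattern$center[1] + r * cos(th),
                      x$pattern$center[2] + r * sin(th),
                      col = "grey70", lty = 2)
  }
  tt <- seq(0, 2 * pi, length.out = n_vertices + 1)
  hue <- (cl$phi / pi) %% 1
  cols <- grDevices::hsv(hue, 0.7, 0.85, alpha = 0.7)
  for (i in seq_len(nrow(cl))) {
    ex <- cl$a[i] * cos(tt); ey <- cl$b[i] * sin(tt)
    cphi <- cos(cl$phi[i]); sphi <- sin(cl$phi[i])
    graphics::polygon(cl$x[i] + ex * cphi - ey * sphi,
                      cl$y[i] + ex * sphi + ey * cphi,
                      col = cols[i], border = NA)
  }
  invisible(x)
}
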