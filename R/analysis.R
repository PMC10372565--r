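# Quantification suite: alignment RMSD against the defect-imposed
# orientation field, radial density / aspect-ratio profiles, velocity
# direction histograms, ridge occupancy, speed time series. All functions are
# pure: identical inputs give identical outputs.

#' Orientation imposed by the ridge pattern at a position
#'
#' For a +1 defect (concentric rings) the imposed axis is tangential: the
#' azimuthal coordinate plus 90 degrees, modulo 180. For the -1 (saddle)
#' defect formed at the box corners by the periodic tiling, the rule is 180
#' minus the azimuth in the first and second quadrants and 360 minus the
#' azimuth in the third and fourth. Azimuths are measured from the defect
#' centre using minimum-image displacements.
#'
#' @param position n x 2 matrix (or length-2 vector) of positions, um.
#' @param defect `"+1"` or `"-1"`.
#' @param center defect core, length-2, um (for `"-1"` typically `c(0, 0)`,
#'   i.e. the box corner).
#' @param L box side, micrometres.
#' @return expected orientations in degrees, in `[0, 180)`.
#' @export
#' @examples
#' expected_orientation(c(cos(pi / 6), sin(pi / 6)), "+1", c(0, 0), 10) # 120
expected_orientation <- function(position, defect = c("+1", "-1"),
                                 center, L) {
  defect <- match.arg(defect)
  if (is.null(dim(position))) position <- matrix(position, ncol = 2)
  dx <- minimum_image(position[, 1] - center[1], L)
  dy <- minimum_image(position[, 2] - center[2], L)
  if (any(dx == 0 & dy == 0))
    stop("expected_orientation: position coincides with the defect centre",
         call. = FALSE)
  az <- (atan2(dy, dx) * 180 / pi) %% 360
  if (defect == "+1") {
    (az + 90) %% 180
  } else {
    ifelse(az < 180, 180 - az, 360 - az) %% 180
  }
}

#' Wrap an angular deviation into [-90, 90)
#'
#' Orientations are nematic (defined modulo 180 degrees), so deviations are
#' reduced to the half-open interval `[-90, 90)`.
#'
#' @param delta angular deviations, degrees.
#' @return wrapped deviations, degrees.
#' @export
wrap_deviation <- function(delta) {
  (delta + 90) %% 180 - 90
}

#' Alignment RMSD from the defect-imposed orientation
#'
#' Root-mean-square deviation of the cells' long-axis orientations from the
#' orientation the ridge pattern imposes at each cell centre, with deviations
#' wrapped to `[-90, 90)`. Reported in degrees, in `[0, 90]`. Set
#' `squared = TRUE` for the un-rooted mean square deviation instead.
#'
#' @param cells cells data frame.
#' @param defect `"+1"` or `"-1"`.
#' @param center defect core, length-2, um.
#' @param L box side, micrometres.
#' @param max_radius optionally restrict to cells within this minimum-image
#'   distance of the centre.
#' @param squared return the mean squared deviation instead of its root.
#' @return list of class `alignment_stats`: `rmsd` (degrees), `n`,
#'   `deviations` (per-cell, degrees).
#' @export
alignment_rmsd <- function(cells, defect = c("+1", "-1"), center, L,
                           max_radius = NULL, squared = FALSE) {
  defect <- match.arg(defect)
  validate_cells(cells)
  r <- radial_distance(cells$x, cells$y, center, L)
  keep <- r > 0
  if (!is.null(max_radius)) keep <- keep & r < max_radius
  cells <- cells[keep, ]
  if (nrow(cells) == 0)
    stop("alignment_rmsd: no cells in range", call. = FALSE)
  theta <- (cells$phi * 180 / pi) %% 180
  theta_e <- expected_orientation(cbind(cells$x, cells$y), defect, center, L)
  dev <- wrap_deviation(theta - theta_e)
  ms <- mean(dev^2)
  structure(list(rmsd = if (squared) ms else sqrt(ms),
                 squared = squared, n = nrow(cells), deviations = dev),
            class = "alignment_stats")
}

#' @export
print.alignment_stats <- function(x, ...) {
  lab <- if (x$squared) "mean squared deviation" else "RMSD"
  cat(sprintf("alignment %s: %.2f deg%s over %d cells\n", lab, x$rmsd,
              if (x$squared) "^2" else "", x$n))
  invisible(x)
}

#' Radial profile of density or aspect ratio around a defect
#'
#' Bins cells into concentric rings (default 60 um wide, out to 600 um or
#' `L/2`, whichever is smaller) by minimum-image distance from the centre.
#' In `"density"` mode the per-ring value is the normalized density deviation
#' `(rho_ring - rho_avg) / rho_avg` with `rho_avg` either the whole-box
#' average density (default) or the average within the profiled range. In
#' `"aspect_ratio"` mode it is the per-ring mean aspect ratio (NA for empty
#' rings).
#'
#' @param cells cells data frame.
#' @param center profile centre, length-2, um.
#' @param L box side, micrometres.
#' @param quantity `"density"` or `"aspect_ratio"`.
#' @param bin_width ring width, micrometres.
#' @param max_radius outer profile radius, micrometres (capped at `L/2`).
#' @param normalization `"whole_box"` or `"within_range"` (density mode).
#' @return data.frame of class `radial_profile` with columns `r_lo`, `r_hi`,
#'   `r_mid`, `n` (cells in ring), `value`.
#' @export
radial_profile <- function(cells, center, L,
                           quantity = c("density", "aspect_ratio"),
                           bin_width = 60, max_radius = 600,
                           normalization = c("whole_box", "within_range")) {
  quantity <- match.arg(quantity)
  normalization <- match.arg(normalization)
  validate_cells(cells)
  max_radius <- min(max_radius, L / 2)
  edges <- seq(0, max_radius, by = bin_width)
  if (length(edges) < 2)
    stop("radial_profile: bin_width too large for the box", call. = FALSE)
  r <- radial_distance(cells$x, cells$y, center, L)
  idx <- findInterval(r, edges, rightmost.closed = FALSE)
  nb <- length(edges) - 1
  counts <- tabulate(idx[idx >= 1 & idx <= nb], nbins = nb)
  area <- pi * diff(edges^2)
  out <- data.frame(r_lo = edges[-length(edges)], r_hi = edges[-1],
                    r_mid = (edges[-1] + edges[-length(edges)]) / 2,
                    n = counts)
  if (quantity == "density") {
    rho_ring <- counts / area
    rho_avg <- if (normalization == "whole_box") nrow(cells) / L^2
               else sum(counts) / (pi * max_radius^2)
    if (rho_avg == 0)
      stop("radial_profile: zero average density", call. = FALSE)
    out$value <- (rho_ring - rho_avg) / rho_avg
  } else {
    ar <- cell_ar(cells)
    out$value <- vapply(seq_len(nb), function(k) {
      inr <- idx == k
      if (!any(inr)) NA_real_ else mean(ar[inr])
    }, numeric(1))
  }
  attr(out, "quantity") <- quantity
  attr(out, "normalization") <- normalization
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Aggregate radial profiles over replicates
#'
#' @param profiles list of [radial_profile()] results on identical bins.
#' @return data.frame with per-ring mean, SE and replicate count.
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  vals <- vapply(profiles, function(p) p$value, numeric(nrow(profiles[[1]])))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  out <- profiles[[1]][, c("r_lo", "r_hi", "r_mid")]
  out$mean <- rowMeans(vals, na.rm = TRUE)
  out$se <- apply(vals, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  })
  out$n_rep <- rowSums(!is.na(vals))
  out
}

#' Histogram of velocity direction relative to the outward radial direction
#'
#' For each cell present in two frames separated by the averaging window
#' (default 60 simulated minutes = 4000 MCS), computes the minimum-image
#' displacement and the angle between it and the outward radial unit vector
#' at the cell's window-start position, measured clockwise-positive so that
#' 90 degrees is azimuthally clockwise and 270 degrees counterclockwise
#' motion. 0 degrees is radially outward.
#'
#' @param trajectory data frame of stacked frames (see [as_trajectory()]).
#' @param center defect core, length-2, um.
#' @param L box side, micrometres.
#' @param window averaging window in simulated minutes.
#' @param bin_width histogram bin width, degrees.
#' @param start_mcs window start (default the trajectory's first frame).
#' @param mcs_to_min simulated minutes per MCS.
#' @return data.frame with columns `bin_lo`, `bin_hi`, `bin_mid`, `count`,
#'   `prop`.
#' @export
velocity_radial_histogram <- function(trajectory, center, L, window = 60,
                                      bin_width = 15, start_mcs = NULL,
                                      mcs_to_min = 1.5 / 100) {
  stopifnot(all(c("mcs", "id", "x", "y") %in% names(trajectory)))
  mcs_vals <- sort(unique(trajectory$mcs))
  if (is.null(start_mcs)) start_mcs <- mcs_vals[1]
  window_mcs <- round(window / mcs_to_min)
  end_target <- start_mcs + window_mcs
  if (max(mcs_vals) < end_target)
    stop("velocity_radial_histogram: trajectory shorter than the window",
         call. = FALSE)
  f0 <- trajectory[trajectory$mcs == start_mcs, ]
  end_mcs <- mcs_vals[which.min(abs(mcs_vals - end_target))]
  f1 <- trajectory[trajectory$mcs == end_mcs, ]
  common <- intersect(f0$id, f1$id)
  f0 <- f0[match(common, f0$id), ]
  f1 <- f1[match(common, f1$id), ]
  dx <- minimum_image(f1$x - f0$x, L)
  dy <- minimum_image(f1$y - f0$y, L)
  rx <- minimum_image(f0$x - center[1], L)
  ry <- minimum_image(f0$y - center[2], L)
  rn <- sqrt(rx^2 + ry^2)
  ok <- rn > 0 & (dx != 0 | dy != 0)
  rhx <- rx[ok] / rn[ok]; rhy <- ry[ok] / rn[ok]
  dot <- rhx * dx[ok] + rhy * dy[ok]
  crs <- rhx * dy[ok] - rhy * dx[ok]
  ang <- (-atan2(crs, dot) * 180 / pi) %% 360 # clockwise-positive
  edges <- seq(0, 360, by = bin_width)
  idx <- findInterval(ang, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
             count = counts, prop = counts / max(1, sum(counts)))
}

#' Ratio of cell number density on vs off the ridges
#'
#' A cell counts as "on" a ridge iff its centre lies within a ridge annulus
#' (minimum-image distance within `width/2` of a ring radius). The ratio is
#' `(N_on / Area_on) / (N_off / Area_off)`, with ridge and off-ridge areas
#' computed analytically from the annuli. Returns `Inf` (with a warning) if
#' no cell is off-ridge.
#'
#' @param cells cells data frame.
#' @param pattern a [ridge_pattern()] object.
#' @return numeric scalar.
#' @export
on_off_ridge_ratio <- function(cells, pattern) {
  validate_cells(cells)
  on <- ridge_membership(cbind(cells$x, cells$y), pattern)
  area_on <- ridge_area(pattern)
  area_off <- pattern$L^2 - area_on
  n_on <- sum(on); n_off <- sum(!on)
  if (n_off == 0) {
    warning("on_off_ridge_ratio: no cells off-ridge; ratio is infinite")
    return(Inf)
  }
  (n_on / area_on) / (n_off / area_off)
}

#' Total ridge area of a pattern
#'
#' Analytic area of the ridge annuli under the minimum image: the region at
#' minimum-image distance within `width/2` of each ring radius. Rings beyond
#' `L/2` are truncated into arcs by the box, which the disc-in-square area
#' formula accounts for exactly.
#'
#' @param pattern a [ridge_pattern()] object.
#' @return area in square micrometres.
#' @export
ridge_area <- function(pattern) {
  L <- pattern$L
  h <- L / 2
  disc_in_box <- function(r) {
    # area of {p in box : minimum-image distance(p, centre) <= r}
    r <- pmin(r, L / sqrt(2))
    ifelse(r <= h, pi * r^2,
           pi * r^2 - 4 * (r^2 * acos(pmin(1, h / r)) -
                             h * sqrt(pmax(0, r^2 - h^2))))
  }
  sum(disc_in_box(pattern$radii + pattern$width / 2) -
        disc_in_box(pattern$radii - pattern$width / 2))
}

#' Mean cell speed over time
#'
#' Per-cell displacement magnitude between consecutive stored frames divided
#' by the frame interval (converted via 100 MCS = 1.5 min), averaged over the
#' cells present in both frames; the dispersion column is the SD over cells.
#'
#' @param trajectory data frame of stacked frames.
#' @param L box side, micrometres.
#' @param mcs_to_min simulated minutes per MCS.
#' @return data.frame with columns `mcs`, `hours`, `mean_speed` (um/h),
#'   `sd_speed`, `n`.
#' @export
mean_speed_timeseries <- function(trajectory, L, mcs_to_min = 1.5 / 100) {
  mcs_vals <- sort(unique(trajectory$mcs))
  if (length(mcs_vals) < 2)
    stop("mean_speed_timeseries: need at least two frames", call. = FALSE)
  out <- lapply(seq_len(length(mcs_vals) - 1), function(k) {
    f0 <- trajectory[trajectory$mcs == mcs_vals[k], ]
    f1 <- trajectory[trajectory$mcs == mcs_vals[k + 1], ]
    common <- intersect(f0$id, f1$id)
    f0 <- f0[match(common, f0$id), ]
    f1 <- f1[match(common, f1$id), ]
    dt_h <- (mcs_vals[k + 1] - mcs_vals[k]) * mcs_to_min / 60
    sp <- sqrt(minimum_image(f1$x - f0$x, L)^2 +
               minimum_image(f1$y - f0$y, L)^2) / dt_h
    data.frame(mcs = mcs_vals[k + 1],
               hours = mcs_vals[k + 1] * mcs_to_min / 60,
               mean_speed = mean(sp), sd_speed = stats::sd(sp),
               n = length(sp))
  })
  do.call(rbind, out)
}

#' Mean aspect ratio in the innermost ring
#'
#' Mean aspect ratio of cells whose centres lie within the first ring radius
#' of the +1 defect core. Returns `NA` when the inner disc is empty (which
#' happens in a sizeable fraction of no-motility runs).
#'
#' @param cells cells data frame.
#' @param pattern a [ridge_pattern()] object.
#' @return numeric scalar (NA if the inner region is empty).
#' @export
inner_ring_mean_ar <- function(cells, pattern) {
  validate_cells(cells)
  r <- radial_distance(cells$x, cells$y, pattern$center, pattern$L)
  inner <- r < pattern$radii[1]
  if (!any(inner)) return(NA_real_)
  mean(cell_ar(cells[inner, ]))
}

#' Stack stored frames into a trajectory table
#'
#' @param sim a `monolayer_sim` (or a `sim_state` with stored frames).
#' @return data.frame with one row per cell per stored frame (columns `mcs`,
#'   `id`, `parent_id`, `x`, `y`, `a`, `b`, `phi`, `px`, `py`).
#' @export
as_trajectory <- function(sim) {
  frames <- if (inherits(sim, "monolayer_sim")) sim$frames else sim$frames
  if (length(frames) == 0)
    stop("as_trajectory: no stored frames", call. = FALSE)
  out <- do.call(rbind, frames)
  rownames(out) <- NULL
  out
}
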