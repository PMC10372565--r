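#' Geometric shape energy
#'
#' Penalizes deviations of area and aspect ratio from their preferred values.
#' With relative deviations \eqn{\delta_A = (A - A_{pref})/A_{pref}} and
#' \eqn{\delta_{AR} = (AR - AR_{pref})/AR_{pref}}, each contributes
#' \eqn{E_X = k_X(\delta^2 - \delta^3/3 + 4\delta^4)}: nearly flat close to
#' the preferred value, steeply (quartically) rising for large deviations.
#' The global minimum is exactly 0, attained only at the preferred shape.
#'
#' @param cells cells data frame (one or more rows).
#' @param params a [model_params()] object.
#' @return numeric vector of energies (one per cell), energy units of `T`.
#' @export
#' @examples
#' p <- model_params()
#' b <- sqrt(p$A_pref / (pi * p$AR_pref))
#' shape_energy(make_cells(0, 0, a = 4 * b, b = b, phi = 0), p) # 0
shape_energy <- function(cells, params) {
  validate_cells(cells)
  vapply(seq_len(nrow(cells)), function(i)
    cpp_shape_energy(cells$a[i], cells$b[i], params$A_pref, params$AR_pref,
                     params$k_A, params$k_AR), numeric(1))
}

#' Core (anti-squeezing) energy
#'
#' \eqn{E_c = k_{core}(1/a^4 + 1/b^4)}: negligible at typical sizes, diverging
#' as either axis shrinks to zero, so cells cannot be squeezed indefinitely.
#'
#' @inheritParams shape_energy
#' @return numeric vector of energies.
#' @export
core_energy <- function(cells, params) {
  validate_cells(cells)
  if (any(cells$a <= 0 | cells$b <= 0))
    stop("core_energy: axes must be positive", call. = FALSE)
  vapply(seq_len(nrow(cells)), function(i)
    cpp_core_energy(cells$a[i], cells$b[i], params$k_core), numeric(1))
}

#' Ridge membership of points
#'
#' TRUE iff the minimum-image distance from the point to the pattern centre
#' lies within `width/2` of some ring radius. Because of the minimum image,
#' the periodic tiling of ring centres is handled automatically (this is what
#' builds the -1 defect at the box corners).
#'
#' @param points n x 2 matrix (or length-2 vector) of coordinates, um.
#' @param pattern a [ridge_pattern()] object.
#' @return logical vector.
#' @export
ridge_membership <- function(points, pattern) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  d <- radial_distance(points[, 1], points[, 2], pattern$center, pattern$L)
  k <- round(d / pattern$spacing)
  k >= 1 & k <= pattern$n_rings &
    abs(d - k * pattern$spacing) <= pattern$width / 2
}

#' Fraction of a cell overlapping the ridges
#'
#' The overlap fraction \eqn{\Upsilon = N_o / N_t} is estimated from points on
#' concentric "feeler" ellipses sharing the cell's centre, orientation and
#' shape: by default three ellipses with axis radii (a, b), (2a/3, 2b/3) and
#' (a/3, b/3), each carrying 64 points evenly spaced in the polar parameter
#' angle (192 points total).
#'
#' @param cells cells data frame.
#' @param pattern a [ridge_pattern()] object.
#' @param params a [model_params()] object (feeler configuration).
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
ridge_overlap_fraction <- function(cells, pattern, params = model_params(L = pattern$L)) {
  validate_cells(cells)
  scales <- rev(seq_len(params$n_feeler_rings)) / params$n_feeler_rings
  vapply(seq_len(nrow(cells)), function(i)
    cpp_ridge_overlap(cells$x[i], cells$y[i], cells$a[i], cells$b[i],
                      cells$phi[i], pattern$center[1], pattern$center[2],
                      pattern$spacing, pattern$width, pattern$n_rings,
                      pattern$L, params$n_feeler_points, scales),
    numeric(1))
}

#' Cell-ridge interaction energy
#'
#' \eqn{E_{ridge} = k_r \Upsilon}: ridge strength times the overlap fraction,
#' bounded by `[0, k_r]`.
#'
#' @inheritParams ridge_overlap_fraction
#' @return numeric vector of energies.
#' @export
ridge_energy <- function(cells, pattern, params = model_params(L = pattern$L)) {
  pattern$k_r * ridge_overlap_fraction(cells, pattern, params)
}
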