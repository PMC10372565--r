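#' Construct a table of cells
#'
#' Cells are rows of a plain data frame with columns `id`, `parent_id`
#' (NA for founders), centre `x`, `y` (um, in `[0, L)` after wrapping),
#' semi-axis radii `a >= b > 0` (um), orientation `phi` of the major axis
#' against the x-axis (radians; the physical orientation is defined modulo
#' pi), and polarity components `px`, `py` (the direction used by the
#' motility energy; the magnitude carries the displacement-feedback memory).
#'
#' @param x,y centre coordinates, micrometres.
#' @param a,b semi-major and semi-minor axis radii, micrometres.
#' @param phi orientation, radians.
#' @param px,py polarity vector components.
#' @param id integer cell ids (default sequential).
#' @param parent_id integer parent ids (NA for founder cells).
#' @return data.frame with one row per cell.
#' @export
#' @examples
#' make_cells(x = 10, y = 20, a = 40, b = 10, phi = pi / 4)
make_cells <- function(x, y, a, b, phi, px = 1, py = 0,
                       id = seq_along(x), parent_id = NA_integer_) {
  n <- length(x)
  d <- data.frame(id = as.integer(rep_len(id, n)),
                  parent_id = as.integer(rep_len(parent_id, n)),
                  x = as.numeric(x), y = as.numeric(y),
                  a = as.numeric(rep_len(a, n)), b = as.numeric(rep_len(b, n)),
                  phi = as.numeric(rep_len(phi, n)),
                  px = as.numeric(rep_len(px, n)),
                  py = as.numeric(rep_len(py, n)))
  validate_cells(d)
  d
}

validate_cells <- function(cells) {
  stopifnot(is.data.frame(cells))
  need <- c("id", "parent_id", "x", "y", "a", "b", "phi", "px", "py")
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0)
    stop("cells table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(cells$b <= 0) || any(cells$a < cells$b))
    stop("cells must satisfy a >= b > 0", call. = FALSE)
  invisible(cells)
}

#' Cell area and aspect ratio
#'
#' Derived quantities, always computed from the axes (never cached):
#' area \eqn{A = \pi a b} and aspect ratio \eqn{AR = a/b \ge 1}.
#'
#' @param cells a cells data frame (see [make_cells()]).
#' @return numeric vector.
#' @export
cell_area <- function(cells) pi * cells$a * cells$b

#' @rdname cell_area
#' @export
cell_ar <- function(cells) cells$a / cells$b

#' Minimum-image displacement on a periodic box
#'
#' Wraps each component of a displacement into `[-L/2, L/2)`. Idempotent, and
#' invariant under addition of any lattice vector of the box.
#'
#' @param d numeric vector, or an n x 2 matrix of displacement components, um.
#' @param L box side, micrometres.
#' @return object of the same shape as `d`.
#' @export
#' @examples
#' minimum_image(c(700, 0), 1200) # c(-500, 0)
minimum_image <- function(d, L) {
  if (!is.numeric(L) || length(L) != 1 || !is.finite(L) || L <= 0)
    stop("minimum_image: L must be a positive number", call. = FALSE)
  d - L * floor(d / L + 0.5)
}

#' Wrap positions into the primary box
#'
#' @param x coordinates (vector or matrix), micrometres.
#' @param L box side, micrometres.
#' @return coordinates wrapped into `[0, L)`.
#' @export
wrap_position <- function(x, L) {
  w <- x - L * floor(x / L)
  w[w >= L] <- 0
  w
}

#' Minimum-image distance to a point
#'
#' @param x,y coordinates of query points, micrometres.
#' @param center length-2 reference point.
#' @param L box side, micrometres.
#' @return numeric vector of distances.
#' @export
radial_distance <- function(x, y, center, L) {
  dx <- minimum_image(x - center[1], L)
  dy <- minimum_image(y - center[2], L)
  sqrt(dx^2 + dy^2)
}
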