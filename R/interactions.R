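# Modified Gay-Berne pair interaction with anisotropic range and strength and
# an elliptical one-sided interaction cutoff. Length scales enter through
# l_i = sqrt(2) a_i and d_i = sqrt(2) b_i, which makes the circular limit
# self-consistent: two identical discs of radius b have contact scale
# sigma = sigma0 = 2b.

#' Orientation-weighted shape matrix of a cell
#'
#' \eqn{\gamma_i = (l_i^2 - d_i^2)\,\hat u_i \hat u_i^T + d_i^2 I} with
#' \eqn{l_i = \sqrt2 a_i}, \eqn{d_i = \sqrt2 b_i}. Symmetric positive
#' definite with eigenvalues \eqn{l_i^2} along the long axis and
#' \eqn{d_i^2} across it.
#'
#' @param cell single-row cells data frame.
#' @return 2 x 2 numeric matrix, um^2.
#' @export
shape_matrix <- function(cell) {
  u <- c(cos(cell$phi[1]), sin(cell$phi[1]))
  l2 <- 2 * cell$a[1]^2
  d2 <- 2 * cell$b[1]^2
  (l2 - d2) * tcrossprod(u) + d2 * diag(2)
}

#' Shape anisotropy parameter of a cell pair
#'
#' \eqn{\chi = [((l_1^2-d_1^2)(l_2^2-d_2^2)) /
#' ((l_1^2+d_1^2)(l_2^2+d_2^2))]^{1/2} \in [0, 1)}; zero when either cell is
#' circular, approaching 1 for two needle-like cells.
#'
#' @param cell1,cell2 single-row cells data frames.
#' @return numeric scalar.
#' @export
anisotropy_chi <- function(cell1, cell2) {
  f <- function(cl) c(2 * cl$a[1]^2, 2 * cl$b[1]^2)
  s1 <- f(cell1); s2 <- f(cell2)
  sqrt(((s1[1] - s1[2]) * (s2[1] - s2[2])) /
       ((s1[1] + s1[2]) * (s2[1] + s2[2])))
}

#' Anisotropic range parameter
#'
#' \eqn{\sigma = (\hat r_{12}^T (\gamma_1+\gamma_2)^{-1} \hat r_{12})^{-1/2}}:
#' the orientation-dependent contact distance. For two identical circular
#' cells it equals \eqn{\sigma_0 = \sqrt{2b_1^2 + 2b_2^2} = 2b}; for identical
#' parallel cells it is `2a` end-to-end and `2b` side-by-side.
#'
#' @param cell1,cell2 single-row cells data frames.
#' @param r12_hat unit vector from cell 2 towards cell 1.
#' @return numeric scalar, micrometres.
#' @export
range_sigma <- function(cell1, cell2, r12_hat) {
  G <- shape_matrix(cell1) + shape_matrix(cell2)
  q <- drop(crossprod(r12_hat, solve(G, r12_hat)))
  1 / sqrt(q)
}

#' Anisotropic interaction strength
#'
#' \eqn{\epsilon = \epsilon_0\,\epsilon_a^\nu\,\epsilon_b^\mu} with
#' \eqn{\epsilon_a = [1 - \chi^2(\hat u_1\cdot\hat u_2)^2]^{-1/2}} (head-tail
#' symmetric, favouring parallel long axes) and the dimensionless
#' \eqn{\epsilon_b = (\sigma_0/\sigma)^2} (favouring side-by-side contact).
#' Both factors equal 1 for circular cells, so the isotropic limit has
#' \eqn{\epsilon = \epsilon_0}.
#'
#' @inheritParams range_sigma
#' @param params a [model_params()] object.
#' @return numeric scalar, energy units.
#' @export
strength_epsilon <- function(cell1, cell2, r12_hat, params) {
  chi <- anisotropy_chi(cell1, cell2)
  u1 <- c(cos(cell1$phi[1]), sin(cell1$phi[1]))
  u2 <- c(cos(cell2$phi[1]), sin(cell2$phi[1]))
  ea <- 1 / sqrt(1 - chi^2 * sum(u1 * u2)^2)
  s0 <- sqrt(2 * cell1$b[1]^2 + 2 * cell2$b[1]^2)
  eb <- (s0 / range_sigma(cell1, cell2, r12_hat))^2
  params$eps0 * ea^params$nu * eb^params$mu
}

#' Gay-Berne pair energy
#'
#' \eqn{U = 4\epsilon\,(r^{-12} - r^{-6})} with the scaled, shifted distance
#' \eqn{r = (|r_{12}| - \sigma + \sigma_0)/\sigma_0}: zero at
#' \eqn{|r_{12}| = \sigma}, minimum \eqn{-\epsilon} at \eqn{r = 2^{1/6}},
#' strongly repulsive below contact. Coincident centres (possible transiently
#' after division) are handled by flooring the scaled distance at `1e-3`, so
#' the energy stays finite (and essentially guarantees Metropolis rejection).
#' Centre separations use the minimum image on the periodic box. Vectorized
#' over rows: `cells1` and `cells2` are matched row by row.
#'
#' @param cells1,cells2 cells data frames with the same number of rows.
#' @param L box side, micrometres.
#' @param params a [model_params()] object.
#' @return numeric vector of pair energies.
#' @export
#' @examples
#' p <- model_params()
#' c1 <- make_cells(0, 0, a = 40, b = 10, phi = 0)
#' c2 <- make_cells(0, 21.1, a = 40, b = 10, phi = 0) # near side-by-side contact
#' pair_energy(c1, c2, L = 1200, params = p)
pair_energy <- function(cells1, cells2, L, params) {
  validate_cells(cells1); validate_cells(cells2)
  if (nrow(cells1) != nrow(cells2))
    stop("pair_energy: cells1 and cells2 must have the same number of rows",
         call. = FALSE)
  m1 <- as.matrix(cells1[, c("x", "y", "a", "b", "phi")])
  m2 <- as.matrix(cells2[, c("x", "y", "a", "b", "phi")])
  cpp_pair_energy(m1, m2, L, params$eps0, params$mu, params$nu)
}

#' Elliptical interaction cutoff test
#'
#' TRUE iff the minimum-image position of cell j's centre lies inside the
#' ellipse centred on cell i, oriented along i's long axis, with semi-axes
#' `rc_maj` and `rc_min`. Note the cutoff is one-sided (asymmetric): it is a
#' property of cell i. Vectorized over matched rows.
#'
#' @param cells_i,cells_j cells data frames with the same number of rows.
#' @param L box side, micrometres.
#' @param params a [model_params()] object.
#' @return logical vector.
#' @export
in_interaction_cutoff <- function(cells_i, cells_j, L, params) {
  validate_cells(cells_i); validate_cells(cells_j)
  mi <- as.matrix(cells_i[, c("x", "y", "a", "b", "phi")])
  mj <- as.matrix(cells_j[, c("x", "y", "a", "b", "phi")])
  cpp_in_cutoff(mi, mj, L, params$rc_maj, params$rc_min)
}

#' Exact neighbor lists under the elliptical cutoff
#'
#' For each cell i, the indices j of all cells whose centres fall inside i's
#' interaction ellipse. This is the exact (unpadded) list; the simulation
#' engine internally keeps circularly padded candidate lists that are rebuilt
#' whenever a cell has moved more than `skin` um since the last rebuild or a
#' division occurs, and re-applies this exact test at every energy
#' evaluation, so no interacting pair is ever missed.
#'
#' @param state a simulation state (see [initialize_state()]), or a cells
#'   data frame together with `L` and `params`.
#' @param L,params used when `state` is a plain cells data frame.
#' @return list of integer index vectors, one per cell.
#' @export
build_neighbor_lists <- function(state, L = NULL, params = NULL) {
  if (inherits(state, "sim_state")) {
    cells <- state$cells; L <- state$params$L; params <- state$params
  } else {
    cells <- state
    if (is.null(L) || is.null(params))
      stop("build_neighbor_lists: supply L and params with a plain cells table",
           call. = FALSE)
  }
  m <- as.matrix(cells[, c("x", "y", "a", "b", "phi")])
  lst <- cpp_exact_neighbors(m, L, params$rc_maj, params$rc_min)
  lapply(lst, as.integer)
}
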