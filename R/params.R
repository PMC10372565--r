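#' Model parameters
#'
#' Constructs the full parameter set of the monolayer model. Defaults are the
#' published simulation values: maximum proposal sizes \eqn{\delta r = 1.2}
#' \eqn{\mu m}, \eqn{\delta\phi = 2^\circ}, \eqn{\delta a = \delta b = 0.6}
#' \eqn{\mu m}; preferred geometry \eqn{A_{pref} = 1400~\mu m^2},
#' \eqn{AR_{pref} = 4}; penalty strengths \eqn{k_A = 18}, \eqn{k_{AR} = 4},
#' \eqn{k_{core} = 1600~T\mu m^4}; Gay-Berne strength \eqn{\epsilon_0 = 0.5}
#' with elliptical cutoff semi-axes 100 and 43.75 \eqn{\mu m} and exponents
#' \eqn{\mu = \nu = 1}; motility strength \eqn{k_{move} = 1~T/\mu m}; polarity
#' decay time 30 min (2000 MCS at the fixed calibration 100 MCS = 1.5 min) and
#' polarity reversals with probability 0.01 every 100 MCS (mean flip time
#' 150 min). The growth schedule seeds circular cells of radius `r0` = 10
#' \eqn{\mu m} at ~70 cells/mm^2, relaxes for 10 h without division, then
#' divides one cell per 100 MCS until the terminal count (3000 cells for the
#' default 1200 x 1200 \eqn{\mu m} box, ~2000 cells/mm^2) is reached.
#'
#' @param T effective temperature setting the energy scale (default 1).
#' @param delta_r max displacement proposal, micrometres.
#' @param delta_phi max rotation proposal, radians (default 2 degrees).
#' @param delta_a,delta_b max semi-axis change proposals, micrometres.
#' @param A_pref preferred cell area, square micrometres.
#' @param AR_pref preferred aspect ratio (semi-major / semi-minor).
#' @param k_A,k_AR area and aspect-ratio penalty strengths, energy units.
#' @param k_core core (anti-squeezing) penalty strength, energy * um^4.
#' @param eps0 Gay-Berne interaction strength.
#' @param rc_maj,rc_min semi-axes of the elliptical interaction cutoff, um.
#' @param k_move motility strength, energy per micrometre.
#' @param mu,nu Gay-Berne strength exponents.
#' @param tau_pol polarity decay timescale, MCS (30 min = 2000 MCS).
#' @param tau_flip_prob polarity reversal probability per check.
#' @param flip_period MCS between reversal checks.
#' @param alpha division shape sensitivity (0 = area only; 2 = the
#'   isotropic-cells-divide regime).
#' @param L periodic box side, micrometres.
#' @param mcs_to_min simulated minutes per MCS (1.5 min / 100 MCS).
#' @param move_mix probabilities of (displace, rotate, resize a, resize b).
#' @param rho_init,rho_f initial and terminal densities, cells/mm^2.
#' @param n_init number of seeded cells; default `round(rho_init*(L/1000)^2)`.
#' @param terminal_count cell count at which division halts; default
#'   `round(rho_f*(L/1000)^2)`. The count, not the density, is authoritative.
#' @param r0 initial (circular) cell radius, micrometres.
#' @param relax_time division-free relaxation time, simulated hours.
#' @param division_period MCS between divisions in the growth phase.
#' @param daughter_factor daughter/parent axis ratio at division.
#' @param division_mode `"shape_dependent"` (softmax in area and aspect
#'   ratio) or `"uniform_random"` (control).
#' @param polarity_update `"accepted"` (polarity feedback uses the realized,
#'   i.e. accepted, displacement; default) or `"proposed"` (sensitivity
#'   variant using the proposed displacement whether or not accepted).
#' @param skin neighbor-list rebuild threshold: lists are rebuilt whenever a
#'   cell has moved more than this distance (um) since the last rebuild, and
#'   on every division.
#' @param n_feeler_rings,n_feeler_points number of concentric feeler ellipses
#'   and points per ellipse used to estimate ridge overlap.
#'
#' @return A list of class `model_params`.
#' @export
#' @examples
#' p <- model_params(L = 600)
#' p$terminal_count # 750 cells for a 600 um box
model_params <- function(T = 1,
                         delta_r = 1.2,
                         delta_phi = 2 * pi / 180,
                         delta_a = 0.6,
                         delta_b = 0.6,
                         A_pref = 1400,
                         AR_pref = 4,
                         k_A = 18,
                         k_AR = 4,
                         k_core = 1600,
                         eps0 = 0.5,
                         rc_maj = 100,
                         rc_min = 43.75,
                         k_move = 1,
                         mu = 1,
                         nu = 1,
                         tau_pol = 2000,
                         tau_flip_prob = 0.01,
                         flip_period = 100,
                         alpha = 2,
                         L = 1200,
                         mcs_to_min = 1.5 / 100,
                         move_mix = c(displace = 0.10, rotate = 0.20,
                                      resize_a = 0.35, resize_b = 0.35),
                         rho_init = 100 / 1.44,
                         rho_f = 3000 / 1.44,
                         n_init = NULL,
                         terminal_count = NULL,
                         r0 = 10,
                         relax_time = 10,
                         division_period = 100,
                         daughter_factor = 0.4,
                         division_mode = c("shape_dependent", "uniform_random"),
                         polarity_update = c("accepted", "proposed"),
                         skin = 25,
                         n_feeler_rings = 3,
                         n_feeler_points = 64) {
  division_mode <- match.arg(division_mode)
  polarity_update <- match.arg(polarity_update)

  lengths_pos <- c(delta_r = delta_r, delta_a = delta_a, delta_b = delta_b,
                   A_pref = A_pref, AR_pref = AR_pref, rc_maj = rc_maj,
                   rc_min = rc_min, L = L, r0 = r0, skin = skin,
                   T = T, delta_phi = delta_phi, mcs_to_min = mcs_to_min,
                   tau_pol = tau_pol)
  bad <- names(lengths_pos)[!is.finite(lengths_pos) | lengths_pos <= 0]
  if (length(bad) > 0)
    stop("model_params: parameter(s) must be positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  nonneg <- c(k_A = k_A, k_AR = k_AR, k_core = k_core, eps0 = eps0,
              k_move = k_move, tau_flip_prob = tau_flip_prob, alpha = alpha)
  bad <- names(nonneg)[!is.finite(nonneg) | nonneg < 0]
  if (length(bad) > 0)
    stop("model_params: parameter(s) must be non-negative: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (length(move_mix) != 4 || any(move_mix < 0) ||
      abs(sum(move_mix) - 1) > 1e-9)
    stop("model_params: move_mix must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  if (daughter_factor <= 0 || daughter_factor >= 1)
    stop("model_params: daughter_factor must lie in (0, 1)", call. = FALSE)
  if (tau_flip_prob > 1)
    stop("model_params: tau_flip_prob must lie in [0, 1]", call. = FALSE)

  if (is.null(n_init)) n_init <- as.integer(round(rho_init * (L / 1000)^2))
  if (is.null(terminal_count))
    terminal_count <- as.integer(round(rho_f * (L / 1000)^2))
  relax_mcs <- as.integer(round(relax_time * 60 / mcs_to_min))
  if (division_period > 0 && relax_mcs %% division_period != 0)
    stop("model_params: relax_time must correspond to a whole number of ",
         "division periods", call. = FALSE)

  structure(list(
    T = T, delta_r = delta_r, delta_phi = delta_phi,
    delta_a = delta_a, delta_b = delta_b,
    A_pref = A_pref, AR_pref = AR_pref,
    k_A = k_A, k_AR = k_AR, k_core = k_core,
    eps0 = eps0, rc_maj = rc_maj, rc_min = rc_min,
    k_move = k_move, mu = mu, nu = nu,
    tau_pol = tau_pol, tau_flip_prob = tau_flip_prob,
    flip_period = as.integer(flip_period),
    alpha = alpha, L = L, mcs_to_min = mcs_to_min,
    move_mix = unname(move_mix),
    rho_init = rho_init, rho_f = rho_f,
    n_init = as.integer(n_init),
    terminal_count = as.integer(terminal_count),
    r0 = r0, relax_time = relax_time, relax_mcs = relax_mcs,
    division_period = as.integer(division_period),
    daughter_factor = daughter_factor,
    division_mode = division_mode,
    polarity_update = polarity_update,
    skin = skin,
    n_feeler_rings = as.integer(n_feeler_rings),
    n_feeler_points = as.integer(n_feeler_points)
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Monolayer model parameters\n")
  cat(sprintf("  box L = %g um, T = %g\n", x$L, x$T))
  cat(sprintf("  preferred shape: A = %g um^2, AR = %g\n", x$A_pref, x$AR_pref))
  cat(sprintf("  proposals (um/rad): dr=%g dphi=%g da=%g db=%g; mix %s\n",
              x$delta_r, x$delta_phi, x$delta_a, x$delta_b,
              paste(x$move_mix, collapse = "/")))
  cat(sprintf("  Gay-Berne: eps0=%g, cutoff (%g, %g) um, mu=%g nu=%g\n",
              x$eps0, x$rc_maj, x$rc_min, x$mu, x$nu))
  cat(sprintf("  motility: k_move=%g, tau_pol=%g MCS, flip p=%g / %d MCS\n",
              x$k_move, x$tau_pol, x$tau_flip_prob, x$flip_period))
  cat(sprintf("  growth: %d -> %d cells, relax %g h, 1 division / %d MCS, alpha=%g (%s)\n",
              x$n_init, x$terminal_count, x$relax_time, x$division_period,
              x$alpha, x$division_mode))
  invisible(x)
}

#' Ridged substrate pattern
#'
#' Concentric ridge annuli centred in a periodic box. Ring centre radii are
#' `k * spacing` for `k = 1, 2, ...`, all below `L/2`; there is no ring at
#' radius zero, so the "inner ring" region is the disc of radius `spacing`.
#' Membership is evaluated with the minimum-image distance to the centre, so
#' the square-periodic tiling of +1 ring centres automatically produces a -1
#' (saddle) defect at the box corners: the corner region is bounded by the
#' outermost ring arcs of the four neighbouring pattern images, whose
#' orientations impose the saddle director field across it.
#'
#' @param L periodic box side, micrometres.
#' @param center pattern centre (the +1 defect core); default box centre.
#' @param spacing radial distance between consecutive ridges, micrometres.
#' @param width radial width of each ridge, micrometres. The published model
#'   does not state a simulated width; 4 um (narrow relative to the 60 um
#'   spacing) is the package default.
#' @param k_r ridge strength: the energy cost of a cell fully overlapping a
#'   ridge. Default 120 (the strong-ridge condition).
#'
#' @return A list of class `ridge_pattern` with elements `center`, `spacing`,
#'   `width`, `k_r`, `n_rings`, `radii`, and `L`.
#' @export
#' @examples
#' ridge_pattern(L = 1200)$radii # 60, 120, ..., 540
ridge_pattern <- function(L, center = c(L / 2, L / 2), spacing = 60,
                          width = 4, k_r = 120) {
  if (L <= 0 || spacing <= 0 || width <= 0 || width >= spacing)
    stop("ridge_pattern: need L, spacing > 0 and 0 < width < spacing",
         call. = FALSE)
  if (k_r < 0) stop("ridge_pattern: k_r must be non-negative", call. = FALSE)
  n_rings <- as.integer(floor(L / (2 * spacing) - 1e-9))
  if (n_rings < 1)
    stop("ridge_pattern: box too small for a single ring (need L > 2*spacing)",
         call. = FALSE)
  structure(list(center = as.numeric(center), spacing = spacing,
                 width = width, k_r = k_r, n_rings = n_rings,
                 radii = spacing * seq_len(n_rings), L = L),
            class = "ridge_pattern")
}

#' @export
print.ridge_pattern <- function(x, ...) {
  cat(sprintf("Ridge pattern: %d rings at %s um (width %g um, k_r = %g)\n",
              x$n_rings, paste(x$radii, collapse = ", "), x$width, x$k_r))
  cat(sprintf("  +1 defect at (%g, %g); -1 defect at the box corners (L = %g um)\n",
              x$center[1], x$center[2], x$L))
  invisible(x)
}
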