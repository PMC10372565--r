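# Metropolis Monte Carlo dynamics. One MCS proposes a single move for every
# cell in random order; acceptance probability is min(1, exp(-dE/T)). The
# fast path is the compiled engine (run_mcs); the single-step functions below
# expose the same rules for inspection and testing, and run_mcs_reference is
# a pure-R sweep that reproduces the engine draw-for-draw on small systems.

engine_params <- function(params) {
  params[c("T", "delta_r", "delta_phi", "delta_a", "delta_b", "A_pref",
           "AR_pref", "k_A", "k_AR", "k_core", "eps0", "rc_maj", "rc_min",
           "mu", "nu", "k_move", "tau_pol", "tau_flip_prob", "flip_period",
           "L", "skin", "move_mix", "alpha", "daughter_factor", "relax_mcs",
           "division_period", "terminal_count", "division_mode",
           "polarity_update", "n_feeler_rings", "n_feeler_points")]
}

cells_to_matrix <- function(cells) {
  m <- as.matrix(cells[, c("id", "parent_id", "x", "y", "a", "b", "phi",
                           "px", "py")])
  m[is.na(m[, "parent_id"]), "parent_id"] <- -1
  m
}

matrix_to_cells <- function(m) {
  d <- data.frame(id = as.integer(m[, 1]), parent_id = as.integer(m[, 2]),
                  x = m[, 3], y = m[, 4], a = m[, 5], b = m[, 6],
                  phi = m[, 7], px = m[, 8], py = m[, 9])
  d$parent_id[d$parent_id < 0] <- NA_integer_
  d
}

frame_to_df <- function(m) {
  d <- matrix_to_cells(m)
  cbind(mcs = attr(m, "mcs"), d)
}

#' Propose a Monte Carlo move
#'
#' Samples the move kind from the move mix (default 10% displacement, 20%
#' rotation, 35% each axis change) and the move amplitude: displacement
#' magnitude `delta_r * X` at uniform angle `2*pi*Y`; rotation
#' `2*delta_phi*(X - 0.5)`; axis changes `delta_a|b * (X - 0.5)`; with
#' `X, Y ~ U[0, 1]` from R's RNG stream.
#'
#' @param cell single-row cells data frame (unused by the sampling itself;
#'   kept for interface symmetry).
#' @param params a [model_params()] object.
#' @return list with elements `kind` (one of `"displace"`, `"rotate"`,
#'   `"resize_a"`, `"resize_b"`) and `delta` (length-2 displacement in um, or
#'   a scalar in radians / um).
#' @export
propose <- function(cell, params) {
  mm <- cumsum(params$move_mix)
  u <- stats::runif(1)
  if (u < mm[1]) {
    X <- stats::runif(1); Y <- stats::runif(1)
    psi <- 2 * pi * Y
    list(kind = "displace",
         delta = params$delta_r * X * c(cos(psi), sin(psi)))
  } else if (u < mm[2]) {
    list(kind = "rotate", delta = 2 * params$delta_phi * (stats::runif(1) - 0.5))
  } else if (u < mm[3]) {
    list(kind = "resize_a", delta = params$delta_a * (stats::runif(1) - 0.5))
  } else {
    list(kind = "resize_b", delta = params$delta_b * (stats::runif(1) - 0.5))
  }
}

#' Motility energy change of a displacement
#'
#' \eqn{\Delta E_{move} = -k_{move}\,(\Pi/|\Pi|)\cdot\Delta r} with
#' \eqn{\Pi = (\hat u \cdot p)\,\hat u} the polarity projected on the long
#' axis: only the sign of the projection matters, so
#' \eqn{\Delta E_{move} = -k_{move}\,\mathrm{sign}(\hat u\cdot p)\,
#' (\hat u\cdot\Delta r)}, independent of \eqn{|p|}, and zero when the
#' polarity is perpendicular to the long axis (\eqn{\Pi = 0} convention).
#'
#' @param cell single-row cells data frame.
#' @param dr length-2 proposed displacement, micrometres.
#' @param params a [model_params()] object.
#' @return numeric scalar energy change.
#' @export
motility_delta <- function(cell, dr, params) {
  u <- c(cos(cell$phi[1]), sin(cell$phi[1]))
  up <- sum(u * c(cell$px[1], cell$py[1]))
  if (up == 0 || params$k_move == 0) return(0)
  -params$k_move * sign(up) * sum(u * dr)
}

#' Local energy of one cell
#'
#' Shape + core + ridge energy of the cell plus the sum of Gay-Berne pair
#' energies with all cells inside its elliptical interaction cutoff. (The
#' motility term is not part of the state energy; it enters only as a
#' \eqn{\Delta E} contribution for displacement proposals.)
#'
#' @param i cell index.
#' @param state a `sim_state` (see [initialize_state()]).
#' @return numeric scalar.
#' @export
local_energy <- function(i, state) {
  cl <- state$cells
  p <- state$params
  e <- shape_energy(cl[i, ], p) + core_energy(cl[i, ], p)
  if (!is.null(state$pattern)) e <- e + ridge_energy(cl[i, ], state$pattern, p)
  e + ref_pair_sum(cl, i, cl$x[i], cl$y[i], cl$a[i], cl$b[i], cl$phi[i], p)
}

# pair-energy sum of cell c (possibly with proposed coordinates) against all
# other cells inside its exact cutoff, in ascending index order
ref_pair_sum <- function(cells, c, x, y, a, b, phi, params) {
  n <- nrow(cells)
  if (n <= 1) return(0)
  js <- setdiff(seq_len(n), c)
  ci <- data.frame(x = x, y = y, a = a, b = b, phi = phi)
  mj <- as.matrix(cells[js, c("x", "y", "a", "b", "phi")])
  mi <- matrix(rep(as.numeric(ci[1, ]), each = length(js)), ncol = 5)
  keep <- cpp_in_cutoff(mi, mj, params$L, params$rc_maj, params$rc_min)
  if (!any(keep)) return(0)
  sum(cpp_pair_energy(mi[keep, , drop = FALSE], mj[keep, , drop = FALSE],
                      params$L, params$eps0, params$mu, params$nu))
}

one_ridge_energy <- function(x, y, a, b, phi, pattern, params) {
  if (is.null(pattern) || pattern$k_r == 0) return(0)
  scales <- rev(seq_len(params$n_feeler_rings)) / params$n_feeler_rings
  pattern$k_r * cpp_ridge_overlap(x, y, a, b, phi, pattern$center[1],
                                  pattern$center[2], pattern$spacing,
                                  pattern$width, pattern$n_rings, pattern$L,
                                  params$n_feeler_points, scales)
}

#' Apply one Metropolis move to one cell
#'
#' Computes the energy change of the proposal (ridge and pair terms for all
#' moves; shape and core for resizes; the motility term for displacements),
#' draws the acceptance uniform, and accepts with probability
#' `min(1, exp(-dE/T))`. Resize proposals that would violate `a >= b > 0` are
#' rejected outright (the acceptance draw is still consumed, matching the
#' engine's stream discipline). On an accepted rotation the polarity vector
#' is rotated by the same angle.
#'
#' @param i index of the cell the proposal addresses.
#' @param proposal a [propose()] result.
#' @param state a `sim_state`.
#' @return list with elements `state` (possibly mutated), `accepted`, and
#'   `dE`.
#' @export
metropolis_step <- function(i, proposal, state) {
  cl <- state$cells
  p <- state$params
  pat <- state$pattern
  ua <- stats::runif(1)

  if (proposal$kind == "displace") {
    dx <- proposal$delta[1]; dy <- proposal$delta[2]
    nx <- wrap_position(cl$x[i] + dx, p$L)
    ny <- wrap_position(cl$y[i] + dy, p$L)
    dE <- one_ridge_energy(nx, ny, cl$a[i], cl$b[i], cl$phi[i], pat, p) -
      one_ridge_energy(cl$x[i], cl$y[i], cl$a[i], cl$b[i], cl$phi[i], pat, p) +
      ref_pair_sum(cl, i, nx, ny, cl$a[i], cl$b[i], cl$phi[i], p) -
      ref_pair_sum(cl, i, cl$x[i], cl$y[i], cl$a[i], cl$b[i], cl$phi[i], p) +
      motility_delta(cl[i, ], c(dx, dy), p)
    acc <- dE <= 0 || ua < exp(-dE / p$T)
    if (acc) { cl$x[i] <- nx; cl$y[i] <- ny }
  } else if (proposal$kind == "rotate") {
    nphi <- cl$phi[i] + proposal$delta
    dE <- one_ridge_energy(cl$x[i], cl$y[i], cl$a[i], cl$b[i], nphi, pat, p) -
      one_ridge_energy(cl$x[i], cl$y[i], cl$a[i], cl$b[i], cl$phi[i], pat, p) +
      ref_pair_sum(cl, i, cl$x[i], cl$y[i], cl$a[i], cl$b[i], nphi, p) -
      ref_pair_sum(cl, i, cl$x[i], cl$y[i], cl$a[i], cl$b[i], cl$phi[i], p)
    acc <- dE <= 0 || ua < exp(-dE / p$T)
    if (acc) {
      cl$phi[i] <- nphi
      rot <- proposal$delta
      npx <- cos(rot) * cl$px[i] - sin(rot) * cl$py[i]
      npy <- sin(rot) * cl$px[i] + cos(rot) * cl$py[i]
      cl$px[i] <- npx; cl$py[i] <- npy
    }
  } else {
    na <- cl$a[i]; nb <- cl$b[i]
    if (proposal$kind == "resize_a") na <- na + proposal$delta
    else nb <- nb + proposal$delta
    if (na < nb || nb <= 0) {
      return(list(state = state, accepted = FALSE, dE = Inf))
    }
    dE <- cpp_shape_energy(na, nb, p$A_pref, p$AR_pref, p$k_A, p$k_AR) +
      cpp_core_energy(na, nb, p$k_core) -
      cpp_shape_energy(cl$a[i], cl$b[i], p$A_pref, p$AR_pref, p$k_A, p$k_AR) -
      cpp_core_energy(cl$a[i], cl$b[i], p$k_core) +
      one_ridge_energy(cl$x[i], cl$y[i], na, nb, cl$phi[i], pat, p) -
      one_ridge_energy(cl$x[i], cl$y[i], cl$a[i], cl$b[i], cl$phi[i], pat, p) +
      ref_pair_sum(cl, i, cl$x[i], cl$y[i], na, nb, cl$phi[i], p) -
      ref_pair_sum(cl, i, cl$x[i], cl$y[i], cl$a[i], cl$b[i], cl$phi[i], p)
    acc <- dE <= 0 || ua < exp(-dE / p$T)
    if (acc) { cl$a[i] <- na; cl$b[i] <- nb }
  }
  state$cells <- cl
  list(state = state, accepted = acc, dE = dE)
}

#' Polarity feedback update
#'
#' \eqn{p_t = (1 - 1/\tau_{pol})\,p_{t-1} + \Delta r}, applied once per cell
#' per MCS, where \eqn{\Delta r} is the displacement realized (accepted) by
#' that cell this MCS — zero if no displacement was proposed or the proposal
#' was rejected. With no input the polarity magnitude decays geometrically;
#' under a constant displacement `d` it converges to `tau_pol * d`.
#'
#' @param cell single-row cells data frame.
#' @param dr_realized length-2 realized displacement this MCS, micrometres.
#' @param params a [model_params()] object.
#' @return the cell with updated polarity.
#' @export
update_polarity <- function(cell, dr_realized, params) {
  fac <- 1 - 1 / params$tau_pol
  cell$px <- fac * cell$px + dr_realized[1]
  cell$py <- fac * cell$py + dr_realized[2]
  cell
}

#' Stochastic polarity reversals
#'
#' At every reversal check (every `flip_period` MCS, i.e. 1.5 min), each cell
#' independently reverses its polarity `p -> -p` with probability
#' `tau_flip_prob` (default 0.01), giving geometric inter-flip waiting times
#' with mean `1/p = 100` checks = 150 simulated minutes.
#'
#' @param state a `sim_state`.
#' @return the state with flipped polarities.
#' @export
flip_polarities <- function(state) {
  n <- nrow(state$cells)
  u <- stats::runif(n)
  fl <- u < state$params$tau_flip_prob
  state$cells$px[fl] <- -state$cells$px[fl]
  state$cells$py[fl] <- -state$cells$py[fl]
  state
}

#' Advance the simulation by whole Monte Carlo steps
#'
#' Runs the compiled engine for `n_mcs` MCS from the current state. Each MCS:
#' a fresh random permutation of the cells; one proposal and Metropolis
#' decision per cell; a polarity-feedback update per cell; at `flip_period`
#' boundaries, stochastic polarity reversals; and at `division_period`
#' boundaries in the growth phase (after `relax_time`, while below
#' `terminal_count`), exactly one division. Neighbor lists are rebuilt after
#' any cell moves more than `skin` um and on every division. With identical
#' seed, parameters, and call pattern the trajectory is reproducible.
#'
#' @param state a `sim_state` from [initialize_state()].
#' @param n_mcs number of Monte Carlo steps to run.
#' @param snapshot_at integer vector of absolute MCS values at which to record
#'   a frame.
#' @return the advanced `sim_state`; recorded frames are appended to
#'   `state$frames` (data frames with an `mcs` column), division events to
#'   `state$divisions`, and per-1000-MCS acceptance logs to `state$log`.
#' @export
run_mcs <- function(state, n_mcs, snapshot_at = integer(0)) {
  stopifnot(inherits(state, "sim_state"), n_mcs >= 0)
  if (n_mcs == 0) return(state)
  snapshot_at <- sort(unique(as.integer(snapshot_at)))
  snapshot_at <- snapshot_at[snapshot_at > state$mcs &
                             snapshot_at <= state$mcs + n_mcs]
  pat <- state$pattern
  res <- cpp_run(cells_to_matrix(state$cells), state$mcs, state$next_id,
                 engine_params(state$params),
                 if (is.null(pat)) list() else pat,
                 as.integer(n_mcs), snapshot_at)
  state$cells <- matrix_to_cells(res$cells)
  state$mcs <- res$mcs
  state$next_id <- res$next_id
  if (length(res$frames) > 0)
    state$frames <- c(state$frames, lapply(res$frames, frame_to_df))
  if (nrow(res$divisions) > 0) {
    dv <- as.data.frame(res$divisions)
    names(dv) <- c("mcs", "parent_id", "daughter1", "daughter2",
                   "parent_area", "parent_ar")
    state$divisions <- rbind(state$divisions, dv)
  }
  if (nrow(res$acclog) > 0) {
    lg <- as.data.frame(res$acclog)
    names(lg) <- c("mcs", "n_cells", "prop_displace", "prop_rotate",
                   "prop_resize_a", "prop_resize_b", "acc_displace",
                   "acc_rotate", "acc_resize_a", "acc_resize_b",
                   "mean_polarity")
    state$log <- rbind(state$log, lg)
  }
  state
}

# Pure-R sweep reproducing the engine draw-for-draw (documented RNG order in
# src/engine.cpp). Used to validate the compiled engine on small systems; not
# exported, and far too slow for production runs.
run_mcs_reference <- function(state, n_mcs) {
  p <- state$params
  pat <- state$pattern
  cl <- state$cells
  next_id <- state$next_id
  mm <- cumsum(p$move_mix)
  proposed_pol <- identical(p$polarity_update, "proposed")

  for (step in seq_len(n_mcs)) {
    g <- state$mcs + step
    n <- nrow(cl)
    perm <- seq_len(n)
    if (n >= 2) for (i in n:2) {
      j <- floor(stats::runif(1) * i) + 1
      if (j > i) j <- i
      tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
    }
    drx <- numeric(n); dry <- numeric(n)

    for (c in perm) {
      u1 <- stats::runif(1)
      if (u1 < mm[1]) {
        X <- stats::runif(1); Y <- stats::runif(1)
        psi <- 2 * pi * Y
        dx <- p$delta_r * X * cos(psi); dy <- p$delta_r * X * sin(psi)
        nx <- wrap_position(cl$x[c] + dx, p$L)
        ny <- wrap_position(cl$y[c] + dy, p$L)
        dE <- one_ridge_energy(nx, ny, cl$a[c], cl$b[c], cl$phi[c], pat, p) -
          one_ridge_energy(cl$x[c], cl$y[c], cl$a[c], cl$b[c], cl$phi[c], pat, p) +
          ref_pair_sum(cl, c, nx, ny, cl$a[c], cl$b[c], cl$phi[c], p) -
          ref_pair_sum(cl, c, cl$x[c], cl$y[c], cl$a[c], cl$b[c], cl$phi[c], p)
        ux <- cos(cl$phi[c]); uy <- sin(cl$phi[c])
        up <- ux * cl$px[c] + uy * cl$py[c]
        if (up != 0 && p$k_move != 0)
          dE <- dE - p$k_move * sign(up) * (ux * dx + uy * dy)
        ua <- stats::runif(1)
        if (dE <= 0 || ua < exp(-dE / p$T)) {
          cl$x[c] <- nx; cl$y[c] <- ny
          drx[c] <- dx; dry[c] <- dy
        } else if (proposed_pol) {
          drx[c] <- dx; dry[c] <- dy
        }
      } else if (u1 < mm[2]) {
        X <- stats::runif(1)
        dphi <- 2 * p$delta_phi * (X - 0.5)
        nphi <- cl$phi[c] + dphi
        dE <- one_ridge_energy(cl$x[c], cl$y[c], cl$a[c], cl$b[c], nphi, pat, p) -
          one_ridge_energy(cl$x[c], cl$y[c], cl$a[c], cl$b[c], cl$phi[c], pat, p) +
          ref_pair_sum(cl, c, cl$x[c], cl$y[c], cl$a[c], cl$b[c], nphi, p) -
          ref_pair_sum(cl, c, cl$x[c], cl$y[c], cl$a[c], cl$b[c], cl$phi[c], p)
        ua <- stats::runif(1)
        if (dE <= 0 || ua < exp(-dE / p$T)) {
          cl$phi[c] <- nphi
          npx <- cos(dphi) * cl$px[c] - sin(dphi) * cl$py[c]
          npy <- sin(dphi) * cl$px[c] + cos(dphi) * cl$py[c]
          cl$px[c] <- npx; cl$py[c] <- npy
        }
      } else {
        X <- stats::runif(1)
        na <- cl$a[c]; nb <- cl$b[c]
        if (u1 < mm[3]) na <- na + p$delta_a * (X - 0.5)
        else nb <- nb + p$delta_b * (X - 0.5)
        ua <- stats::runif(1)
        if (na < nb || nb <= 0) next
        dE <- cpp_shape_energy(na, nb, p$A_pref, p$AR_pref, p$k_A, p$k_AR) +
          cpp_core_energy(na, nb, p$k_core) -
          cpp_shape_energy(cl$a[c], cl$b[c], p$A_pref, p$AR_pref, p$k_A, p$k_AR) -
          cpp_core_energy(cl$a[c], cl$b[c], p$k_core) +
          one_ridge_energy(cl$x[c], cl$y[c], na, nb, cl$phi[c], pat, p) -
          one_ridge_energy(cl$x[c], cl$y[c], cl$a[c], cl$b[c], cl$phi[c], pat, p) +
          ref_pair_sum(cl, c, cl$x[c], cl$y[c], na, nb, cl$phi[c], p) -
          ref_pair_sum(cl, c, cl$x[c], cl$y[c], cl$a[c], cl$b[c], cl$phi[c], p)
        if (dE <= 0 || ua < exp(-dE / p$T)) {
          cl$a[c] <- na; cl$b[c] <- nb
        }
      }
    }

    fac <- 1 - 1 / p$tau_pol
    cl$px <- fac * cl$px + drx
    cl$py <- fac * cl$py + dry

    if (p$flip_period > 0 && g %% p$flip_period == 0) {
      u <- stats::runif(n)
      fl <- u < p$tau_flip_prob
      cl$px[fl] <- -cl$px[fl]
      cl$py[fl] <- -cl$py[fl]
    }

    if (p$division_period > 0 && g %% p$division_period == 0 &&
        g >= p$relax_mcs && n < p$terminal_count) {
      u <- stats::runif(1)
      if (p$division_mode == "uniform_random") {
        idx <- min(n, floor(u * n) + 1)
      } else {
        ex <- pi * cl$a * cl$b / p$A_pref - p$alpha * (cl$a / cl$b) / p$AR_pref
        w <- exp(ex - max(ex))
        idx <- which(cumsum(w) >= u * sum(w))[1]
        if (is.na(idx)) idx <- n
      }
      pa <- cl$a[idx]; pb <- cl$b[idx]
      pid <- cl$id[idx]
      off <- p$daughter_factor * pa
      ux <- cos(cl$phi[idx]); uy <- sin(cl$phi[idx])
      d2 <- cl[idx, ]
      cl$x[idx] <- wrap_position(cl$x[idx] + off * ux, p$L)
      cl$y[idx] <- wrap_position(cl$y[idx] + off * uy, p$L)
      cl$a[idx] <- p$daughter_factor * pa
      cl$b[idx] <- p$daughter_factor * pb
      cl$id[idx] <- next_id; cl$parent_id[idx] <- pid
      d2$x <- wrap_position(d2$x - off * ux, p$L)
      d2$y <- wrap_position(d2$y - off * uy, p$L)
      d2$a <- p$daughter_factor * pa
      d2$b <- p$daughter_factor * pb
      d2$id <- next_id + 1L; d2$parent_id <- pid
      d2$px <- cl$px[idx]; d2$py <- cl$py[idx]
      cl <- rbind(cl, d2)
      rownames(cl) <- NULL
      next_id <- next_id + 2L
    }
  }

  state$cells <- cl
  state$mcs <- state$mcs + n_mcs
  state$next_id <- next_id
  state
}
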