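# Seeding, growth schedule, and shape-dependent division.

#' Initialize a simulation state
#'
#' Seeds `n_init` circular cells of radius `r0` (default 10 um) at uniformly
#' random, non-overlapping positions in the periodic box (circle-circle
#' rejection sampling), with uniformly random orientations in `[0, pi)` and
#' unit polarity vectors at uniformly random angles. For the default
#' 1200 x 1200 um box this is 100 cells (~70 cells/mm^2).
#'
#' @param params a [model_params()] object.
#' @param pattern a [ridge_pattern()] object, or NULL for a plain substrate.
#' @param seed optional integer; when given, `set.seed(seed)` is called so the
#'   whole trajectory is reproducible.
#' @param max_attempts placement attempts per cell before giving up.
#' @return a list of class `sim_state` with elements `cells`, `mcs` (= 0),
#'   `next_id`, `params`, `pattern`, plus empty `frames`, `divisions`, `log`
#'   accumulators.
#' @export
#' @examples
#' st <- initialize_state(model_params(L = 600), seed = 1)
#' nrow(st$cells) # 25 founder cells
initialize_state <- function(params, pattern = NULL, seed = NULL,
                             max_attempts = 5000L) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_init
  L <- params$L
  r0 <- params$r0
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      cx <- stats::runif(1, 0, L)
      cy <- stats::runif(1, 0, L)
      if (i == 1) { ok <- TRUE }
      else {
        dx <- minimum_image(x[seq_len(i - 1)] - cx, L)
        dy <- minimum_image(y[seq_len(i - 1)] - cy, L)
        ok <- all(dx^2 + dy^2 > (2 * r0)^2)
      }
      if (ok) { x[i] <- cx; y[i] <- cy; break }
    }
    if (!ok)
      stop("initialize_state: failed to place cell ", i, " after ",
           max_attempts, " attempts (density too high for r0 = ", r0, ")",
           call. = FALSE)
  }
  phi <- stats::runif(n, 0, pi)
  pang <- stats::runif(n, 0, 2 * pi)
  cells <- make_cells(x = x, y = y, a = r0, b = r0, phi = phi,
                      px = cos(pang), py = sin(pang),
                      id = seq_len(n), parent_id = NA_integer_)
  structure(list(cells = cells, mcs = 0L, next_id = n + 1L,
                 params = params, pattern = pattern,
                 frames = list(), divisions = NULL, log = NULL),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("sim_state: %d cells, MCS %d (%.2f h), box %g um\n",
              nrow(x$cells), x$mcs, x$mcs * x$params$mcs_to_min / 60,
              x$params$L))
  invisible(x)
}

#' Shape-dependent division probabilities
#'
#' Cell i is selected to divide with probability proportional to
#' \eqn{\exp(A_i/A_{pref} - \alpha\,AR_i/AR_{pref})}: larger cells are more
#' likely to divide, and for \eqn{\alpha > 0} more isotropic (low aspect
#' ratio) cells are favoured. Computed with a max-shifted exponent, so the
#' weights are numerically stable for thousands of cells with extreme areas.
#'
#' @param cells cells data frame.
#' @param alpha shape sensitivity (default from `params`).
#' @param params a [model_params()] object.
#' @return numeric vector of probabilities summing to 1.
#' @export
#' @examples
#' p <- model_params()
#' cl <- make_cells(c(0, 100), c(0, 0), a = c(21.1, 29.9), b = c(21.1, 29.9),
#'                  phi = 0) # areas ~ A_pref and ~ 2 A_pref
#' division_weights(cl, alpha = 0, params = p)
division_weights <- function(cells, alpha = params$alpha, params) {
  validate_cells(cells)
  ex <- cell_area(cells) / params$A_pref -
    alpha * cell_ar(cells) / params$AR_pref
  w <- exp(ex - max(ex))
  w / sum(w)
}

#' Perform one division
#'
#' Samples a cell from [division_weights()] (or uniformly when
#' `division_mode = "uniform_random"`), and replaces it by two daughters with
#' axes `(0.4 a, 0.4 b)` (aspect ratio preserved; area deliberately not
#' conserved), the parent's orientation, centres at the parent centre
#' `+/- 0.4 a` along the long axis (so the daughters touch at the parent
#' centre and stay within the parent footprint), and the parent's polarity.
#' Daughters get fresh ids with `parent_id` set.
#'
#' @param state a `sim_state`.
#' @return the state with one more cell.
#' @export
perform_division <- function(state) {
  cl <- state$cells
  p <- state$params
  n <- nrow(cl)
  u <- stats::runif(1)
  if (identical(p$division_mode, "uniform_random")) {
    idx <- min(n, floor(u * n) + 1)
  } else {
    w <- division_weights(cl, p$alpha, p)
    idx <- which(cumsum(w) >= u)[1]
    if (is.na(idx)) idx <- n
  }
  pa <- cl$a[idx]; pb <- cl$b[idx]; pid <- cl$id[idx]
  off <- p$daughter_factor * pa
  ux <- cos(cl$phi[idx]); uy <- sin(cl$phi[idx])
  d2 <- cl[idx, ]
  cl$x[idx] <- wrap_position(cl$x[idx] + off * ux, p$L)
  cl$y[idx] <- wrap_position(cl$y[idx] + off * uy, p$L)
  cl$a[idx] <- p$daughter_factor * pa
  cl$b[idx] <- p$daughter_factor * pb
  cl$id[idx] <- state$next_id
  cl$parent_id[idx] <- pid
  d2$x <- wrap_position(d2$x - off * ux, p$L)
  d2$y <- wrap_position(d2$y - off * uy, p$L)
  d2$a <- p$daughter_factor * pa
  d2$b <- p$daughter_factor * pb
  d2$id <- state$next_id + 1L
  d2$parent_id <- pid
  cl <- rbind(cl, d2)
  rownames(cl) <- NULL
  ev <- data.frame(mcs = state$mcs, parent_id = pid,
                   daughter1 = state$next_id, daughter2 = state$next_id + 1L,
                   parent_area = pi * pa * pb, parent_ar = pa / pb)
  state$cells <- cl
  state$next_id <- state$next_id + 2L
  state$divisions <- rbind(state$divisions, ev)
  state
}

#' Is a division due at this MCS?
#'
#' The growth schedule: no divisions during the relaxation phase (the first
#' `relax_time` simulated hours), then exactly one division every
#' `division_period` MCS (default 100 MCS = 1.5 min), halting once the cell
#' count reaches `terminal_count`.
#'
#' @param mcs the MCS clock value (after completing that step).
#' @param n_cells current cell count.
#' @param params a [model_params()] object.
#' @return logical.
#' @export
#' @examples
#' p <- model_params() # relax 10 h = 40000 MCS, terminal 3000 cells
#' division_due(39900, 100, p) # FALSE: still relaxing
#' division_due(40000, 100, p) # TRUE: first division at exactly 10 h
#' division_due(50000, 3000, p) # FALSE: terminal density reached
division_due <- function(mcs, n_cells, params) {
  params$division_period > 0 &&
    mcs %% params$division_period == 0 &&
    mcs >= params$relax_mcs &&
    n_cells < params$terminal_count
}

#' Apply the growth schedule at a division boundary
#'
#' No-op unless [division_due()] holds at the state's current MCS, in which
#' case exactly one [perform_division()] is applied.
#'
#' @param state a `sim_state`.
#' @return the (possibly grown) state.
#' @export
growth_step <- function(state) {
  if (division_due(state$mcs, nrow(state$cells), state$params))
    state <- perform_division(state)
  state
}
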