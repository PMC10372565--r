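p_def <- model_params()

test_that("shape matrix has eigenvalues l^2 and d^2 along and across the axis", {
  circ <- make_cells(0, 0, a = 10, b = 10, phi = 0.7)
  expect_equal(shape_matrix(circ), 200 * diag(2))
  el <- make_cells(0, 0, a = 40, b = 10, phi = 0)
  expect_equal(shape_matrix(el), diag(c(3200, 200)))
  # rotation equivariance: similarity transform by the rotation matrix
  th <- 0.6
  el2 <- el; el2$phi <- th
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(shape_matrix(el2), R %*% diag(c(3200, 200)) %*% t(R),
               tolerance = 1e-12)
})

test_that("anisotropy chi is 0 for discs, 15/17 for identical AR = 4 cells, symmetric", {
  c1 <- make_cells(0, 0, a = 10, b = 10, phi = 0)
  c2 <- make_cells(0, 0, a = 42, b = 10.5, phi = 1)
  expect_equal(anisotropy_chi(c1, c1), 0)
  expect_equal(anisotropy_chi(c2, c2), 15 / 17, tolerance = 1e-12)
  c3 <- make_cells(0, 0, a = 30, b = 15, phi = 2)
  expect_equal(anisotropy_chi(c2, c3), anisotropy_chi(c3, c2))
  expect_lt(anisotropy_chi(c2, c3), 1)
})

test_that("range parameter reproduces contact scales 2b, 2a, 2b", {
  b <- 10.5; a <- 42
  disc <- make_cells(0, 0, a = b, b = b, phi = 0)
  expect_equal(range_sigma(disc, disc, c(1, 0)), 2 * b, tolerance = 1e-12)
  par1 <- make_cells(0, 0, a = a, b = b, phi = 0)
  expect_equal(range_sigma(par1, par1, c(1, 0)), 2 * a, tolerance = 1e-9)
  expect_equal(range_sigma(par1, par1, c(0, 1)), 2 * b, tolerance = 1e-9)
})

test_that("interaction strength is eps0 in the circular limit and swap-invariant", {
  disc <- make_cells(0, 0, a = 9, b = 9, phi = 0.3)
  expect_equal(strength_epsilon(disc, disc, c(1, 0), p_def), p_def$eps0,
               tolerance = 1e-12)
  c1 <- make_cells(0, 0, a = 42, b = 10.5, phi = 0.2)
  c2 <- make_cells(0, 0, a = 30, b = 12, phi = 1.4)
  rh <- c(cos(0.9), sin(0.9))
  expect_equal(strength_epsilon(c1, c2, rh, p_def),
               strength_epsilon(c2, c1, rh, p_def), tolerance = 1e-12)
  # side-by-side parallel elongated: eb = (sigma0/2b)^2 by direct formula
  s0 <- sqrt(4 * 10.5^2)
  eb <- (s0 / (2 * 10.5))^2
  chi2 <- (15 / 17)^2
  ea <- 1 / sqrt(1 - chi2)
  el <- make_cells(0, 0, a = 42, b = 10.5, phi = 0)
  expect_equal(strength_epsilon(el, el, c(0, 1), p_def),
               p_def$eps0 * ea * eb, tolerance = 1e-12)
})

test_that("pair energy has the 12-6 structure: zero at sigma, depth -eps at 2^(1/6)", {
  a <- 42; b <- 10.5; L <- 1200
  c1 <- make_cells(100, 100, a = a, b = b, phi = 0)
  # side-by-side: sigma = 2b
  at_sigma <- make_cells(100, 100 + 2 * b, a = a, b = b, phi = 0)
  expect_equal(pair_energy(c1, at_sigma, L, p_def), 0, tolerance = 1e-12)
  # scaled distance r = 2^(1/6): |r12| = sigma + sigma0 (2^(1/6) - 1)
  s0 <- sqrt(4 * b^2)
  dmin <- 2 * b + s0 * (2^(1 / 6) - 1)
  at_min <- make_cells(100, 100 + dmin, a = a, b = b, phi = 0)
  eps <- strength_epsilon(c1, at_min, c(0, 1), p_def)
  expect_equal(pair_energy(c1, at_min, L, p_def), -eps, tolerance = 1e-9)
  # single sign change / interior minimum over separation
  dd <- seq(19, 100, by = 0.25)
  u <- vapply(dd, function(d)
    pair_energy(c1, make_cells(100, 100 + d, a = a, b = b, phi = 0), L,
                p_def), numeric(1))
  nz <- u[u != 0]
  expect_equal(sum(diff(sign(nz)) != 0), 1)
  expect_gte(min(u), -eps - 1e-9)
  expect_equal(min(u), -eps, tolerance = 1e-3) # grid resolution
  expect_gt(u[1], 0)
})

test_that("parallel side-by-side contact is energetically preferred", {
  a <- 42; b <- 10.5; L <- 1200
  r <- 2^(1 / 6) # compare configurations at equal scaled distance
  base <- make_cells(300, 300, a = a, b = b, phi = 0)
  at_scaled <- function(phi2, rhat) {
    c2 <- make_cells(0, 0, a = a, b = b, phi = phi2)
    sig <- range_sigma(base, c2, rhat)
    s0 <- sqrt(4 * b^2)
    d <- sig + s0 * (r - 1)
    c2$x <- 300 + d * rhat[1]; c2$y <- 300 + d * rhat[2]
    c2
  }
  side <- pair_energy(base, at_scaled(0, c(0, 1)), L, p_def)
  tee <- pair_energy(base, at_scaled(pi / 2, c(0, 1)), L, p_def)
  endend <- pair_energy(base, at_scaled(0, c(1, 0)), L, p_def)
  expect_lt(side, tee)
  expect_lt(side, endend)
})

test_that("circular-cell limit reduces to the isotropic 12-6 closed form", {
  b <- 12; L <- 800
  for (d in seq(20, 80, by = 5)) {
    c1 <- make_cells(50, 50, a = b, b = b, phi = 0.3)
    c2 <- make_cells(50 + d, 50, a = b, b = b, phi = 2.1)
    expect_equal(pair_energy(c1, c2, L, p_def), oracle_lj_circular(d, b),
                 tolerance = 1e-12)
  }
})

test_that("pair energy agrees with the matrix-formula oracle and is symmetric", {
  set.seed(7)
  L <- 900
  for (k in 1:50) {
    c1 <- random_cells(1, L, seed = 2000 + k)
    c2 <- random_cells(1, L, seed = 3000 + k)
    c2$x <- c1$x + runif(1, -80, 80)
    c2$y <- c1$y + runif(1, -80, 80)
    u <- pair_energy(c1, c2, L, p_def)
    expect_equal(u, oracle_pair_energy(c1, c2, L), tolerance = 1e-9)
    expect_equal(u, pair_energy(c2, c1, L, p_def), tolerance = 1e-12)
  }
})

test_that("elliptical cutoff admits the defining ellipse inequality", {
  p <- model_params()
  ci <- make_cells(500, 500, a = 40, b = 10, phi = 0)
  at <- function(dx, dy) make_cells(500 + dx, 500 + dy, a = 10, b = 10,
                                    phi = 0)
  expect_true(in_interaction_cutoff(ci, at(0, 0), 1200, p))
  expect_true(in_interaction_cutoff(ci, at(99, 0), 1200, p))
  expect_false(in_interaction_cutoff(ci, at(101, 0), 1200, p))
  expect_true(in_interaction_cutoff(ci, at(0, 43), 1200, p))
  expect_false(in_interaction_cutoff(ci, at(0, 44), 1200, p))
  # asymmetry: i may see j while j does not see i
  cj <- make_cells(500 + 80, 500, a = 40, b = 10, phi = pi / 2)
  expect_true(in_interaction_cutoff(ci, cj, 1200, p))
  expect_false(in_interaction_cutoff(cj, ci, 1200, p))
})

test_that("neighbor lists equal the brute-force cutoff evaluation", {
  p <- model_params(L = 600)
  cl <- random_cells(50, 600, seed = 11)
  got <- build_neighbor_lists(cl, L = 600, params = p)
  want <- oracle_neighbors(cl, 600, p$rc_maj, p$rc_min)
  expect_equal(got, want)
  # single cell and two far cells
  one <- random_cells(1, 600, seed = 1)
  expect_equal(build_neighbor_lists(one, L = 600, params = p),
               list(integer(0)))
  two <- make_cells(c(10, 310), c(10, 310), a = 20, b = 10, phi = 0)
  expect_equal(build_neighbor_lists(two, L = 600, params = p),
               list(integer(0), integer(0)))
})

test_that("neighbor bookkeeping never misses an interacting pair during dynamics", {
  p <- model_params(L = 420, n_init = 50, relax_time = 0.025,
                    terminal_count = 55)
  pat <- ridge_pattern(L = 420, k_r = 60)
  st <- initialize_state(p, pat, seed = 5)
  for (chunk in 1:4) {
    st <- run_mcs(st, 250)
    got <- build_neighbor_lists(st)
    want <- oracle_neighbors(st$cells, p$L, p$rc_maj, p$rc_min)
    expect_equal(got, want)
  }
  expect_gt(nrow(st$cells), 50) # divisions occurred, lists rebuilt en route
})
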