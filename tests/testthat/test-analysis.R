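test_that("expected orientation follows the +1 and -1 angle rules", {
  ctr <- c(0, 0); L <- 1000
  at_az <- function(az) c(cos(az * pi / 180), sin(az * pi / 180)) * 100
  expect_equal(expected_orientation(at_az(30), "+1", ctr, L), 120)
  expect_equal(expected_orientation(at_az(120), "+1", ctr, L), 30) # mod 180
  expect_equal(expected_orientation(at_az(30), "-1", ctr, L), 150)
  expect_equal(expected_orientation(at_az(120), "-1", ctr, L), 60)
  expect_equal(expected_orientation(at_az(210), "-1", ctr, L), 150)
  expect_equal(expected_orientation(at_az(300), "-1", ctr, L), 60)
  # continuity of the -1 field across the quadrant boundaries
  gap <- wrap_deviation(expected_orientation(at_az(179.9), "-1", ctr, L) -
                          expected_orientation(at_az(180.1), "-1", ctr, L))
  expect_lt(abs(gap), 0.3)
  expect_error(expected_orientation(c(0, 0), "+1", ctr, L), "centre")
})

test_that("alignment RMSD handles perfect, maximal, and uniform deviations", {
  L <- 1200; ctr <- c(600, 600)
  set.seed(41)
  az <- runif(300, 0, 2 * pi)
  r <- runif(300, 30, 500)
  x <- ctr[1] + r * cos(az); y <- ctr[2] + r * sin(az)
  theta_e <- expected_orientation(cbind(x, y), "+1", ctr, L)
  aligned <- make_cells(x, y, a = 40, b = 10, phi = theta_e * pi / 180)
  expect_equal(alignment_rmsd(aligned, "+1", ctr, L)$rmsd, 0, tolerance = 1e-9)
  off90 <- make_cells(x, y, a = 40, b = 10,
                      phi = (theta_e + 90) * pi / 180)
  expect_equal(alignment_rmsd(off90, "+1", ctr, L)$rmsd, 90, tolerance = 1e-9)
  # uniform random orientations -> 90/sqrt(3) ~ 51.96 deg
  unif <- make_cells(x, y, a = 40, b = 10, phi = runif(300, 0, pi))
  got <- alignment_rmsd(unif, "+1", ctr, L)$rmsd
  expect_equal(got, 90 / sqrt(3), tolerance = 0.12)
  # squared variant returns the mean square
  expect_equal(alignment_rmsd(unif, "+1", ctr, L, squared = TRUE)$rmsd,
               got^2, tolerance = 1e-9)
})

test_that("alignment RMSD is invariant under global rotation about the defect centre", {
  L <- 900; ctr <- c(450, 450)
  cl <- random_cells(80, L, seed = 55)
  # keep cells within L/2 of the centre: beyond it a rigid rotation is not a
  # symmetry of the torus
  set.seed(56)
  az0 <- runif(80, 0, 2 * pi); rr0 <- runif(80, 20, 0.49 * L)
  cl$x <- wrap_position(ctr[1] + rr0 * cos(az0), L)
  cl$y <- wrap_position(ctr[2] + rr0 * sin(az0), L)
  base <- alignment_rmsd(cl, "+1", ctr, L)$rmsd
  th <- 0.77
  dx <- minimum_image(cl$x - ctr[1], L); dy <- minimum_image(cl$y - ctr[2], L)
  rot <- cl
  rot$x <- wrap_position(ctr[1] + cos(th) * dx - sin(th) * dy, L)
  rot$y <- wrap_position(ctr[2] + sin(th) * dx + cos(th) * dy, L)
  rot$phi <- cl$phi + th
  expect_equal(alignment_rmsd(rot, "+1", ctr, L)$rmsd, base,
               tolerance = 1e-9)
})

test_that("radial density profiles match direct binning and conserve mass", {
  L <- 1200; ctr <- c(600, 600)
  set.seed(61)
  n <- 1000
  cl <- make_cells(runif(n, 0, L), runif(n, 0, L), a = 20, b = 10, phi = 0)
  prof <- radial_profile(cl, ctr, L, "density")
  # ring counts equal an independent histogram of distances
  d <- sqrt(oracle_mimg(cl$x - ctr[1], L)^2 + oracle_mimg(cl$y - ctr[2], L)^2)
  want <- hist(d[d < 600], breaks = seq(0, 600, by = 60), plot = FALSE)$counts
  expect_equal(prof$n, want)
  # uniform cells: deviations are 0 within counting noise
  expect_true(all(abs(prof$value) < 0.5))
  expect_lt(mean(abs(prof$value)), 0.15)
  # all cells in ring 1: large positive there, -1 (-100%) elsewhere
  inner <- make_cells(ctr[1] + runif(50, 5, 55), ctr[2], a = 10, b = 5,
                      phi = 0)
  pin <- radial_profile(inner, ctr, L, "density")
  expect_gt(pin$value[1], 10)
  expect_equal(pin$value[-1], rep(-1, 9))
  # within-range normalization: area-weighted deviations average to zero
  pr <- radial_profile(cl, ctr, L, "density", normalization = "within_range")
  area <- pi * (pr$r_hi^2 - pr$r_lo^2)
  expect_equal(sum(pr$value * area) / sum(area), 0, tolerance = 1e-12)
})

test_that("aspect-ratio profiles flag empty rings as missing", {
  L <- 1200; ctr <- c(600, 600)
  cl <- make_cells(ctr[1] + c(10, 30, 100), ctr[2], a = c(40, 20, 30),
                   b = c(10, 10, 10), phi = 0)
  pr <- radial_profile(cl, ctr, L, "aspect_ratio")
  expect_equal(pr$value[1], mean(c(4, 2)))
  expect_equal(pr$value[2], 3)
  expect_true(all(is.na(pr$value[3:10])))
})

test_that("velocity histograms resolve radial, azimuthal and isotropic motion", {
  L <- 1200; ctr <- c(600, 600)
  set.seed(71)
  n <- 400
  az <- runif(n, 0, 2 * pi); r0 <- runif(n, 100, 400)
  x0 <- ctr[1] + r0 * cos(az); y0 <- ctr[2] + r0 * sin(az)
  f0 <- cbind(mcs = 0L, make_cells(x0, y0, a = 10, b = 5, phi = 0))
  mk <- function(x1, y1) rbind(f0, cbind(mcs = 4000L,
    make_cells(x1, y1, a = 10, b = 5, phi = 0)))
  # radially outward -> all mass at 0 degrees
  h_out <- velocity_radial_histogram(mk(x0 + 5 * cos(az), y0 + 5 * sin(az)),
                                     ctr, L)
  # exactly-radial angles straddle 0/360 by floating-point rounding
  expect_equal(sum(h_out$count[h_out$bin_lo %in% c(0, 345)]), n)
  # counterclockwise circles -> 270 degrees under the clockwise-positive
  # convention
  tang <- cbind(-sin(az), cos(az))
  h_ccw <- velocity_radial_histogram(mk(x0 + 5 * tang[, 1],
                                        y0 + 5 * tang[, 2]), ctr, L)
  expect_equal(sum(h_ccw$count[h_ccw$bin_lo %in% c(255, 270)]), n)
  # isotropic displacements -> flat histogram within multinomial error
  set.seed(72)
  ang <- runif(n, 0, 2 * pi)
  h_iso <- velocity_radial_histogram(mk(x0 + 5 * cos(ang), y0 + 5 * sin(ang)),
                                     ctr, L, bin_width = 45)
  expect_true(all(abs(h_iso$count - n / 8) < 3.5 * sqrt(n * (1 / 8) * (7 / 8))))
  expect_error(velocity_radial_histogram(f0, ctr, L), "shorter")
})

test_that("on/off-ridge density ratio uses analytic areas", {
  pat <- ridge_pattern(L = 600, k_r = 120)
  set.seed(81)
  # ridge area agrees with a fine deterministic grid estimate
  gx <- seq(0.5, 599.5, by = 1)
  grid <- as.matrix(expand.grid(gx, gx))
  frac <- mean(ridge_membership(grid, pat))
  expect_equal(ridge_area(pat) / 600^2, frac, tolerance = 0.02)
  # no cells on ridges -> 0
  off <- make_cells(pat$center[1] + c(20, 90, 150), pat$center[2],
                    a = 10, b = 5, phi = 0)
  expect_equal(on_off_ridge_ratio(off, pat), 0)
  # uniform random cells -> ratio ~ 1
  n <- 40000
  cl <- make_cells(runif(n, 0, 600), runif(n, 0, 600), a = 10, b = 5, phi = 0)
  expect_equal(on_off_ridge_ratio(cl, pat), 1, tolerance = 0.15)
  # everyone on a ring -> infinite ratio, flagged
  on <- make_cells(pat$center[1] + c(60, 120), pat$center[2], a = 10, b = 5,
                   phi = 0)
  expect_warning(rr <- on_off_ridge_ratio(on, pat), "off-ridge")
  expect_identical(rr, Inf)
})

test_that("speed series converts displacement per frame interval to um/h", {
  L <- 600
  tr <- rbind(cbind(mcs = 0L, make_cells(100, 100, a = 10, b = 5, phi = 0)),
              cbind(mcs = 100L, make_cells(101, 100, a = 10, b = 5, phi = 0)),
              cbind(mcs = 200L, make_cells(101, 100, a = 10, b = 5, phi = 0)))
  ts <- mean_speed_timeseries(tr, L)
  # 1 um per 100 MCS = 1 um / 1.5 min = 40 um/h
  expect_equal(ts$mean_speed, c(40, 0))
  expect_true(all(ts$mean_speed >= 0))
  expect_error(mean_speed_timeseries(tr[tr$mcs == 0, ], L), "two frames")
})

test_that("inner-ring mean aspect ratio filters by the first ring radius", {
  pat <- ridge_pattern(L = 600, k_r = 120)
  cl <- make_cells(pat$center[1] + c(10, 40, 100), pat$center[2],
                   a = c(40, 30, 20), b = c(10, 10, 10), phi = 0)
  expect_equal(inner_ring_mean_ar(cl, pat), mean(c(4, 3)))
  empty <- make_cells(pat$center[1] + 100, pat$center[2], a = 20, b = 10,
                      phi = 0)
  expect_true(is.na(inner_ring_mean_ar(empty, pat)))
})
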