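test_that("proposals respect the move amplitudes and symmetry", {
  p <- model_params()
  set.seed(1)
  kinds <- character(4000)
  disp <- numeric(0); rot <- numeric(0)
  cell <- make_cells(0, 0, a = 40, b = 10, phi = 0)
  for (i in seq_along(kinds)) {
    pr <- propose(cell, p)
    kinds[i] <- pr$kind
    if (pr$kind == "displace") disp <- c(disp, sqrt(sum(pr$delta^2)))
    if (pr$kind == "rotate") rot <- c(rot, pr$delta)
  }
  expect_true(all(disp <= p$delta_r))
  expect_true(all(abs(rot) <= p$delta_phi))
  expect_lt(abs(mean(rot)), 3 * p$delta_phi / sqrt(12 * length(rot)))
  expect_setequal(unique(kinds),
                  c("displace", "rotate", "resize_a", "resize_b"))
})

test_that("motility energy follows the sign of the polarity projection", {
  p <- model_params(k_move = 1)
  cell <- make_cells(0, 0, a = 40, b = 10, phi = 0, px = 1, py = 0)
  expect_equal(motility_delta(cell, c(1, 0), p), -1)
  expect_equal(motility_delta(cell, c(0, 1), p), 0) # dr perpendicular to u
  cell$px <- 0; cell$py <- 1 # polarity perpendicular: Pi = 0 convention
  expect_equal(motility_delta(cell, c(1, 0), p), 0)
  cell$px <- -0.3; cell$py <- 5 # only the sign of u.p matters
  expect_equal(motility_delta(cell, c(1, 0), p), 1)
})

test_that("local energy decomposes into the published components", {
  p <- model_params(L = 600)
  pat <- ridge_pattern(L = 600, k_r = 120)
  b0 <- sqrt(p$A_pref / (pi * p$AR_pref))
  st <- initialize_state(model_params(L = 600, n_init = 1), pat, seed = 2)
  # major axis tangential so the cell tip stays clear of ring 1
  st$cells <- make_cells(pat$center[1] + 30, pat$center[2], a = 4 * b0,
                         b = b0, phi = pi / 2)
  # isolated preferred-shape cell off-ridge: core term only
  expect_equal(local_energy(1, st), 0.1294127, tolerance = 1e-6)
  # two-cell state: components add up
  st$cells <- rbind(st$cells,
                    make_cells(pat$center[1] + 55, pat$center[2] + 5,
                               a = 30, b = 10, phi = 0.2, id = 2))
  e1 <- shape_energy(st$cells[1, ], p) + core_energy(st$cells[1, ], p) +
    ridge_energy(st$cells[1, ], pat, p) +
    pair_energy(st$cells[1, ], st$cells[2, ], 600, p)
  expect_equal(local_energy(1, st), e1, tolerance = 1e-10)
})

test_that("metropolis acceptance follows min(1, exp(-dE/T)) and conventions", {
  p <- model_params(L = 600, k_move = 0)
  st <- initialize_state(model_params(L = 600, n_init = 1, k_move = 0),
                         NULL, seed = 3)
  st$cells <- make_cells(300, 300, a = 40, b = 10, phi = 0)
  # dE = 0 (isolated displacement, no pattern, no motility): always accepted
  set.seed(4)
  out <- metropolis_step(1, list(kind = "displace", delta = c(0.5, 0.2)), st)
  expect_true(out$accepted)
  expect_equal(out$dE, 0)
  expect_equal(out$state$cells$x[1], 300.5)
  # resize violating a >= b is rejected regardless of energy
  out2 <- metropolis_step(1, list(kind = "resize_a", delta = -31), st)
  expect_false(out2$accepted)
  # accepted rotation co-rotates the polarity
  st$cells$px <- 1; st$cells$py <- 0
  out3 <- metropolis_step(1, list(kind = "rotate", delta = pi / 6), st)
  expect_true(out3$accepted)
  expect_equal(atan2(out3$state$cells$py[1], out3$state$cells$px[1]), pi / 6,
               tolerance = 1e-12)
})

test_that("polarity feedback decays geometrically and saturates at tau_pol * d", {
  p <- model_params()
  cell <- make_cells(0, 0, a = 40, b = 10, phi = 0, px = 2, py = -1)
  dec <- update_polarity(cell, c(0, 0), p)
  expect_equal(c(dec$px, dec$py), (1 - 1 / p$tau_pol) * c(2, -1))
  # constant displacement drives p to the fixed point tau_pol * d
  p_small <- model_params(tau_pol = 50)
  cl <- make_cells(0, 0, a = 40, b = 10, phi = 0, px = 0, py = 0)
  for (i in 1:2000) cl <- update_polarity(cl, c(0.1, 0), p_small)
  expect_equal(cl$px, 50 * 0.1, tolerance = 1e-6)
  # tau_pol = 1: polarity equals the last displacement exactly
  p1 <- model_params(tau_pol = 1)
  cl2 <- update_polarity(make_cells(0, 0, a = 1, b = 1, phi = 0, px = 9,
                                    py = 9), c(0.3, -0.2), p1)
  expect_equal(c(cl2$px, cl2$py), c(0.3, -0.2))
})

test_that("polarity reversals are Bernoulli per cell and off at probability 0", {
  p <- model_params(tau_flip_prob = 0)
  st <- initialize_state(model_params(L = 600, n_init = 20,
                                      tau_flip_prob = 0), NULL, seed = 6)
  before <- st$cells[, c("px", "py")]
  st2 <- flip_polarities(st)
  expect_equal(st2$cells[, c("px", "py")], before)
  # flips are independent across cells (sample correlation near 0)
  p2 <- model_params(tau_flip_prob = 0.5)
  st$params <- p2
  set.seed(8)
  fl <- replicate(400, {
    s <- flip_polarities(st)
    as.numeric(s$cells$px != st$cells$px)
  })
  cc <- cor(fl[1, ], fl[2, ])
  expect_lt(abs(cc), 0.2)
})

test_that("the engine reproduces the pure-R reference sweep draw for draw", {
  p <- model_params(L = 200, n_init = 5, relax_time = 0.025,
                    terminal_count = 9, division_period = 100)
  pat <- ridge_pattern(L = 200, k_r = 60)
  set.seed(42)
  st_a <- initialize_state(p, pat)
  st_a <- run_mcs(st_a, 400)
  set.seed(42)
  st_b <- initialize_state(p, pat)
  st_b <- spindlemc:::run_mcs_reference(st_b, 400)
  expect_equal(nrow(st_a$cells), nrow(st_b$cells))
  expect_equal(st_a$cells, st_b$cells, tolerance = 1e-9)
  # and with the proposed-displacement polarity variant
  p2 <- model_params(L = 200, n_init = 5, relax_time = 0.025,
                     terminal_count = 9, polarity_update = "proposed")
  set.seed(43)
  st_c <- run_mcs(initialize_state(p2, pat), 200)
  set.seed(43)
  st_d <- spindlemc:::run_mcs_reference(initialize_state(p2, pat), 200)
  expect_equal(st_c$cells, st_d$cells, tolerance = 1e-9)
})

test_that("identical seeds give identical trajectories", {
  p <- model_params(L = 300, n_init = 10, relax_time = 0.025,
                    terminal_count = 14)
  pat <- ridge_pattern(L = 300)
  s1 <- simulate_monolayer(p, pat, seed = 99, n_mcs = 600)
  s2 <- simulate_monolayer(p, pat, seed = 99, n_mcs = 600)
  expect_identical(s1$state$cells, s2$state$cells)
  s3 <- simulate_monolayer(p, pat, seed = 100, n_mcs = 600)
  expect_false(isTRUE(all.equal(s1$state$cells$x, s3$state$cells$x)))
})

test_that("acceptance logging reports healthy per-move-type fractions", {
  p <- model_params(L = 300, n_init = 10, relax_time = 0.025,
                    terminal_count = 30)
  sim <- simulate_monolayer(p, ridge_pattern(L = 300), seed = 12,
                            n_mcs = 2000)
  lg <- sim$log
  expect_true(!is.null(lg) && nrow(lg) == 2)
  prop <- as.matrix(lg[, 3:6]); acc <- as.matrix(lg[, 7:10])
  expect_true(all(acc <= prop))
  frac <- colSums(acc) / colSums(prop)
  expect_true(all(frac > 0 & frac < 1))
})

test_that("mean speed decreases with density", {
  sims <- get_arm("a2")
  lowhi <- vapply(sims, function(s) {
    tr <- as_trajectory(s)
    ts <- mean_speed_timeseries(tr, s$params$L, s$params$mcs_to_min)
    ms <- sort(unique(tr$mcs))
    c(low = ts$mean_speed[ts$mcs == ms[2]],
      high = ts$mean_speed[ts$mcs == max(ms)])
  }, numeric(2))
  # ~800 cells/mm^2 vs terminal ~2083 cells/mm^2, paired across seeds
  expect_lt(mean(lowhi["high", ] - lowhi["low", ]), 0)
  expect_gt(mean(lowhi["low", ]), mean(lowhi["high", ]))
  tt <- t.test(lowhi["high", ], lowhi["low", ], paired = TRUE,
               alternative = "less")
  expect_lt(tt$p.value, 0.05)
})

test_that("motion near the +1 defect is predominantly azimuthal with no net radial drift", {
  sims <- get_arm("a2")
  p <- sims[[1]]$params
  at_low <- mcs_at_count(141, p)
  pooled <- NULL
  drift <- numeric(length(sims))
  for (k in seq_along(sims)) {
    s <- sims[[k]]
    tr <- as_trajectory(s)
    h <- velocity_radial_histogram(tr, s$pattern$center, p$L, window = 60,
                                   start_mcs = at_low, bin_width = 30)
    pooled <- if (is.null(pooled)) h$count else pooled + h$count
    # net radial displacement component over the window
    f0 <- tr[tr$mcs == at_low, ]
    f1 <- tr[tr$mcs == at_low + 4000, ]
    common <- intersect(f0$id, f1$id)
    f0 <- f0[match(common, f0$id), ]; f1 <- f1[match(common, f1$id), ]
    rx <- minimum_image(f0$x - s$pattern$center[1], p$L)
    ry <- minimum_image(f0$y - s$pattern$center[2], p$L)
    rn <- sqrt(rx^2 + ry^2)
    dx <- minimum_image(f1$x - f0$x, p$L); dy <- minimum_image(f1$y - f0$y, p$L)
    drift[k] <- mean((rx * dx + ry * dy) / rn)
  }
  mids <- seq(15, 345, by = 30)
  azimuthal <- mids %in% c(75, 105, 255, 285)
  radial <- mids %in% c(15, 345, 165, 195)
  expect_gt(sum(pooled[azimuthal]) / sum(pooled[radial]), 1.5)
  # the two azimuthal peaks dominate
  expect_true(which.max(pooled) %in% which(azimuthal))
  # no net radial drift at 95% confidence over the seeds
  expect_gt(t.test(drift)$p.value, 0.05)
})
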