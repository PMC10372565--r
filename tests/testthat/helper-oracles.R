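# Independent reference implementations used as oracles. These deliberately
# use different code paths (matrix algebra, explicit loops, R arithmetic)
# from the package internals they check.

# minimum image via round(), valid for any displacement
oracle_mimg <- function(d, L) d - L * round(d / L)

# Gay-Berne pair energy by direct matrix-formula evaluation
oracle_pair_energy <- function(c1, c2, L, eps0 = 0.5, mu = 1, nu = 1) {
  u1 <- c(cos(c1$phi), sin(c1$phi))
  u2 <- c(cos(c2$phi), sin(c2$phi))
  l1 <- sqrt(2) * c1$a; d1 <- sqrt(2) * c1$b
  l2 <- sqrt(2) * c2$a; d2 <- sqrt(2) * c2$b
  g1 <- (l1^2 - d1^2) * tcrossprod(u1) + d1^2 * diag(2)
  g2 <- (l2^2 - d2^2) * tcrossprod(u2) + d2^2 * diag(2)
  r12 <- oracle_mimg(c(c1$x - c2$x, c1$y - c2$y), L)
  rn <- sqrt(sum(r12^2))
  if (rn < 1e-6) { r12 <- c(1e-6, 0); rn <- 1e-6 }
  rhat <- r12 / rn
  sigma <- 1 / sqrt(drop(t(rhat) %*% solve(g1 + g2) %*% rhat))
  sigma0 <- sqrt(2 * c1$b^2 + 2 * c2$b^2)
  chi2 <- ((l1^2 - d1^2) * (l2^2 - d2^2)) /
    ((l1^2 + d1^2) * (l2^2 + d2^2))
  ea <- 1 / sqrt(1 - chi2 * sum(u1 * u2)^2)
  eb <- (sigma0 / sigma)^2
  eps <- eps0 * ea^nu * eb^mu
  r <- max((rn - sigma + sigma0) / sigma0, 1e-3)
  4 * eps * (r^-12 - r^-6)
}

# isotropic 12-6 closed form for two identical discs of radius b
oracle_lj_circular <- function(dist, b, eps0 = 0.5) {
  sigma <- 2 * b
  r <- max(dist / sigma, 1e-3) # sigma == sigma0, so r = |r12|/sigma0
  4 * eps0 * (r^-12 - r^-6)
}

# brute-force elliptical-cutoff neighbor lists
oracle_neighbors <- function(cells, L, rc_maj, rc_min) {
  n <- nrow(cells)
  lapply(seq_len(n), function(i) {
    u <- c(cos(cells$phi[i]), sin(cells$phi[i]))
    keep <- integer(0)
    for (j in seq_len(n)) {
      if (j == i) next
      d <- oracle_mimg(c(cells$x[j] - cells$x[i],
                         cells$y[j] - cells$y[i]), L)
      along <- sum(d * u)
      across <- d[2] * u[1] - d[1] * u[2]
      if ((along / rc_maj)^2 + (across / rc_min)^2 <= 1)
        keep <- c(keep, j)
    }
    keep
  })
}

# brute-force feeler-point overlap fraction
oracle_ridge_overlap <- function(cell, pattern, n_rings = 3, n_points = 64) {
  scales <- rev(seq_len(n_rings)) / n_rings
  tt <- 2 * pi * (seq_len(n_points) - 1) / n_points
  n_on <- 0
  for (s in scales) {
    ex <- s * cell$a * cos(tt)
    ey <- s * cell$b * sin(tt)
    px <- cell$x + ex * cos(cell$phi) - ey * sin(cell$phi)
    py <- cell$y + ex * sin(cell$phi) + ey * cos(cell$phi)
    d <- sqrt(oracle_mimg(px - pattern$center[1], pattern$L)^2 +
              oracle_mimg(py - pattern$center[2], pattern$L)^2)
    k <- round(d / pattern$spacing)
    on <- k >= 1 & k <= pattern$n_rings &
      abs(d - k * pattern$spacing) <= pattern$width / 2
    n_on <- n_on + sum(on)
  }
  n_on / (n_rings * n_points)
}

# Boltzmann marginal CDF of the semi-major axis for a single isolated cell
# (geometric + core energies only), by 2D quadrature on an (a, b) grid
oracle_boltzmann_a_cdf <- function(params, a_grid = seq(25, 65, by = 0.05),
                                   b_grid = seq(4, 25, by = 0.05)) {
  en <- outer(a_grid, b_grid, function(a, b) {
    dA <- (pi * a * b - params$A_pref) / params$A_pref
    dR <- (a / b - params$AR_pref) / params$AR_pref
    params$k_A * (dA^2 - dA^3 / 3 + 4 * dA^4) +
      params$k_AR * (dR^2 - dR^3 / 3 + 4 * dR^4) +
      params$k_core * (1 / a^4 + 1 / b^4)
  })
  w <- exp(-en / params$T)
  w[outer(a_grid, b_grid, function(a, b) a < b)] <- 0
  marg <- rowSums(w)
  cdf <- cumsum(marg) / sum(marg)
  list(a = a_grid, cdf = cdf,
       fun = stats::approxfun(a_grid, cdf, yleft = 0, yright = 1))
}

# deterministic pseudo-random cell tables for fixtures
random_cells <- function(n, L, seed, a_range = c(15, 45), ar_max = 4) {
  set.seed(seed)
  a <- runif(n, a_range[1], a_range[2])
  b <- a / runif(n, 1, ar_max)
  make_cells(x = runif(n, 0, L), y = runif(n, 0, L), a = a, b = b,
             phi = runif(n, 0, 2 * pi),
             px = runif(n, -1, 1), py = runif(n, -1, 1))
}
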