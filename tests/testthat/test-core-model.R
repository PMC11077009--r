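test_that("monolayer initialization builds tanh cells on a packed lattice", {
  p <- model_params(N = 1L, R0 = 8, grid = c(32L, 32L, 24L),
                    n_sim = 0L, n_relax = 0L, seed = 5L)
  st <- init_monolayer(p)
  # smoothed indicator: phi^2 volume close to the target before relaxation
  expect_lt(abs(sum(st$phi^2) - p$V0) / p$V0, 0.10)
  expect_true(all(st$phi >= 0 & st$phi <= 1))
  expect_true(all(st$theta >= -pi & st$theta <= pi))

  # bitwise determinism from the seed
  st2 <- init_monolayer(p)
  expect_identical(st, st2)

  # 16 distinct, well-separated centres
  p16 <- model_params(N = 16L, R0 = 8, grid = c(128L, 128L, 24L), seed = 2L)
  st16 <- init_monolayer(p16)
  cen <- stresschains:::centroid_cpp(st16$phi, p16$grid)$centroid
  expect_equal(nrow(unique(round(cen, 3))), 16L)
  dx <- stresschains:::min_image(outer(cen[, 1], cen[, 1], "-"), 128)
  dy <- stresschains:::min_image(outer(cen[, 2], cen[, 2], "-"), 128)
  d <- sqrt(dx^2 + dy^2)
  expect_gt(min(d[upper.tri(d)]), 8 / 2)

  # sizing error names the minimal box
  expect_error(init_monolayer(model_params(N = 64L, R0 = 8,
                                           grid = c(32L, 32L, 24L))),
               "too small")
})

test_that("bulk energy density is the symmetric double well", {
  expect_equal(bulk_energy_density(0), 0)
  expect_equal(bulk_energy_density(1), 0)
  expect_equal(bulk_energy_density(0.5), 0.25)
  x <- seq(0, 1, by = 0.05)
  expect_equal(bulk_energy_density(x), bulk_energy_density(1 - x))
})

test_that("free energy reduces to the volume term for empty fields and drops disjoint cross-terms", {
  p <- tiny_params(N = 2L)
  st <- init_monolayer(p)
  st$phi[] <- 0
  st$wall[] <- 0
  expect_equal(free_energy(st, p), p$N * p$mu, tolerance = 1e-12)

  # disjoint supports: kappa_cc and omega_cc cross-terms vanish exactly
  p2 <- tiny_params(N = 2L, grid = c(48L, 24L, 18L))
  st2 <- init_monolayer(p2)
  coords <- stresschains:::grid_coords(p2$grid)
  s1 <- stresschains:::tanh_sphere(coords, c(10, 12, 8), 5, p2$lam, p2$grid)
  s2 <- stresschains:::tanh_sphere(coords, c(34, 12, 8), 5, p2$lam, p2$grid)
  s1[s1 < 1e-3] <- 0
  s2[s2 < 1e-3] <- 0
  st2$phi[, 1] <- s1
  st2$phi[, 2] <- s2
  terms <- free_energy(st2, p2, by_term = TRUE)
  expect_equal(unname(terms["rep_cc"]), 0)
  expect_equal(unname(terms["adh_cc"]), 0)
})

test_that("discrete interface energy matches the analytic kink line tension", {
  # kink-antikink profile along x; analytic energy per unit cross-section
  # for phi = (1 + tanh(2x/lam))/2 is c_bulk * (lam/6 + 2*lam/3) per kink
  lam <- 4
  p <- model_params(N = 1L, R0 = 8, grid = c(96L, 6L, 6L), lam = lam,
                    omega_cw = 0, kappa_cw = 0, n_sim = 0L)
  x <- stresschains:::grid_coords(p$grid)[, 1]
  kink <- function(u) 0.5 * (1 + tanh(2 * u / lam))
  st <- structure(list(phi = matrix(kink(x - 24) * kink(72 - x), ncol = 1),
                       theta = 0, wall = numeric(length(x)),
                       grid = p$grid, time = 0L),
                  class = "monolayer_state")
  terms <- free_energy(st, p, by_term = TRUE)
  got <- unname(terms["bulk"] + terms["gradient"])
  expected <- 2 * p$c_bulk * (lam / 6 + 2 * lam / 3) * 6 * 6
  expect_lt(abs(got - expected) / expected, 0.02)
})

test_that("functional derivative matches finite differences of the free energy", {
  set.seed(42)
  p <- model_params(N = 2L, R0 = 6, grid = c(20L, 20L, 18L), z_wall = 3,
                    n_sim = 0L, n_relax = 0L, seed = 9L)
  st <- pair_state(p, sep = 8)
  # central differences of the total energy (magnitude ~2e3) resolve the
  # derivative cleanly at interface/body nodes; eps balances truncation
  # against cancellation in the energy sum
  eps <- 1e-3
  for (cell in 1:2) {
    df <- functional_derivative(st, p, cell)
    body <- which(st$phi[, cell] > 0.05 & st$phi[, cell] < 0.95)
    nodes <- sample(body, 20)
    for (k in nodes) {
      stp <- st; stm <- st
      stp$phi[k, cell] <- st$phi[k, cell] + eps
      stm$phi[k, cell] <- st$phi[k, cell] - eps
      fd <- (free_energy(stp, p) - free_energy(stm, p)) / (2 * eps)
      expect_lt(abs(fd - df[k]) / max(abs(df[k]), 1e-3 * max(abs(df))), 1e-4)
    }
  }
  # all-zero field with decoupled substrate: derivative vanishes identically
  p0 <- model_params(N = 1L, grid = c(16L, 16L, 16L), R0 = 5, z_wall = 2,
                     omega_cw = 0, kappa_cw = 0)
  st0 <- init_monolayer(p0)
  st0$phi[] <- 0
  expect_equal(max(abs(functional_derivative(st0, p0, 1))), 0)
  expect_error(functional_derivative(st0, p0, 3), "out of range")
})

test_that("cell traction matches a dense R oracle and symmetry expectations", {
  p <- model_params(N = 2L, R0 = 6, grid = c(24L, 24L, 18L), z_wall = 3,
                    n_sim = 0L, n_relax = 0L, seed = 4L)
  st <- pair_state(p, sep = 9)

  # dense oracle: central-difference gradient assembled in R
  grad_r <- function(a, grid) {
    arr <- array(a, dim = grid)
    shift <- function(A, d, ax) {
      idx <- lapply(dim(A), seq_len)
      n <- dim(A)[ax]
      idx[[ax]] <- ((idx[[ax]] - 1 + d) %% n) + 1
      do.call(`[`, c(list(A), idx))
    }
    gx <- (shift(arr, 1, 1) - shift(arr, -1, 1)) / 2
    gy <- (shift(arr, 1, 2) - shift(arr, -1, 2)) / 2
    gz <- (shift(arr, 1, 3) - shift(arr, -1, 3)) / 2
    gz[, , 1] <- arr[, , 2] - arr[, , 1]
    nz <- grid[3]
    gz[, , nz] <- arr[, , nz] - arr[, , nz - 1]
    list(gx = as.numeric(gx), gy = as.numeric(gy), gz = as.numeric(gz))
  }
  for (cell in 1:2) {
    df <- as.numeric(functional_derivative(st, p, cell))
    g <- grad_r(st$phi[, cell], p$grid)
    oracle <- -c(sum(df * g$gx), sum(df * g$gy), sum(df * g$gz))
    expect_equal(cell_traction(st, p, cell), oracle, tolerance = 1e-10)
  }

  # symmetric isolated cell, substrate decoupled: traction vanishes
  ps <- model_params(N = 1L, R0 = 6, grid = c(32L, 32L, 24L),
                     omega_cw = 0, kappa_cw = 0, n_sim = 0L)
  sts <- init_monolayer(ps)
  coords <- stresschains:::grid_coords(ps$grid)
  sts$phi[, 1] <- stresschains:::tanh_sphere(coords, c(16, 16, 11.5), 6,
                                             ps$lam, ps$grid)
  expect_lt(sqrt(sum(cell_traction(sts, ps, 1)^2)), 1e-8 * ps$E * ps$R0^2)

  # interaction tractions of a pair are equal and opposite; the pair sits
  # mid-height in a tall box with the substrate decoupled so the periodic
  # summation-by-parts identity behind the antisymmetry is exact
  pp <- model_params(N = 2L, R0 = 6, grid = c(24L, 24L, 32L), z_wall = 10,
                     omega_cc = 0, kappa_cc = 1, omega_cw = 0, kappa_cw = 0,
                     n_sim = 0L, seed = 4L)
  stp <- pair_state(pp, sep = 9)
  inter <- function(i) {
    solo <- stp
    solo$phi[, setdiff(1:2, i)] <- 0
    cell_traction(stp, pp, i) - cell_traction(solo, pp, i)
  }
  t1 <- inter(1); t2 <- inter(2)
  expect_lt(sqrt(sum((t1 + t2)^2)) / sqrt(sum(t1^2)), 1e-6)
})

test_that("polarity dynamics align toward the traction and inject the configured noise", {
  p <- tiny_params()
  # fixed point: aligned polarity, no noise
  expect_equal(update_polarity(0, c(5, 0, 0), p, noise = 0), 0)
  # drift sign: traction along +x rotates theta = pi/2 toward 0
  th <- update_polarity(pi / 2, c(5, 0, 0), p, noise = 0)
  expect_lt(th, pi / 2)
  expect_gt(th, 0)
  # antisymmetric case
  th2 <- update_polarity(-pi / 2, c(5, 0, 0), p, noise = 0)
  expect_equal(th2, -th)
  # zero traction: drift undefined -> zero, noise still applied
  expect_equal(update_polarity(1.2, c(0, 0, 0), p, noise = 2),
               1.2 + p$Dr * sqrt(p$dt) * 2)
  # Monte-Carlo check of the noise discretization
  set.seed(99)
  inc <- replicate(1e4, update_polarity(0, c(0, 0, 0), p)) - 0
  expect_lt(abs(var(inc) / (p$Dr^2 * p$dt) - 1), 0.05)
})

test_that("passive dynamics are energy-descending and conserve cell volume", {
  p <- model_params(N = 2L, R0 = 6, grid = c(24L, 24L, 18L), z_wall = 3,
                    alpha = 0, Dr = 0, n_sim = 0L, seed = 8L)
  st <- pair_state(p, sep = 10)
  e <- free_energy(st, p)
  for (i in 1:100) {
    st <- advance(st, p)
    e2 <- free_energy(st, p)
    expect_lt(e2 - e, 1e-6 * abs(e))
    e <- e2
  }
  vols <- stresschains:::centroid_cpp(st$phi, st$grid)$volume
  expect_true(all(abs(vols - p$V0) / p$V0 < 0.06))

  # equilibrium: a relaxed symmetric passive cell barely moves per step
  # (substrate decoupled so the symmetric profile is a fixed point)
  p1 <- model_params(N = 1L, R0 = 6, grid = c(24L, 24L, 18L), z_wall = 3,
                     omega_cw = 0, kappa_cw = 0, alpha = 0, Dr = 0,
                     n_sim = 0L)
  s1 <- init_monolayer(p1)
  coords <- stresschains:::grid_coords(p1$grid)
  s1$phi[, 1] <- stresschains:::tanh_sphere(coords, c(12, 12, 8.5),
                                            p1$R0, p1$lam, p1$grid)
  for (i in 1:300) s1 <- advance(s1, p1)
  c0 <- stresschains:::centroid_cpp(s1$phi, s1$grid)$centroid
  s1 <- advance(s1, p1)
  c1 <- stresschains:::centroid_cpp(s1$phi, s1$grid)$centroid
  expect_lt(max(abs(c1 - c0)), 1e-6 * p1$a0)
  expect_lt(abs(sum(s1$phi^2) - p1$V0) / p1$V0, 0.05)
})

test_that("an isolated active cell reaches the overdamped steady speed alpha/xi", {
  # fixed polarity: enormous tau_pol freezes the CIL drift, Dr = 0
  p <- model_params(N = 1L, R0 = 6, grid = c(32L, 32L, 20L), z_wall = 3,
                    alpha = 48, tau_pol = 1e6, Dr = 0, n_sim = 0L, seed = 3L)
  st <- init_monolayer(p)
  for (i in 1:150) st <- advance(st, p)
  cen <- function(s) stresschains:::centroid_cpp(s$phi, s$grid)$centroid[1, ]
  c0 <- cen(st)
  nstep <- 200
  pos <- c0
  prev <- c0
  for (i in seq_len(nstep)) {
    st <- advance(st, p)
    cc <- cen(st)
    d <- cc - prev
    d[1] <- stresschains:::min_image(d[1], p$grid[1])
    d[2] <- stresschains:::min_image(d[2], p$grid[2])
    pos <- pos + d
    prev <- cc
  }
  speed <- sqrt(sum((pos[1:2] - c0[1:2])^2)) / (nstep * p$dt)
  expect_lt(abs(speed - p$alpha / p$xi_fric) / (p$alpha / p$xi_fric), 0.05)
})

test_that("free energy is invariant under relabeling and lattice translation", {
  p <- model_params(N = 2L, R0 = 6, grid = c(24L, 24L, 18L), z_wall = 3,
                    n_sim = 0L, seed = 12L)
  st <- pair_state(p, sep = 9)
  f0 <- free_energy(st, p)

  sw <- st
  sw$phi <- sw$phi[, 2:1]
  sw$theta <- sw$theta[2:1]
  expect_identical(free_energy(sw, p), f0)

  # shift all fields (and the wall) by 5 sites along periodic x
  arr_shift <- function(v, grid, d) {
    a <- array(v, dim = grid)
    idx <- ((seq_len(grid[1]) - 1 - d) %% grid[1]) + 1
    as.numeric(a[idx, , ])
  }
  tr <- st
  tr$phi <- apply(st$phi, 2, arr_shift, grid = p$grid, d = 5L)
  tr$wall <- arr_shift(st$wall, p$grid, 5L)
  expect_lt(abs(free_energy(tr, p) - f0) / abs(f0), 1e-10)
})

test_that("simulation runs are reproducible and guard the CFL bound", {
  p <- model_params(N = 2L, R0 = 6, grid = c(24L, 24L, 18L), z_wall = 3,
                    n_sim = 25L, n_relax = 20L, seed = 21L)
  p <- params_from_drives(0.2, 0.3, base = p)
  t1 <- run_simulation(p)
  t2 <- run_simulation(p)
  expect_identical(t1$centroid, t2$centroid)
  expect_identical(t1$theta, t2$theta)
  expect_identical(t1$state$phi, t2$state$phi)
  # empty run: initial state only
  p0 <- params_from_drives(0.2, 0.3,
                           base = model_params(N = 2L, R0 = 6,
                                               grid = c(24L, 24L, 18L),
                                               z_wall = 3, n_sim = 0L,
                                               n_relax = 0L, seed = 21L))
  t0 <- run_simulation(p0)
  expect_equal(nrow(t0$theta), 0L)
  expect_equal(t0$state$time, 0L)
  # a huge self-propulsion violates the advection CFL bound with a diagnostic
  pb <- model_params(N = 1L, R0 = 6, grid = c(24L, 24L, 18L), z_wall = 3,
                     alpha = 1e5, n_sim = 5L, n_relax = 0L, seed = 1L)
  expect_error(run_simulation(pb), "CFL")
})
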