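# random symmetric tensor field fixture
rand_tensor <- function(ext = c(9L, 7L), seed = 1) {
  set.seed(seed)
  tensor_field2d(matrix(rnorm(prod(ext) * 6), prod(ext), 6), extent = ext)
}

test_that("nodal traction density integrates back to the per-cell totals", {
  p <- model_params(N = 2L, R0 = 6, grid = c(24L, 24L, 18L), z_wall = 3,
                    alpha = 30, n_sim = 0L, seed = 6L)
  st <- pair_state(p, sep = 9)
  td <- nodal_traction_field(st, p)
  total <- colSums(td)
  expected <- cell_traction(st, p, 1) + cell_traction(st, p, 2) +
    p$alpha * (c(cos(st$theta[1]), sin(st$theta[1]), 0) +
                 c(cos(st$theta[2]), sin(st$theta[2]), 0))
  expect_lt(sqrt(sum((total - expected)^2)) / sqrt(sum(expected^2)), 1e-6)

  # empty monolayer: zero field
  st0 <- st
  st0$phi[] <- 0
  expect_equal(max(abs(nodal_traction_field(st0, p))), 0)
})

test_that("coarse-grained stress is linear, annihilates uniform tractions and matches a loop oracle", {
  grid <- c(8L, 6L, 5L)
  n <- prod(grid)
  set.seed(3)
  t1 <- matrix(rnorm(3 * n), n, 3)
  t2 <- matrix(rnorm(3 * n), n, 3)

  s0 <- coarse_grained_stress(matrix(0, n, 3), grid = grid)
  expect_equal(max(abs(s0$values)), 0)

  su <- coarse_grained_stress(matrix(rep(c(1, -2, 3), each = n), n, 3),
                              grid = grid)
  expect_lt(max(abs(su$values)), 1e-12)

  sa <- coarse_grained_stress(t1, grid = grid)
  sb <- coarse_grained_stress(t2, grid = grid)
  sab <- coarse_grained_stress(t1 + t2, grid = grid)
  expect_equal(sab$values, sa$values + sb$values, tolerance = 1e-12)

  # independent dense-loop oracle of the dual-lattice moment formula
  oracle <- function(td, grid) {
    nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
    zmid <- (nz - 1) / 2
    out <- array(0, c(nx + 1, ny + 1, 6))
    for (ix in 0:nx) for (iy in 0:ny) {
      acc <- matrix(0, 3, 3)
      for (cx in 0:1) for (cy in 0:1) for (oz in 0:(nz - 1)) {
        ox <- (ix - 1 + cx) %% nx
        oy <- (iy - 1 + cy) %% ny
        r <- c(ifelse(cx == 0, 0.5, -0.5), ifelse(cy == 0, 0.5, -0.5),
               zmid - oz)
        Tj <- td[1 + ox + nx * (oy + ny * oz), ]
        acc <- acc + (outer(r, Tj) + outer(Tj, r)) / 2
      }
      out[ix + 1, iy + 1, ] <- c(acc[1, 1], acc[2, 2], acc[3, 3],
                                 acc[1, 2], acc[1, 3], acc[2, 3])
    }
    matrix(out, (nx + 1) * (ny + 1), 6)
  }
  expect_equal(sa$values, oracle(t1, grid), tolerance = 1e-12,
               ignore_attr = TRUE)

  # outward-pushing force dipole -> compressive (negative) sigma_xx between
  td <- matrix(0, n, 3)
  at <- function(x, y, z) 1 + x + grid[1] * (y + grid[2] * z)
  td[at(2, 3, 2), 1] <- -1   # pushes left
  td[at(5, 3, 2), 1] <- +1   # pushes right
  sd <- coarse_grained_stress(td, grid = grid)
  sxx <- matrix(sd$values[, "xx"], grid[1] + 1, grid[2] + 1)
  expect_lt(sxx[4, 4], 0)    # dual column between the two forces
})

test_that("time averaging is an exact arithmetic mean with frame bookkeeping", {
  f1 <- rand_tensor(seed = 1)
  expect_equal(time_average(list(f1))$values, f1$values)

  neg <- tensor_field2d(-f1$values, extent = f1$extent)
  expect_equal(max(abs(time_average(list(f1, neg))$values)), 0)

  frames <- lapply(1:50, function(i) rand_tensor(seed = i))
  avg <- time_average(frames)
  acc <- 0
  for (f in frames) acc <- acc + f$values
  expect_equal(avg$values, acc / 50, tolerance = 1e-14)
  expect_equal(avg$n_frames_averaged, 50L)

  # idempotent on a constant sequence
  expect_equal(time_average(list(f1, f1, f1))$values, f1$values)

  expect_error(time_average(list()), "at least one")
  small <- rand_tensor(ext = c(4L, 4L))
  expect_error(time_average(list(f1, small)), "mismatch")
})

test_that("isotropic stress is the trace third with the compression normalization", {
  ext <- c(6L, 5L)
  idt <- tensor_field2d(matrix(rep(c(1, 1, 1, 0, 0, 0), each = prod(ext)),
                               prod(ext), 6), extent = ext)
  expect_equal(unique(as.numeric(isotropic_stress(idt)$values)), 1)

  dev <- tensor_field2d(matrix(rep(c(2, -1, -1, 5, 3, 2), each = prod(ext)),
                               prod(ext), 6), extent = ext)
  expect_equal(max(abs(isotropic_stress(dev)$values)), 0)

  f <- rand_tensor(seed = 11)
  iso <- isotropic_stress(f)
  oracle <- (f$values[, 1] + f$values[, 2] + f$values[, 3]) / 3
  expect_equal(as.numeric(iso$values), oracle, tolerance = 1e-14)

  # normalization by maximum compression preserves sign and scales to |1|
  ison <- isotropic_stress(f, normalize = TRUE)
  comp <- oracle[oracle < 0]
  expect_equal(ison$normalization, max(abs(comp)))
  expect_equal(as.numeric(ison$values), oracle / max(abs(comp)))

  zero <- tensor_field2d(matrix(0, prod(ext), 6), extent = ext)
  expect_error(isotropic_stress(zero, normalize = TRUE), "zero")
})

test_that("out-of-plane stress extracts the zz component", {
  ext <- c(5L, 4L)
  d <- tensor_field2d(matrix(rep(c(1, 2, 5, 0, 0, 0), each = prod(ext)),
                             prod(ext), 6), extent = ext)
  expect_equal(unique(as.numeric(out_of_plane_stress(d)$values)), 5)
  ip <- tensor_field2d(matrix(rep(c(3, -2, 0, 1, 0, 0), each = prod(ext)),
                              prod(ext), 6), extent = ext)
  expect_equal(max(abs(out_of_plane_stress(ip)$values)), 0)
  f <- rand_tensor(seed = 12)
  expect_equal(as.numeric(out_of_plane_stress(f)$values), f$values[, 3])
})

test_that("maximum in-plane shear matches the principal-stress formula and is rotation invariant", {
  ext <- c(4L, 4L)
  mk <- function(xx, yy, xy) {
    tensor_field2d(matrix(rep(c(xx, yy, 0, xy, 0, 0), each = prod(ext)),
                          prod(ext), 6), extent = ext)
  }
  expect_equal(unique(as.numeric(max_inplane_shear(mk(3, -1, 0))$values)), 2)
  expect_equal(unique(as.numeric(max_inplane_shear(mk(0, 0, 1.5))$values)), 1.5)

  f <- rand_tensor(seed = 13)
  tau <- max_inplane_shear(f)
  phi <- 0.7
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  rot <- f
  for (i in seq_len(nrow(f$values))) {
    m <- matrix(c(f$values[i, 1], f$values[i, 4],
                  f$values[i, 4], f$values[i, 2]), 2, 2)
    m2 <- R %*% m %*% t(R)
    rot$values[i, 1] <- m2[1, 1]
    rot$values[i, 2] <- m2[2, 2]
    rot$values[i, 4] <- m2[1, 2]
  }
  expect_equal(max_inplane_shear(rot)$values, tau$values, tolerance = 1e-10)
})

test_that("susceptibility is the extensive population variance", {
  expect_equal(susceptibility(matrix(3, 5, 5)), 0)
  expect_equal(susceptibility(matrix(c(1, 1, -1, -1), 2, 2)), 4)
  set.seed(7)
  v <- matrix(rnorm(200), 10, 20)
  two_pass <- length(v) * mean((v - mean(v))^2)
  expect_equal(susceptibility(v), two_pass, tolerance = 1e-10)
  expect_equal(susceptibility(scalar_field2d(v)), two_pass, tolerance = 1e-10)
})

test_that("field statistics sweeps normalize to the reference control value", {
  f <- scalar_field2d(matrix(rnorm(100, mean = 2), 10, 10))
  sw <- field_statistics_sweep(list(`0.2` = f, `0.4` = f, `0.3` = f))
  expect_equal(sw$control, c(0.2, 0.3, 0.4))       # sorted controls
  expect_equal(sw$mean_rel, rep(1, 3))
  expect_equal(sw$chi_rel, rep(1, 3))
  expect_error(field_statistics_sweep(list(`0.3` = f, `0.4` = f),
                                      reference = 0.2), "reference")
})
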