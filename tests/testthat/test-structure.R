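test_that("pair correlation is ideal-gas-normalized and resolves discrete configurations", {
  # Poisson reference: g ~ 1 away from contact
  set.seed(31)
  box <- c(400, 400)
  pos <- cbind(runif(2000, 0, box[1]), runif(2000, 0, box[2]))
  gr <- pair_correlation(pos, box, R0 = 8)
  sel <- gr$r_centers >= 3 & gr$r_centers <= 5
  expect_lt(abs(mean(gr$g[sel]) - 1), 0.05)

  # two points: a single occupied bin at their separation
  g2 <- pair_correlation(rbind(c(10, 10), c(18, 10)), c(40, 40), R0 = 8)
  expect_equal(sum(g2$n_pairs > 0), 1L)
  expect_equal(g2$r_centers[g2$n_pairs > 0], 1, tolerance = 0.05)
  expect_equal(sum(g2$n_pairs), 2)  # ordered pairs

  # triangular lattice of spacing 2*R0: first peak bin at r/R0 = 2
  R0 <- 8; a <- 2 * R0
  rows <- 8; cols <- 8
  xy <- do.call(rbind, lapply(0:(rows - 1), function(r) {
    cbind((0:(cols - 1)) * a + (r %% 2) * a / 2, r * a * sqrt(3) / 2)
  }))
  boxt <- c(cols * a, rows * a * sqrt(3) / 2)
  gt <- pair_correlation(xy, boxt, R0 = R0)
  first <- which(gt$n_pairs > 0)[1]
  expect_equal(gt$r_centers[first], 2, tolerance = 0.05)

  # pair-count bookkeeping against a direct distance count
  set.seed(5)
  ps <- cbind(runif(40, 0, 30), runif(40, 0, 30))
  gs <- pair_correlation(ps, c(30, 30), R0 = 4)
  dx <- stresschains:::min_image(outer(ps[, 1], ps[, 1], "-"), 30)
  dy <- stresschains:::min_image(outer(ps[, 2], ps[, 2], "-"), 30)
  d <- sqrt(dx^2 + dy^2)[upper.tri(dx)]
  expect_equal(sum(gs$n_pairs), 2 * sum(d < 15 + 0.2))

  # invariance under global translation (periodic wrap) and relabeling
  ps2 <- (ps + 7.3) %% 30
  gs2 <- pair_correlation(ps2, c(30, 30), R0 = 4)
  expect_equal(gs2$g, gs$g, tolerance = 1e-12)
  gs3 <- pair_correlation(ps[sample(40), ], c(30, 30), R0 = 4)
  expect_equal(gs3$g, gs$g, tolerance = 1e-12)

  expect_error(pair_correlation(ps, c(30, 30), R0 = 4, bin_width = 0),
               "bin width")
  expect_error(pair_correlation(ps[1, , drop = FALSE], c(30, 30), R0 = 4),
               "at least 2")
})

test_that("the static structure factor shows the expected limits", {
  # single particle: S = 1 everywhere
  s1 <- structure_factor_2d(matrix(c(3, 4), 1, 2), c(20, 20), n_modes = 4)
  expect_true(all(abs(s1$S - 1) < 1e-12))

  # perfect square lattice: Bragg peaks S = N at reciprocal lattice vectors
  a <- 5; n <- 6
  xy <- as.matrix(expand.grid(x = (0:(n - 1)) * a, y = (0:(n - 1)) * a))
  sf <- structure_factor_2d(xy, c(n * a, n * a), n_modes = n)
  # q = (2*pi/a, 0) is mode index n along x
  izero <- n + 1  # index of q = 0
  expect_equal(sf$S[izero + n, izero], n^2, tolerance = 1e-8)
  expect_equal(sf$S[izero, izero + n], n^2, tolerance = 1e-8)
  expect_equal(sf$S[izero, izero], n^2, tolerance = 1e-8)  # S(0) = N
  # non-Bragg mode is destructive
  expect_lt(sf$S[izero + 1, izero], 1e-8)

  # Poisson configuration: angular average ~ 1 at large |q|
  set.seed(8)
  pr <- cbind(runif(400, 0, 100), runif(400, 0, 100))
  sr <- structure_factor_2d(pr, c(100, 100), n_modes = 16)
  qq <- sqrt(outer(sr$qx^2, sr$qy^2, "+"))
  big <- qq > 0.5 * max(qq)
  expect_lt(abs(mean(sr$S[big]) - 1), 0.10)
})

test_that("the g(r) classifier separates solid and liquid signatures", {
  r <- seq(0.05, 4, by = 0.05)
  mk <- function(peak_at, height) {
    g <- 1 + (height - 1) * exp(-(r - peak_at)^2 / (2 * 0.15^2))
    structure(list(r_centers = r, g = g, n_pairs = rep(1, length(r)),
                   rho = 0.01, N = 16, R0 = 8),
              class = "pair_correlation")
  }
  expect_equal(classify_state(mk(2.0, 2.5))$label, "solid")
  expect_equal(classify_state(mk(0.6, 2.5))$label, "liquid")
  flat <- mk(2.0, 1.0)
  flat$g[] <- 1
  expect_equal(classify_state(flat)$label, "indeterminate")
  # peak positions are reported
  rep1 <- classify_state(mk(2.0, 2.5))
  expect_equal(rep1$dominant$r_over_R0, 2, tolerance = 0.05)
})
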