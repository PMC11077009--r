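test_that("percentile thresholding follows the strict '>' rank rule", {
  f <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(sum(threshold_field(f, 1)$occupied), 4L)
  expect_equal(sum(threshold_field(f, 0)$occupied), 0L)
  occ <- threshold_field(f, 0.5)$occupied
  expect_identical(as.logical(f > 2.5), as.logical(occ))
  expect_error(threshold_field(matrix(1, 3, 3), 0.4), "ties")
  expect_error(threshold_field(f, 1.2), "\\[0, 1\\]")

  # occupied fraction tracks p up to rank rounding on a continuous field
  v <- iid_uniform_field(c(64L, 64L), seed = 17)
  for (p in c(0.2, 0.5927, 0.8)) {
    frac <- mean(threshold_field(v, p)$occupied)
    expect_lt(abs(frac - p), 2 / 64)
  }
})

test_that("cluster labelling handles the degenerate grids exactly", {
  full <- matrix(TRUE, 8, 8)
  lf <- label_clusters(full, "face4")
  expect_equal(length(lf$sizes), 1L)
  expect_equal(lf$sizes, 64L)
  expect_true(lf$spanning)

  checker <- outer(1:8, 1:8, function(i, j) (i + j) %% 2 == 0)
  l4 <- label_clusters(checker, "face4")
  expect_equal(length(l4$sizes), sum(checker))
  expect_true(all(l4$sizes == 1L))
  l8 <- label_clusters(checker, "moore8")
  expect_equal(length(l8$sizes), 1L)

  empty <- label_clusters(matrix(FALSE, 4, 4), "face4")
  expect_equal(length(empty$sizes), 0L)
  expect_equal(spanning_density(empty), 0)
})

test_that("cluster observables agree with dense brute-force oracles on random grids", {
  set.seed(123)
  for (conn in c("face4", "moore8")) {
    for (rep in 1:40) {
      occ <- matrix(runif(144) < runif(1, 0.3, 0.7), 12, 12)
      lab <- label_clusters(occ, conn)
      olab <- oracle_label(occ, conn)
      expect_identical(canonical_labels(lab$labels), canonical_labels(olab))
      ost <- oracle_stats(olab)
      expect_equal(sort(lab$sizes), sort(ost$sizes))
      expect_equal(spanning_density(lab), ost$P)
      expect_equal(average_cluster_size(lab), ost$S)
      if (is.na(ost$xi)) {
        expect_true(is.na(correlation_length(lab)))
      } else {
        expect_equal(correlation_length(lab), ost$xi, tolerance = 1e-10)
      }
    }
  }
})

test_that("spanning density and cluster-size conventions match hand-computable cases", {
  # single full row of an l x l grid
  occ <- matrix(FALSE, 10, 10)
  occ[4, ] <- TRUE
  lab <- label_clusters(occ, "face4")
  expect_equal(spanning_density(lab), 1 / 10)

  # clusters of sizes {1, 3}: second moment (1+9)/(1+3), arithmetic 2
  occ2 <- matrix(FALSE, 8, 8)
  occ2[2, 2] <- TRUE
  occ2[5, 3:5] <- TRUE
  lab2 <- label_clusters(occ2, "face4")
  expect_equal(average_cluster_size(lab2), 2.5)
  expect_equal(average_cluster_size(lab2, method = "arithmetic"), 2)

  # only a spanning cluster: S = 0 by the exclusion convention
  occ3 <- matrix(FALSE, 6, 6)
  occ3[3, ] <- TRUE
  expect_equal(average_cluster_size(label_clusters(occ3, "face4")), 0)

  # two adjacent sites: xi = sqrt(2 * Rg^2) = sqrt(1/2)
  occ4 <- matrix(FALSE, 6, 6)
  occ4[2, 2:3] <- TRUE
  expect_equal(correlation_length(label_clusters(occ4, "face4")),
               sqrt(0.5), tolerance = 1e-12)
  # all singletons: xi = 0
  occ5 <- matrix(FALSE, 6, 6)
  occ5[cbind(c(1, 3, 5), c(1, 3, 5))] <- TRUE
  expect_equal(correlation_length(label_clusters(occ5, "face4")), 0)
})

test_that("percolation curves agree with the direct labelling route and honour the contracts", {
  f <- iid_uniform_field(c(48L, 48L), seed = 23)
  pg <- c(0.3, 0.5, 0.5927, 0.7, 1.0)
  cv <- percolation_curves(f, pg, 47L)$curves

  for (p in pg) {
    occ <- threshold_field(f, p)
    lab <- label_clusters(occ)
    row <- cv[abs(cv$p - p) < 1e-12, ]
    expect_equal(row$P, spanning_density(lab), tolerance = 1e-12)
    expect_equal(row$S, average_cluster_size(lab), tolerance = 1e-12)
    xi <- correlation_length(lab)
    if (!is.na(xi)) expect_equal(row$xi, xi, tolerance = 1e-10)
  }
  # p = 1: everything spans, the finite-cluster size is 0 by convention
  expect_equal(cv$P[cv$p == 1], 1)
  expect_equal(cv$S[cv$p == 1], 0)

  expect_error(percolation_curves(f, pg, 64L), "exceeds")
})

test_that("spanning probability sharpens with subsystem size on uncorrelated fields", {
  fields <- lapply(1:40, function(i) iid_uniform_field(c(96L, 96L), seed = 400 + i))
  pg <- seq(0.40, 0.80, by = 0.02)
  cur <- percolation_curves(fields, pg, c(23L, 47L, 95L))
  slopes <- vapply(cur$ells, function(l) {
    d <- cur$curves[cur$curves$ell == l, ]
    max(diff(d$Pi) / diff(d$p))
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
  # monotone occupation response: mean Pi non-decreasing within noise
  for (l in cur$ells) {
    d <- cur$curves[cur$curves$ell == l, ]
    expect_true(all(diff(d$Pi) > -2 * sqrt(0.25 / 40)))
  }
})

test_that("the crossing estimator pins the threshold of synthetic spanning curves", {
  sc <- scaling_curve_set(pc = 0.5, beta = 0.14, nu = 4 / 3, gamma = 2.4,
                          ells = c(24L, 48L, 96L),
                          p_grid = seq(0.3, 0.7, by = 0.005),
                          noise = 0, seed = 2, n_real = 2L)
  est <- spanning_probability_crossing(sc)
  expect_lt(abs(est$pc - 0.5), 0.01)

  # identical curves on a common grid for all sizes: crossing undefined
  pg <- seq(0.3, 0.7, by = 0.01)
  cvs <- do.call(rbind, lapply(c(16L, 32L, 64L), function(l) {
    data.frame(ell = l, p = pg, Pi = plogis((pg - 0.5) * 30),
               P = 0, S = 0, xi = 0, n_realizations = 2L)
  }))
  same <- structure(list(curves = cvs, ells = c(16L, 32L, 64L), p = pg,
                         n_realizations = 2L),
                    class = "percolation_curves")
  expect_error(spanning_probability_crossing(same), "cross")
})
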