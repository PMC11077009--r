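# Threshold percolation on 2D scalar fields: percentile occupation, cluster
# labelling, spanning-cluster observables and curve accumulation over
# subsystem sizes and realizations.

conn_code <- function(connectivity) {
  switch(match.arg(connectivity, c("face4", "moore8")),
         face4 = 4L, moore8 = 8L)
}

field_values <- function(field) {
  if (inherits(field, "scalar_field2d")) field$values
  else if (is.matrix(field)) field
  else stop("expected a scalar_field2d or a matrix")
}

#' Percentile-threshold occupation of a scalar field
#'
#' Occupies the sites whose value is strictly greater than the
#' `(1-p)*100`-th percentile of the field's own value distribution
#' (linear-interpolation percentile), so that the occupied fraction equals
#' `p` up to rank rounding; for an i.i.d. continuous field this is exactly
#' site percolation at occupation probability `p`.  `p = 1` occupies every
#' site and `p = 0` none.
#'
#' @param field a [scalar_field2d()] or numeric matrix.
#' @param p occupation probability in `[0, 1]`.
#' @param connectivity `"face4"` (nearest neighbours) or `"moore8"`
#'   (eight-point) — recorded on the grid for the labelling stage.
#' @return An `occupancy_grid`: list with `occupied` (logical matrix),
#'   `connectivity`, `extent` (characteristic length, nodes minus one).
#' @export
threshold_field <- function(field, p, connectivity = "face4") {
  v <- field_values(field)
  if (!is.finite(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  n <- length(v)
  occ <- if (p == 1) {
    matrix(TRUE, nrow(v), ncol(v))
  } else if (p == 0) {
    matrix(FALSE, nrow(v), ncol(v))
  } else {
    if (max(v) == min(v))
      stop(paste("degenerate ties: the field is constant, so the strict '>'",
                 "percentile rule cannot occupy a fraction p of sites"))
    q <- quantile(v, probs = 1 - p, names = FALSE)
    v > q
  }
  structure(list(occupied = occ,
                 connectivity = match.arg(connectivity, c("face4", "moore8")),
                 extent = min(dim(v)) - 1L),
            class = "occupancy_grid")
}

#' Label connected clusters of an occupancy grid
#'
#' Connected components under the grid's connectivity (open boundaries),
#' with per-cluster sizes, radii of gyration and spanning flags (a cluster
#' spans if it touches both the left and right edges, or both the top and
#' bottom edges).
#'
#' @param grid an [threshold_field()] `occupancy_grid`, or a logical matrix.
#' @param connectivity used when `grid` is a bare matrix.
#' @return A `cluster_labels` object: list with `labels` (integer matrix,
#'   0 = empty), `sizes`, `rg` (radius of gyration per cluster), `spanning`
#'   (logical per cluster), `dim`, `connectivity`.
#' @export
label_clusters <- function(grid, connectivity = "face4") {
  if (inherits(grid, "occupancy_grid")) {
    occ <- grid$occupied
    connectivity <- grid$connectivity
  } else {
    occ <- grid
    stopifnot(is.logical(occ), is.matrix(occ))
  }
  code <- conn_code(connectivity)
  lab <- label_clusters_cpp(occ, code)
  k <- attr(lab, "n_clusters")
  if (k == 0L) {
    return(structure(list(labels = lab, sizes = integer(0), rg = numeric(0),
                          spanning = logical(0), dim = dim(occ),
                          connectivity = connectivity),
                     class = "cluster_labels"))
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  row <- (idx - 1L) %% nrow(occ)
  col <- (idx - 1L) %/% nrow(occ)
  sizes <- tabulate(l, nbins = k)
  sx <- rowsum(as.numeric(row), l)[, 1]
  sy <- rowsum(as.numeric(col), l)[, 1]
  sx2 <- rowsum(as.numeric(row)^2, l)[, 1]
  sy2 <- rowsum(as.numeric(col)^2, l)[, 1]
  rg2 <- (sx2 + sy2) / sizes - (sx / sizes)^2 - (sy / sizes)^2
  rg2[rg2 < 0] <- 0
  minr <- tapply(row, l, min); maxr <- tapply(row, l, max)
  minc <- tapply(col, l, min); maxc <- tapply(col, l, max)
  spanning <- (minr == 0 & maxr == nrow(occ) - 1L) |
    (minc == 0 & maxc == ncol(occ) - 1L)
  structure(list(labels = lab, sizes = sizes, rg = sqrt(rg2),
                 spanning = as.logical(spanning), dim = dim(occ),
                 connectivity = connectivity),
            class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat(sprintf("cluster_labels: %d clusters on %d x %d (%s), %d spanning\n",
              length(x$sizes), x$dim[1], x$dim[2], x$connectivity,
              sum(x$spanning)))
  invisible(x)
}

#' Spanning-cluster density P
#'
#' The probability that a site belongs to a spanning cluster: total sites in
#' spanning clusters divided by all lattice sites; 0 when nothing spans.
#'
#' @param labels a [label_clusters()] result.
#' @return Scalar in `[0, 1]`.
#' @export
spanning_density <- function(labels) {
  if (!length(labels$sizes)) return(0)
  sum(labels$sizes[labels$spanning]) / prod(labels$dim)
}

#' Average (second-moment) cluster size S
#'
#' `S = sum(s^2 n_s) / sum(s n_s)` over non-spanning clusters — the
#' second-moment convention presupposed by the scaling law
#' `S ~ |p - pc|^-gamma`; the arithmetic mean is available as an
#' alternative.  Returns 0 when no finite cluster exists.
#'
#' @param labels a [label_clusters()] result.
#' @param method `"second_moment"` (default) or `"arithmetic"`.
#' @return Scalar average cluster size.
#' @export
average_cluster_size <- function(labels, method = "second_moment") {
  method <- match.arg(method, c("second_moment", "arithmetic"))
  s <- labels$sizes[!labels$spanning]
  if (!length(s)) return(0)
  if (method == "second_moment") sum(as.numeric(s)^2) / sum(s) else mean(s)
}

#' Cluster correlation length
#'
#' The size-weighted gyration measure
#' `xi^2 = sum(2 Rg_s^2 s^2 n_s) / sum(s^2 n_s)` over non-spanning
#' clusters, equivalent to the root-mean-square distance between two sites
#' of the same (finite) cluster.  Returns `NA` when no finite cluster
#' exists (undefined marker, not an error); all-singleton grids give 0.
#'
#' @param labels a [label_clusters()] result.
#' @return Scalar correlation length, or `NA_real_`.
#' @export
correlation_length <- function(labels) {
  s <- as.numeric(labels$sizes[!labels$spanning])
  if (!length(s)) return(NA_real_)
  rg2 <- labels$rg[!labels$spanning]^2
  sqrt(sum(2 * rg2 * s^2) / sum(s^2))
}

# type-7 percentile thresholds -> occupied counts, for every p at once
threshold_counts <- function(v, p_grid) {
  n <- length(v)
  sv <- sort(v)
  k <- integer(length(p_grid))
  for (i in seq_along(p_grid)) {
    p <- p_grid[i]
    if (p <= 0) { k[i] <- 0L; next }
    if (p >= 1) { k[i] <- n; next }
    h <- (n - 1) * (1 - p) + 1
    fl <- floor(h)
    q <- sv[fl] + (h - fl) * (sv[min(fl + 1, n)] - sv[fl])
    k[i] <- n - findInterval(q, sv)  # strict '>' count
  }
  k
}

# canonical-ensemble conversion: average the fixed-count observables over
# the binomial distribution of the occupied count at each p (truncated to
# the +/- 8 sigma window; row k of `allk` holds the observables at count k)
binom_convolve <- function(allk, n, p_grid) {
  out <- matrix(0, length(p_grid), 4)
  for (i in seq_along(p_grid)) {
    p <- p_grid[i]
    if (p <= 0) next
    if (p >= 1) { out[i, ] <- allk[n, ]; next }
    s <- sqrt(n * p * (1 - p))
    lo <- max(1L, floor(n * p - 8 * s))
    hi <- min(n, ceiling(n * p + 8 * s))
    k <- lo:hi
    w <- dbinom(k, n, p)
    w <- w / sum(w)
    out[i, ] <- crossprod(w, allk[k, , drop = FALSE])
  }
  out
}

# non-overlapping (l+1)^2 tiles of a value matrix
extract_tiles <- function(v, ell) {
  m <- ell + 1L
  ntx <- nrow(v) %/% m
  nty <- ncol(v) %/% m
  if (ntx < 1L || nty < 1L)
    stop(sprintf("subsystem size %d exceeds field extent %dx%d",
                 ell, nrow(v), ncol(v)))
  tiles <- vector("list", ntx * nty)
  t <- 0L
  for (a in seq_len(ntx)) {
    for (b in seq_len(nty)) {
      t <- t + 1L
      tiles[[t]] <- v[((a - 1L) * m + 1L):(a * m),
                      ((b - 1L) * m + 1L):(b * m)]
    }
  }
  tiles
}

#' Percolation observables over occupation probabilities and subsystem sizes
#'
#' For every requested subsystem size `ell`, extracts non-overlapping
#' subsystems of `(ell+1)^2` sites from each field of the ensemble,
#' thresholds each subsystem at every occupation probability of `p_grid`
#' (the percentile rule applied to the subsystem's own values), and
#' accumulates the spanning probability `Pi`, the spanning-cluster density
#' `P`, the second-moment mean cluster size `S` (spanning cluster excluded)
#' and the correlation length `xi` over subsystems and realizations.
#'
#' Clusters are built with open boundaries; the full occupation sequence per
#' subsystem is processed incrementally (sorted union-find), so all
#' thresholds cost one pass.
#'
#' Two occupation ensembles are available.  `"rank"` (the percentile rule
#' as applied to real stress fields) occupies exactly the top `k(p)` sites
#' of each subsystem — a fixed-count, microcanonical ensemble.
#' `"binomial"` convolves the fixed-count observables with the binomial
#' distribution of the occupied count at probability `p` (the
#' Newman-Ziff construction), which reproduces ordinary site percolation
#' with independent Bernoulli(p) occupation; use it when validating
#' against canonical-ensemble reference values, whose finite-size widths
#' include the occupancy fluctuations that the rank rule suppresses.
#'
#' @param fields a [scalar_field2d()], a matrix, or a list of them (one
#'   entry per independent realization).
#' @param p_grid increasing occupation probabilities.
#' @param ells integer subsystem sizes; a field of extent `(ell+1)` yields a
#'   single subsystem.
#' @param connectivity `"face4"` or `"moore8"`.
#' @param ensemble `"rank"` (percentile rule, fixed occupied count) or
#'   `"binomial"` (canonical site percolation via binomial convolution).
#' @return A `percolation_curves` object: `curves` data frame with columns
#'   `(ell, p, Pi, P, S, xi, n_realizations)` plus per-realization arrays in
#'   `$arr` used for bootstrap resampling.
#' @export
percolation_curves <- function(fields, p_grid, ells,
                               connectivity = "face4",
                               ensemble = c("rank", "binomial")) {
  ensemble <- match.arg(ensemble)
  if (!is.list(fields) || inherits(fields, "scalar_field2d"))
    fields <- list(fields)
  p_grid <- sort(p_grid)
  if (any(p_grid < 0) || any(p_grid > 1)) stop("p_grid must lie in [0, 1]")
  ells <- sort(as.integer(ells))
  code <- conn_code(connectivity)
  nreal <- length(fields)
  np <- length(p_grid)
  nell <- length(ells)

  arr <- list(Pi = array(NA_real_, c(nreal, nell, np)),
              P = array(NA_real_, c(nreal, nell, np)),
              S = array(NA_real_, c(nreal, nell, np)),
              xi = array(NA_real_, c(nreal, nell, np)))

  for (r in seq_len(nreal)) {
    v <- field_values(fields[[r]])
    for (e in seq_len(nell)) {
      tiles <- extract_tiles(v, ells[e])
      acc <- matrix(0, np, 4)
      for (tile in tiles) {
        if (ensemble == "rank") {
          kv <- threshold_counts(as.numeric(tile), p_grid)
          ord <- order(kv)
          obs <- perc_observables_cpp(as.numeric(tile), nrow(tile), ncol(tile),
                                      as.integer(kv[ord]), code)
          obs[ord, ] <- obs
        } else {
          n <- length(tile)
          allk <- perc_observables_cpp(as.numeric(tile), nrow(tile),
                                       ncol(tile), seq_len(n), code)
          obs <- binom_convolve(allk, n, p_grid)
        }
        acc <- acc + obs
      }
      acc <- acc / length(tiles)
      arr$Pi[r, e, ] <- acc[, 1]
      arr$P[r, e, ] <- acc[, 2]
      arr$S[r, e, ] <- acc[, 3]
      arr$xi[r, e, ] <- acc[, 4]
    }
  }

  curves <- data.frame(
    ell = rep(ells, each = np),
    p = rep(p_grid, nell),
    Pi = as.numeric(t(apply(arr$Pi, c(2, 3), mean))),
    P = as.numeric(t(apply(arr$P, c(2, 3), mean))),
    S = as.numeric(t(apply(arr$S, c(2, 3), mean))),
    xi = as.numeric(t(apply(arr$xi, c(2, 3), mean))),
    n_realizations = nreal)
  structure(list(curves = curves, arr = arr, ells = ells, p = p_grid,
                 connectivity = connectivity, n_realizations = nreal),
            class = "percolation_curves")
}

#' @export
print.percolation_curves <- function(x, ...) {
  cat(sprintf(paste0("percolation_curves: sizes {%s}, %d occupation levels, ",
                     "%d realization(s), %s connectivity\n"),
              paste(x$ells, collapse = ", "), length(x$p),
              x$n_realizations, x$connectivity))
  invisible(x)
}

#' Percolation threshold from spanning-probability crossings
#'
#' Fits a probit curve to `Pi(p, ell)` for each subsystem size and estimates
#' the threshold from the pairwise crossing points of the fitted curves
#' (curves for different sizes cross close to `p_c`); the quoted error is
#' the scatter of the pairwise crossings.  Used to initialize and
#' cross-check the finite-size-scaling collapse.
#'
#' @param curves a [percolation_curves()] object.
#' @return List with `pc`, `err`, and the matrix of pairwise `crossings`.
#' @export
spanning_probability_crossing <- function(curves) {
  cv <- curves$curves
  ells <- curves$ells
  if (length(ells) < 2L) stop("need Pi curves for at least 2 sizes")
  fits <- lapply(ells, function(l) {
    d <- cv[cv$ell == l & cv$Pi > 0.005 & cv$Pi < 0.995, ]
    if (nrow(d) < 3L) d <- cv[cv$ell == l, ]
    w <- rep(curves$n_realizations, nrow(d))
    suppressWarnings(glm(Pi ~ p, family = binomial("probit"),
                         data = d, weights = w))
  })
  cross <- c()
  for (a in seq_along(ells)) {
    for (b in seq_along(ells)) {
      if (b <= a) next
      ca <- coef(fits[[a]]); cb <- coef(fits[[b]])
      if (!all(is.finite(c(ca, cb))) || abs(ca[2] - cb[2]) < 1e-8) next
      pc <- (cb[1] - ca[1]) / (ca[2] - cb[2])
      if (pc > min(curves$p) && pc < max(curves$p)) cross <- c(cross, pc)
    }
  }
  if (!length(cross))
    stop("spanning-probability curves do not cross within the p grid")
  list(pc = mean(cross),
       err = if (length(cross) > 1) sd(cross) else NA_real_,
       crossings = cross)
}
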