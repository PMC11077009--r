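# Shared oracles and tiny fixtures.  Oracles are deliberately naive
# (dense loops, O(n^2) scans) and independent of the package's code paths.

# flood-fill connected components, plain R, open boundaries
oracle_label <- function(occ, connectivity = "face4") {
  nr <- nrow(occ); nc <- ncol(occ)
  moves <- if (connectivity == "face4") {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!occ[rr, cc] || lab[rr, cc] != 0L) next
    cur <- cur + 1L
    queue <- list(c(rr, cc))
    lab[rr, cc] <- cur
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (m in seq_len(nrow(moves))) {
        r2 <- q[1] + moves[m, 1]; c2 <- q[2] + moves[m, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (occ[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          queue <- c(queue, list(c(r2, c2)))
        }
      }
    }
  }
  lab
}

# observables from a label matrix, dense-loop version
oracle_stats <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  k <- max(lab)
  sizes <- integer(k); span <- logical(k); msd <- numeric(k)
  for (l in seq_len(k)) {
    idx <- which(lab == l, arr.ind = TRUE)
    sizes[l] <- nrow(idx)
    span[l] <- (min(idx[, 1]) == 1 && max(idx[, 1]) == nr) ||
      (min(idx[, 2]) == 1 && max(idx[, 2]) == nc)
    # mean squared distance over all ordered site pairs (incl. i = j)
    d2 <- 0
    for (a in seq_len(nrow(idx))) for (b in seq_len(nrow(idx)))
      d2 <- d2 + sum((idx[a, ] - idx[b, ])^2)
    msd[l] <- d2 / nrow(idx)^2
  }
  fin <- !span
  P <- sum(sizes[span]) / (nr * nc)
  S <- if (any(fin)) sum(sizes[fin]^2) / sum(sizes[fin]) else 0
  xi <- if (any(fin)) sqrt(sum(msd[fin] * sizes[fin]^2) / sum(sizes[fin]^2))
        else NA_real_
  list(sizes = sizes, spanning = span, P = P, S = S, xi = xi)
}

# canonical form of a labelling: map labels to first-occurrence order
canonical_labels <- function(lab) {
  v <- as.integer(lab)
  seen <- integer(0)
  out <- integer(length(v))
  for (i in seq_along(v)) {
    if (v[i] == 0L) next
    j <- match(v[i], seen)
    if (is.na(j)) { seen <- c(seen, v[i]); j <- length(seen) }
    out[i] <- j
  }
  matrix(out, nrow(lab), ncol(lab))
}

# small monolayer test parameters (grid kept tiny for speed)
tiny_params <- function(N = 1L, grid = c(24L, 24L, 18L), R0 = 6, ...) {
  model_params(N = N, R0 = R0, grid = grid, z_wall = 3,
               n_sim = 10L, n_relax = 0L, ...)
}

# two partially overlapping cells on a small grid, no substrate coupling
pair_state <- function(params, sep = 9) {
  st <- init_monolayer(params)
  coords <- stresschains:::grid_coords(params$grid)
  zc <- params$z_wall + params$R0
  cx <- params$grid[1] / 2; cy <- params$grid[2] / 2
  st$phi[, 1] <- stresschains:::tanh_sphere(coords, c(cx - sep / 2, cy, zc),
                                            params$R0, params$lam, params$grid)
  st$phi[, 2] <- stresschains:::tanh_sphere(coords, c(cx + sep / 2, cy, zc),
                                            params$R0, params$lam, params$grid)
  st
}
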