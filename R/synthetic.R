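# Synthetic-input generators: every input class the analysis stages accept
# can be produced in code, so the whole pipeline is testable with no
# external data.  All generators are deterministic given (parameters, seed)
# and embed their generating parameters as metadata.

synth_meta <- function(x, kind, ...) {
  attr(x, "synthetic_spec") <- c(list(kind = kind), list(...))
  x
}

#' I.i.d. uniform random field
#'
#' Independent Uniform(0,1) values per node.  Percentile thresholding of
#' such a field is exactly nearest-neighbour site percolation at occupation
#' probability `p`, which makes this the null ensemble for validating the
#' percolation stage against the 2D random-percolation universality class.
#'
#' @param shape integer `c(nx, ny)`, at least 2 x 2.
#' @param seed RNG seed.
#' @return A [scalar_field2d()] with the generator recorded as attribute
#'   `"synthetic_spec"`.
#' @export
iid_uniform_field <- function(shape, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 2L))
    stop("shape must be two extents of at least 2")
  set.seed(seed)
  f <- scalar_field2d(matrix(runif(prod(shape)), shape[1], shape[2]))
  synth_meta(f, "iid_uniform", shape = shape, seed = seed)
}

#' Spectrally correlated Gaussian random field
#'
#' Gaussian field with power spectrum `|q|^(-spectral_exponent)` built by
#' spectral synthesis: white noise is filtered in Fourier space with the
#' (real, symmetric) amplitude `|q|^(-exponent/2)`, the DC mode is zeroed,
#' and the result is standardized to unit variance.  Exponent 0 reduces to
#' white noise; larger exponents give long-range correlated disorder, the
#' contrast case to short-range (random-percolation) behaviour.
#'
#' @param shape integer `c(nx, ny)`.
#' @param spectral_exponent non-negative power-spectrum exponent.
#' @param seed RNG seed.
#' @return A [scalar_field2d()].
#' @export
gaussian_correlated_field <- function(shape, spectral_exponent, seed = 1L) {
  if (!is.finite(spectral_exponent) || spectral_exponent < 0)
    stop("spectral_exponent must be finite and non-negative")
  shape <- as.integer(shape)
  set.seed(seed)
  nx <- shape[1]; ny <- shape[2]
  w <- matrix(rnorm(nx * ny), nx, ny)
  qx <- 2 * pi * c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  qy <- 2 * pi * c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  qq <- sqrt(outer(qx^2, qy^2, "+"))
  amp <- qq
  amp[qq > 0] <- qq[qq > 0]^(-spectral_exponent / 2)
  amp[qq == 0] <- 0  # zero DC mode
  v <- Re(fft(fft(w) * amp, inverse = TRUE)) / length(w)
  v <- (v - mean(v)) / sd(v)
  f <- scalar_field2d(v)
  synth_meta(f, "gaussian_correlated", shape = shape,
             spectral_exponent = spectral_exponent, seed = seed)
}

#' Toy dipole stress-chain field
#'
#' Superposition of line-arranged contractile (negative) and extensile
#' (positive) stripe kernels, producing the filamentary compressive and
#' tensile patterns characteristic of stress chains.  Each chain is an
#' anisotropic Gaussian ridge with a random sign, centre and orientation
#' (drawn within `orientation_spread` of horizontal); the field mean is
#' subtracted so compressive and tensile weight balance.
#'
#' @param shape integer `c(nx, ny)`.
#' @param n_chains number of chains, at least 1.
#' @param amplitude kernel amplitude (0 gives the zero field).
#' @param orientation_spread half-range (radians) of chain orientations
#'   around horizontal.
#' @param seed RNG seed.
#' @param width,length_frac ridge half-width (lattice units) and chain
#'   length as a fraction of the smaller box edge.
#' @return A [scalar_field2d()].
#' @export
dipole_chain_field <- function(shape, n_chains = 6L, amplitude = 1,
                               orientation_spread = pi / 6, seed = 1L,
                               width = 2, length_frac = 0.4) {
  if (n_chains < 1L) stop("n_chains must be at least 1")
  shape <- as.integer(shape)
  set.seed(seed)
  nx <- shape[1]; ny <- shape[2]
  xs <- matrix(rep(seq_len(nx) - 1, ny), nx, ny)
  ys <- matrix(rep(seq_len(ny) - 1, each = nx), nx, ny)
  v <- matrix(0, nx, ny)
  L <- length_frac * min(shape)
  for (k in seq_len(n_chains)) {
    cx <- runif(1, 0, nx); cy <- runif(1, 0, ny)
    th <- runif(1, -orientation_spread, orientation_spread)
    sgn <- sample(c(-1, 1), 1)
    dx <- min_image(xs - cx, nx)
    dy <- min_image(ys - cy, ny)
    along <- dx * cos(th) + dy * sin(th)
    perp <- -dx * sin(th) + dy * cos(th)
    v <- v + sgn * amplitude *
      exp(-perp^2 / (2 * width^2)) * exp(-along^2 / (2 * L^2))
  }
  v <- v - mean(v)
  f <- scalar_field2d(v)
  synth_meta(f, "dipole_chain", shape = shape, n_chains = n_chains,
             amplitude = amplitude, orientation_spread = orientation_spread,
             seed = seed)
}

#' Exact scaling-law percolation curve sets
#'
#' Generates `P(p, ell)` and `S(p, ell)` curves that satisfy the
#' finite-size-scaling forms exactly:
#' `P = ell^(-beta/nu) F((p - pc) ell^(1/nu))` and
#' `S = ell^(gamma/nu) G((p - pc) ell^(1/nu))`, with fixed smooth master
#' functions `F(x) = 1/(1 + exp(-2x))` (also used, steepened, for the
#' spanning probability) and `G(x) = exp(-x^2/2)`, plus multiplicative
#' log-normal noise per realization.  The occupation grids are
#' size-adapted (`p = pc + x * ell^(-1/nu)` on a common `x` grid anchored
#' to the largest size), so at the true parameters the scaled points of
#' all sizes share identical collapse coordinates and a perfect collapse
#' is exactly representable — the property that makes this set the oracle
#' for [fss_collapse()] parameter recovery.
#'
#' @param pc,beta,nu,gamma true threshold and exponents (positive).
#' @param ells at least 3 subsystem sizes.
#' @param p_grid occupation grid for the largest size (defines the master
#'   `x` grid).
#' @param noise multiplicative noise level (log-normal sigma).
#' @param seed RNG seed.
#' @param n_real number of noisy realizations.
#' @return A `percolation_curves` object whose `$generator` records the
#'   true parameters.
#' @export
scaling_curve_set <- function(pc, beta, nu, gamma, ells, p_grid,
                              noise = 0, seed = 1L, n_real = 20L) {
  if (nu <= 0 || gamma <= 0 || beta < 0)
    stop("nu and gamma must be positive, beta non-negative")
  ells <- sort(as.integer(ells))
  if (length(ells) < 3L) stop("need at least 3 sizes")
  p_grid <- sort(p_grid)
  set.seed(seed)
  lref <- max(ells)
  xgrid <- (p_grid - pc) * lref^(1 / nu)
  np <- length(xgrid); nell <- length(ells)

  Fm <- function(x) 1 / (1 + exp(-2 * x))
  Gm <- function(x) exp(-x^2 / 2)

  arr <- list(Pi = array(NA_real_, c(n_real, nell, np)),
              P = array(NA_real_, c(n_real, nell, np)),
              S = array(NA_real_, c(n_real, nell, np)),
              xi = array(NA_real_, c(n_real, nell, np)))
  pmat <- matrix(NA_real_, np, nell)
  for (e in seq_len(nell)) {
    l <- ells[e]
    pmat[, e] <- pc + xgrid * l^(-1 / nu)
    P0 <- l^(-beta / nu) * Fm(xgrid)
    S0 <- l^(gamma / nu) * Gm(xgrid)
    Pi0 <- Fm(3 * xgrid)
    xi0 <- l * Gm(xgrid / 2) / 4
    for (r in seq_len(n_real)) {
      jig <- function(v) {
        if (noise == 0) v
        else v * exp(noise * rnorm(np) - noise^2 / 2)
      }
      arr$P[r, e, ] <- jig(P0)
      arr$S[r, e, ] <- jig(S0)
      arr$Pi[r, e, ] <- pmin(1, jig(Pi0))
      arr$xi[r, e, ] <- jig(xi0)
    }
  }
  curves <- data.frame(
    ell = rep(ells, each = np),
    p = as.numeric(pmat),
    Pi = as.numeric(t(apply(arr$Pi, c(2, 3), mean))),
    P = as.numeric(t(apply(arr$P, c(2, 3), mean))),
    S = as.numeric(t(apply(arr$S, c(2, 3), mean))),
    xi = as.numeric(t(apply(arr$xi, c(2, 3), mean))),
    n_realizations = n_real)
  structure(list(curves = curves, arr = arr, ells = ells, p = p_grid,
                 connectivity = "face4", n_realizations = n_real,
                 generator = list(pc = pc, beta = beta, nu = nu,
                                  gamma = gamma, noise = noise, seed = seed,
                                  master_P = "1/(1+exp(-2x))",
                                  master_S = "exp(-x^2/2)")),
            class = "percolation_curves")
}

#' Desk-scale monolayer fixtures
#'
#' Ready-to-run parameter sets and initial states for the two sides of the
#' solid-to-liquid transition: `solid_like` uses low drives
#' `(omega_tilde, alpha_tilde) = (0.1, 0.2)` and `liquid_like` high drives
#' `(0.5, 0.8)`; all other numerics are identical.  Intended for desk-scale
#' runs (N up to 64); larger N only triggers a warning.
#'
#' @param N number of cells (desk scale).
#' @param R0 cell radius.
#' @param box optional `c(Lx, Ly, Lz)`; sized from the packing if omitted.
#' @param regime `"solid_like"` or `"liquid_like"`.
#' @param seed RNG seed.
#' @param ... further [model_params()] overrides.
#' @return List with `params` (a `model_params`) and `state` (the initial
#'   [init_monolayer()] state).
#' @export
monolayer_fixture <- function(N = 16L, R0 = 8, box = NULL,
                              regime = c("solid_like", "liquid_like"),
                              seed = 1L, ...) {
  regime <- match.arg(regime)
  if (N > 64L)
    warning("fixture requested beyond desk scale (N > 64)", call. = FALSE)
  if (is.null(box)) {
    # pressed confluence: in-plane area ~ N pi R0^2 / 1.07 so neighbours
    # cage each other; near-triangular aspect (rows closer by sqrt(3)/2)
    ncols <- ceiling(sqrt(N))
    nrows <- ceiling(N / ncols)
    squeeze <- 0.93
    box <- c(2 * round(R0 * ncols * squeeze),
             2 * round(R0 * nrows * squeeze * sqrt(3) / 2),
             ceiling(2 * R0 + 8))
  }
  dr <- if (regime == "solid_like") c(0.1, 0.2) else c(0.5, 0.8)
  base <- model_params(N = N, R0 = R0, grid = box, seed = seed, ...)
  params <- params_from_drives(dr[1], dr[2], base = base)
  list(params = params, state = init_monolayer(params), regime = regime)
}
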