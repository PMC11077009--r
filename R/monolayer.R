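# Monolayer state construction and time evolution.
#
# A monolayer_state holds all N phase fields as columns of an nnode x N
# matrix (node index x + Lx*(y + Ly*z), zero-based coordinates), the static
# substrate field, and the polarity angles.  The in-plane boundaries are
# periodic; the substrate sits at the bottom z layers.

grid_nnode <- function(grid) prod(grid)

# zero-based lattice coordinates of every node, as an nnode x 3 matrix
grid_coords <- function(grid) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  x <- rep.int(seq_len(nx) - 1L, ny * nz)
  y <- rep.int(rep(seq_len(ny) - 1L, each = nx), nz)
  z <- rep(seq_len(nz) - 1L, each = nx * ny)
  cbind(x = x, y = y, z = z)
}

# minimum-image displacement along a periodic axis
min_image <- function(d, L) d - L * round(d / L)

# tanh sphere of radius R0 centred at `centre` (periodic x, y)
tanh_sphere <- function(coords, centre, R0, lam, grid) {
  dx <- min_image(coords[, 1] - centre[1], grid[1])
  dy <- min_image(coords[, 2] - centre[2], grid[2])
  dz <- coords[, 3] - centre[3]
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  0.5 * (1 - tanh((r - R0) / lam))
}

# near-triangular in-plane packing of N centres in an Lx x Ly periodic box
pack_centres <- function(N, grid, R0, jitter_frac = 0.05) {
  Lx <- grid[1]; Ly <- grid[2]
  ncols <- ceiling(sqrt(N * Lx / Ly))
  nrows <- ceiling(N / ncols)
  sx <- Lx / ncols; sy <- Ly / nrows
  if (min(sx, sy) < R0) {
    stop(sprintf(paste0(
      "box %dx%d too small for %d cells of radius %g at confluence; ",
      "need an in-plane box of at least %.0fx%.0f"),
      Lx, Ly, N, R0, ncols * R0, nrows * R0), call. = FALSE)
  }
  idx <- 0:(N - 1)
  row <- idx %/% ncols
  col <- idx %% ncols
  x <- (col + 0.5 + 0.5 * (row %% 2)) * sx
  y <- (row + 0.5) * sy
  x <- (x + runif(N, -jitter_frac * sx, jitter_frac * sx)) %% Lx
  y <- (y + runif(N, -jitter_frac * sy, jitter_frac * sy)) %% Ly
  cbind(x, y)
}

#' Initialize a confluent monolayer
#'
#' Places `N` tanh-profile spherical cells of radius `R0` on a jittered
#' near-triangular in-plane packing resting on the substrate, draws polarity
#' angles uniformly on `[-pi, pi]`, and builds the static substrate field (a
#' tanh profile occupying `z < z_wall`).  All randomness is drawn from the
#' global RNG after seeding with `params$seed`, so the same parameters always
#' yield bitwise-identical states.
#'
#' @param params a [model_params()] object.
#' @param seed_rng if `FALSE`, use the current RNG state instead of seeding
#'   from `params$seed` (used internally by [run_simulation()]).
#' @return An object of class `monolayer_state`: list with elements `phi`
#'   (nnode x N matrix), `theta`, `wall`, `grid`, `time`.
#' @export
init_monolayer <- function(params, seed_rng = TRUE) {
  stopifnot(inherits(params, "model_params"))
  if (seed_rng) set.seed(params$seed)
  grid <- params$grid
  coords <- grid_coords(grid)
  centres <- pack_centres(params$N, grid, params$R0)
  zc <- params$z_wall + params$R0
  if (zc + params$R0 + params$lam > grid[3])
    stop(sprintf(paste0("box height %d too small: cells of radius %g on a ",
                        "wall at z = %g need Lz >= %.0f"),
                 grid[3], params$R0, params$z_wall,
                 ceiling(zc + params$R0 + params$lam)), call. = FALSE)
  phi <- matrix(0, nrow(coords), params$N)
  # the phi^2 support of a tanh sphere sits ~0.44*lam inside the nominal
  # radius; offset the initial radius so the initial volume integral of
  # phi^2 starts near V0
  r_init <- params$R0 + 0.44 * params$lam
  for (i in seq_len(params$N)) {
    phi[, i] <- tanh_sphere(coords, c(centres[i, 1], centres[i, 2], zc),
                            r_init, params$lam, grid)
  }
  theta <- runif(params$N, -pi, pi)
  wall <- 0.5 * (1 - tanh((coords[, 3] - params$z_wall) / params$lam))
  structure(list(phi = phi, theta = theta, wall = wall,
                 grid = grid, time = 0L),
            class = "monolayer_state")
}

#' @export
print.monolayer_state <- function(x, ...) {
  cat(sprintf("monolayer_state: %d cells on a %s grid, t = %d steps\n",
              ncol(x$phi), paste(x$grid, collapse = "x"), x$time))
  invisible(x)
}

#' Double-well bulk energy density
#'
#' The local part of the interface free energy, `4 phi^2 (1 - phi)^2`,
#' minimized (zero) exactly at `phi = 0` and `phi = 1`.
#'
#' @param phi phase-field value(s) in `[0, 1]` (vectorized).
#' @return Energy density of the same shape as `phi`.
#' @export
bulk_energy_density <- function(phi) 4 * phi^2 * (1 - phi)^2

#' Free energy of a monolayer state
#'
#' Evaluates the discrete free energy: per-cell double-well plus gradient
#' interface terms, the soft volume constraint, phi^2-phi^2 overlap
#' repulsions and gradient adhesion cross-terms between cells and with the
#' substrate.  Gradients use forward differences so that the functional
#' derivative assembled by the stepper is the exact gradient of this
#' discrete functional.
#'
#' @param state a `monolayer_state`.
#' @param params a `model_params` object.
#' @param by_term if `TRUE` return the named vector of the seven terms
#'   (with per-cell volumes as attribute `"volumes"`) instead of their sum.
#' @return Total free energy, or the term vector.
#' @export
free_energy <- function(state, params, by_term = FALSE) {
  terms <- fe_terms_cpp(state$phi, state$wall, state$grid, cpp_par(params))
  if (by_term) terms else sum(terms)
}

#' Functional derivative of the free energy for one cell
#'
#' Assembles `dF/dphi_i` term by term: double-well derivative, interface
#' Laplacian, volume-constraint feedback, overlap repulsion with the other
#' cells and the substrate, and the adhesion Laplacian cross-terms.
#'
#' @param state a `monolayer_state`.
#' @param params a `model_params` object.
#' @param i cell index (1-based).
#' @return A 3D array over the grid.
#' @export
functional_derivative <- function(state, params, i) {
  if (i < 1 || i > ncol(state$phi)) stop("cell index out of range")
  v <- fderiv_cpp(state$phi, state$wall, state$grid, cpp_par(params), i)
  array(v, dim = state$grid)
}

#' Passive traction of one cell
#'
#' The interface-resolved force a cell exerts,
#' `T_i = -sum_nodes (dF/dphi_i) grad phi_i` (lattice sum, `a0 = 1`).  The
#' active polar force `alpha * (cos theta, sin theta, 0)` is not included;
#' the overdamped balance is `xi v = T + F_act`.
#'
#' @inheritParams functional_derivative
#' @return Numeric 3-vector `(Tx, Ty, Tz)`.
#' @export
cell_traction <- function(state, params, i) {
  if (i < 1 || i > ncol(state$phi)) stop("cell index out of range")
  traction_cpp(state$phi, state$wall, state$grid, cpp_par(params), i)
}

#' Contact-inhibition-of-locomotion polarity update
#'
#' One Euler-Maruyama step of the polarity angle:
#' `theta <- theta + dt * (-|T|/tau_pol) * dTheta + Dr * sqrt(dt) * eta`,
#' where `dTheta` is the signed smallest angle from the in-plane traction
#' direction to the polarity, so the drift rotates the polarity toward the
#' traction.  When the in-plane traction vanishes the drift is zero (the
#' alignment direction is undefined) and only noise acts.  The noise
#' amplitude is `Dr` applied literally; the common alternative
#' `sqrt(2*Dr)` scaling can be obtained by rescaling `Dr`.
#'
#' @param theta current polarity angle.
#' @param traction 3-vector; only the in-plane part enters.
#' @param params a `model_params` object (uses `dt`, `tau_pol`, `Dr`).
#' @param noise standard normal draw; defaults to one from the global RNG.
#' @return Updated angle wrapped to `(-pi, pi]`.
#' @export
update_polarity <- function(theta, traction, params, noise = rnorm(1)) {
  tx <- traction[1]; ty <- traction[2]
  tmag <- sqrt(tx^2 + ty^2)
  drift <- 0
  if (tmag > 1e-12) {
    d <- theta - atan2(ty, tx)
    d <- d - 2 * pi * floor((d + pi) / (2 * pi))  # wrap to (-pi, pi]
    if (d <= -pi) d <- d + 2 * pi
    drift <- -(tmag / params$tau_pol) * d
  }
  th <- theta + params$dt * drift + params$Dr * sqrt(params$dt) * noise
  th <- th - 2 * pi * floor((th + pi) / (2 * pi))
  if (th <= -pi) th <- th + 2 * pi
  th
}

#' Advance a monolayer by one explicit Euler step
#'
#' Computes all tractions, the overdamped velocities
#' `v_i = (T_i + alpha * Fhat_pol) / xi`, advects each field with its own
#' velocity (first-order upwind), relaxes via `-Gamma dF/dphi_i`, clamps the
#' fields to `[0, 1]`, and updates all polarities.  Aborts with a diagnostic
#' if the advection CFL bound is violated.
#'
#' @param state a `monolayer_state`.
#' @param params a `model_params` object.
#' @return A new `monolayer_state` with attributes `traction`, `velocity`
#'   (N x 3 matrices), `clamped` and `max_speed` describing the step.
#' @export
advance <- function(state, params) {
  phi <- state$phi + 0        # private copies: the kernel mutates in place
  theta <- state$theta + 0
  noise <- rnorm(length(theta))
  res <- step_cpp(phi, theta, state$wall, state$grid, cpp_par(params),
                  noise, FALSE)
  out <- state
  out$phi <- phi
  out$theta <- theta
  out$time <- state$time + 1L
  attr(out, "traction") <- res$traction
  attr(out, "velocity") <- res$velocity
  attr(out, "clamped") <- res$clamped
  attr(out, "max_speed") <- res$max_speed
  out
}

#' Run a monolayer simulation
#'
#' Seeds the RNG from `params$seed`, initializes the monolayer, relaxes it
#' passively for `params$n_relax` steps (activity and noise off), then runs
#' `params$n_sim` recorded steps of the full dynamics.  Per-cell positions
#' (periodic-aware, plus unwrapped copies), polarity angles, tractions and
#' volumes are recorded every `record_every` steps; optionally the
#' coarse-grained stress tensor on the complementary lattice is accumulated
#' into a running time average every `stress_every` steps.
#'
#' @param params a [model_params()] object.
#' @param init optional pre-built initial `monolayer_state` (the RNG is
#'   still seeded from `params$seed` for reproducibility).
#' @param record_every recording stride for positions/tractions.
#' @param record_stress accumulate the time-averaged stress field.
#' @param stress_every stride (in steps) for stress accumulation.
#' @param record_fields keep full phase-field snapshots every
#'   `record_every` steps (memory heavy; off by default).
#' @param energy_every if positive, log the free energy every that many
#'   steps.
#' @param verbose print a progress line every 200 steps.
#' @return A `monolayer_trajectory`: list with `params`, final `state`,
#'   recorded arrays (`centroid`, `centroid_unwrapped` of dim steps x N x 3,
#'   `theta`, `traction`, `volume`), per-step `clamped` counts, optional
#'   `energy` log, optional `stress_mean` ([tensor_field2d()]) and
#'   `low_volume_cells` flags.
#' @export
run_simulation <- function(params, init = NULL, record_every = 1L,
                           record_stress = FALSE, stress_every = 5L,
                           record_fields = FALSE, energy_every = 0L,
                           verbose = FALSE) {
  set.seed(params$seed)
  state <- if (is.null(init)) init_monolayer(params, seed_rng = FALSE) else init
  phi <- state$phi + 0
  theta <- state$theta + 0
  wall <- state$wall
  grid <- state$grid
  N <- params$N
  mx <- grid[1] + 1L; my <- grid[2] + 1L

  # passive relaxation: no activity, no polarity noise
  if (params$n_relax > 0L) {
    pr <- params; pr$alpha <- 0; pr$Dr <- 0
    prl <- cpp_par(pr)
    zero <- numeric(N)
    for (s in seq_len(params$n_relax)) {
      step_with_context(phi, theta, wall, grid, prl, zero, FALSE,
                        step = s, phase = "relax")
    }
  }

  nrec <- if (params$n_sim > 0L) length(seq(1L, params$n_sim, by = record_every)) else 0L
  centroid <- array(NA_real_, c(nrec, N, 3))
  unwrapped <- array(NA_real_, c(nrec, N, 3))
  theta_rec <- matrix(NA_real_, nrec, N)
  traction_rec <- array(NA_real_, c(nrec, N, 3))
  volume_rec <- matrix(NA_real_, nrec, N)
  clamped <- integer(params$n_sim)
  energy <- if (energy_every > 0L) list(step = integer(0), F = numeric(0)) else NULL
  fields <- if (record_fields) vector("list", nrec) else NULL

  stress_sum <- NULL
  stress_frames <- 0L
  low_volume <- rep(FALSE, N)

  prl <- cpp_par(params)
  cen0 <- centroid_cpp(phi, grid)
  prev <- cen0$centroid
  unw <- cen0$centroid

  ri <- 0L
  for (s in seq_len(params$n_sim)) {
    want_td <- record_stress && (s %% stress_every == 0L)
    res <- step_with_context(phi, theta, wall, grid, prl, rnorm(N), want_td,
                             step = s, phase = "active")
    clamped[s] <- res$clamped
    if (want_td) {
      sig <- coarse_stress_cpp(res$tdens, grid)
      if (is.null(stress_sum)) stress_sum <- sig else stress_sum <- stress_sum + sig
      stress_frames <- stress_frames + 1L
    }
    if ((s - 1L) %% record_every == 0L) {
      ri <- ri + 1L
      cen <- centroid_cpp(phi, grid)
      d <- cen$centroid - prev
      d[, 1] <- min_image(d[, 1], grid[1])
      d[, 2] <- min_image(d[, 2], grid[2])
      unw <- unw + d
      prev <- cen$centroid
      centroid[ri, , ] <- cen$centroid
      unwrapped[ri, , ] <- unw
      theta_rec[ri, ] <- theta
      traction_rec[ri, , ] <- res$traction
      volume_rec[ri, ] <- cen$volume
      low_volume <- low_volume | (cen$volume < 0.5 * params$V0)
      if (record_fields) fields[[ri]] <- phi + 0
    }
    if (energy_every > 0L && s %% energy_every == 0L) {
      energy$step <- c(energy$step, s)
      energy$F <- c(energy$F, sum(fe_terms_cpp(phi, wall, grid, prl)))
    }
    if (verbose && s %% 200L == 0L)
      message(sprintf("step %d / %d (max speed %.3g)", s, params$n_sim,
                      res$max_speed))
  }

  final <- structure(list(phi = phi, theta = theta, wall = wall,
                          grid = grid, time = params$n_relax + params$n_sim),
                     class = "monolayer_state")
  out <- list(params = params, state = final,
              centroid = centroid[seq_len(ri), , , drop = FALSE],
              centroid_unwrapped = unwrapped[seq_len(ri), , , drop = FALSE],
              theta = theta_rec[seq_len(ri), , drop = FALSE],
              traction = traction_rec[seq_len(ri), , , drop = FALSE],
              volume = volume_rec[seq_len(ri), , drop = FALSE],
              clamped = clamped, energy = energy,
              low_volume_cells = which(low_volume),
              fields = fields)
  if (record_stress && stress_frames > 0L) {
    out$stress_mean <- tensor_field2d(stress_sum / stress_frames,
                                      extent = c(mx, my),
                                      n_frames_averaged = stress_frames)
  }
  class(out) <- "monolayer_trajectory"
  if (length(out$low_volume_cells))
    warning(sprintf("cell volume collapsed below 50%% of V0 for cell(s) %s",
                    paste(out$low_volume_cells, collapse = ", ")),
            call. = FALSE)
  out
}

# wrap the kernel call so mid-run failures name the step
step_with_context <- function(phi, theta, wall, grid, prl, noise, want_td,
                              step, phase) {
  tryCatch(
    step_cpp(phi, theta, wall, grid, prl, noise, want_td),
    error = function(e) {
      stop(sprintf("simulation aborted at %s step %d: %s",
                   phase, step, conditionMessage(e)), call. = FALSE)
    })
}

#' @export
print.monolayer_trajectory <- function(x, ...) {
  cat(sprintf("monolayer_trajectory: %d cells, %d recorded steps\n",
              x$params$N, nrow(x$theta)))
  if (!is.null(x$stress_mean))
    cat(sprintf("  time-averaged stress over %d frames\n",
                x$stress_mean$n_frames_averaged))
  invisible(x)
}

#' Per-cell view of a monolayer state
#'
#' @param state a `monolayer_state`.
#' @param params a `model_params` object (needed for traction/velocity).
#' @param i cell index.
#' @return List with `phi` (3D array), `theta`, `centroid`, `velocity`,
#'   `traction` and the polarity unit vector `f_pol` (zero z-component).
#' @export
cell_state <- function(state, params, i) {
  if (i < 1 || i > ncol(state$phi)) stop("cell index out of range")
  cen <- centroid_cpp(state$phi, state$grid)
  tr <- cell_traction(state, params, i)
  fpol <- c(cos(state$theta[i]), sin(state$theta[i]), 0)
  vel <- (tr + params$alpha * fpol) / params$xi_fric
  list(phi = array(state$phi[, i], dim = state$grid),
       theta = state$theta[i],
       centroid = cen$centroid[i, ],
       volume = cen$volume[i],
       velocity = vel,
       traction = tr,
       f_pol = fpol)
}

#' Time-averaged in-plane cell positions of a trajectory
#'
#' Averages the unwrapped centroid trajectories over recorded steps and maps
#' the result back into the periodic box; the standard configuration for the
#' pair-correlation solid/liquid diagnostic.
#'
#' @param traj a `monolayer_trajectory`.
#' @return N x 2 matrix of in-plane positions.
#' @export
time_averaged_positions <- function(traj) {
  m <- apply(traj$centroid_unwrapped[, , 1:2, drop = FALSE], c(2, 3), mean)
  m[, 1] <- m[, 1] %% traj$params$grid[1]
  m[, 2] <- m[, 2] %% traj$params$grid[2]
  colnames(m) <- c("x", "y")
  m
}
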