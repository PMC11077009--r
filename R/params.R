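#' Model parameters for the multi-phase-field monolayer
#'
#' Collects every physical and numerical control of the monolayer model: the
#' interface energetics (stiffness `E`, interface width `lam`,
#' compressibility `mu`), the cell-cell and cell-substrate repulsions
#' (`kappa_cc`, `kappa_cw`) and adhesions (`omega_cc`, `omega_cw`), the
#' overdamped traction balance (substrate friction `xi_fric`, self-propulsion
#' strength `alpha`), the contact-inhibition-of-locomotion polarity dynamics
#' (`tau_pol`, rotational noise amplitude `Dr`), and the lattice/time-step
#' controls.
#'
#' The target cell volume is `V0 = (4/3) pi R0^3`.  The interface, repulsion
#' and adhesion prefactors are exposed as independently configurable
#' coefficients `c_bulk`, `c_rep`, `c_adh` (and the substrate analogues)
#' because more than one reading of the energy prefactors is in circulation;
#' the defaults are `c_bulk = E*lam/2`, `c_rep = kappa/lam`,
#' `c_adh = omega*lam^2`.  Universality conclusions do not depend on this
#' convention, but either reading is a one-line configuration change.
#'
#' Default magnitudes are calibrated only to produce a stable confluent
#' layer at desk scale (lattice units, `a0 = 1`); every value can be
#' overridden.
#'
#' @param N number of cells.
#' @param R0 initial cell radius, lattice units.
#' @param grid integer vector `c(Lx, Ly, Lz)` of lattice extents.
#' @param E cell stiffness.
#' @param mu compressibility (volume-constraint strength).
#' @param lam diffuse-interface width; must be at least `2*a0`.
#' @param Gamma relaxational mobility.
#' @param xi_fric substrate friction.
#' @param alpha self-propulsion (active traction) strength.
#' @param tau_pol polarity alignment time.
#' @param Dr rotational noise amplitude, applied literally as `Dr * eta`
#'   in the polarity dynamics (Euler-Maruyama; see the methods vignette).
#' @param kappa_cc,kappa_cw cell-cell and cell-substrate repulsion strengths.
#' @param omega_cc,omega_cw cell-cell and cell-substrate adhesion strengths.
#' @param a0 lattice spacing (fixed to 1 in this implementation).
#' @param dt explicit Euler time step.
#' @param n_sim number of recorded simulation steps.
#' @param n_relax passive relaxation steps run before activity is switched on.
#' @param z_wall height of the substrate interface.
#' @param seed RNG seed; all randomness in a run flows from it.
#' @param c_bulk,c_rep,c_adh,c_repw,c_adhw optional explicit prefactor
#'   overrides for the bulk+gradient, repulsion and adhesion terms.
#'
#' @return An object of class `model_params` (a validated list).
#' @seealso [drives()], [params_from_drives()], [init_monolayer()]
#' @export
model_params <- function(N = 16L, R0 = 8, grid = c(60L, 52L, 24L),
                         E = 1, mu = 8000, lam = 2, Gamma = 0.2,
                         xi_fric = 400, alpha = 0, tau_pol = 20, Dr = 0.5,
                         kappa_cc = 0.5, kappa_cw = 1,
                         omega_cc = 0.025, omega_cw = 0.25,
                         a0 = 1, dt = 0.025, n_sim = 2400L, n_relax = 600L,
                         z_wall = 4, seed = 1L,
                         c_bulk = NULL, c_rep = NULL, c_adh = NULL,
                         c_repw = NULL, c_adhw = NULL) {
  p <- list(
    N = as.integer(N), R0 = R0, V0 = (4 / 3) * pi * R0^3,
    grid = as.integer(grid),
    E = E, mu = mu, lam = lam, Gamma = Gamma, xi_fric = xi_fric,
    alpha = alpha, tau_pol = tau_pol, Dr = Dr,
    kappa_cc = kappa_cc, kappa_cw = kappa_cw,
    omega_cc = omega_cc, omega_cw = omega_cw,
    a0 = a0, dt = dt, n_sim = as.integer(n_sim),
    n_relax = as.integer(n_relax), z_wall = z_wall,
    seed = as.integer(seed),
    c_bulk = if (is.null(c_bulk)) E * lam / 2 else c_bulk,
    c_rep  = if (is.null(c_rep)) kappa_cc / lam else c_rep,
    c_adh  = if (is.null(c_adh)) omega_cc * lam^2 else c_adh,
    c_repw = if (is.null(c_repw)) kappa_cw / lam else c_repw,
    c_adhw = if (is.null(c_adhw)) omega_cw * lam^2 else c_adhw
  )
  class(p) <- "model_params"
  validate_params(p)
  p
}

#' Validate model parameters
#'
#' Checks the structural invariants of a parameter set: strictly positive
#' stiffness, compressibility, mobility, friction, alignment time and
#' interface width; non-negative activity, noise, repulsions and adhesions;
#' `a0` much smaller than `R0`; and an interface resolved by at least two
#' lattice spacings.
#'
#' @param p a `model_params` object.
#' @param stop_on_error if `FALSE`, return a character vector of violations
#'   instead of raising an error.
#' @return `p` invisibly (or the violation messages).
#' @export
validate_params <- function(p, stop_on_error = TRUE) {
  bad <- character()
  pos <- c("E", "mu", "Gamma", "xi_fric", "tau_pol", "lam", "dt", "R0")
  for (nm in pos)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      bad <- c(bad, sprintf("%s must be strictly positive", nm))
  nn <- c("alpha", "Dr", "kappa_cc", "kappa_cw", "omega_cc", "omega_cw")
  for (nm in nn)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      bad <- c(bad, sprintf("%s must be non-negative", nm))
  if (length(p$grid) != 3L || any(p$grid < 4L))
    bad <- c(bad, "grid must be three extents of at least 4 nodes")
  if (p$a0 != 1)
    bad <- c(bad, "lattice spacing a0 is fixed to 1")
  if (is.finite(p$R0) && p$R0 <= 4 * p$a0)
    bad <- c(bad, "a0 must be much smaller than R0 (need R0 > 4*a0)")
  if (is.finite(p$lam) && p$lam < 2 * p$a0)
    bad <- c(bad, "interface width lam must be at least 2*a0 to be resolved")
  if (p$N < 1L)
    bad <- c(bad, "N must be at least 1")
  if (length(bad) && stop_on_error)
    stop("invalid model parameters:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  if (stop_on_error) invisible(p) else bad
}

#' Dimensionless drives of the solid-to-liquid transition
#'
#' Returns the two control parameters that drive the transition: the
#' cell-cell to cell-substrate adhesion ratio `omega_tilde = omega_cc /
#' omega_cw` and the dimensionless traction strength `alpha_tilde =
#' alpha * tau_pol / (xi_fric * R0)`.
#'
#' @param p a `model_params` object.
#' @return Named numeric vector `c(omega_tilde, alpha_tilde)`.
#' @export
drives <- function(p) {
  c(omega_tilde = p$omega_cc / p$omega_cw,
    alpha_tilde = p$alpha * p$tau_pol / (p$xi_fric * p$R0))
}

#' Build parameters from the dimensionless drives
#'
#' Inverse of [drives()]: given `omega_tilde` and `alpha_tilde`, sets
#' `omega_cc = omega_tilde * omega_cw` and `alpha = alpha_tilde * xi_fric *
#' R0 / tau_pol` on top of a base parameter set.
#'
#' @param omega_tilde adhesion ratio, typically in `[0.1, 0.5]`.
#' @param alpha_tilde dimensionless traction, typically in `[0, 0.8]`.
#' @param base a `model_params` object supplying everything else.
#' @param ... further overrides passed to [model_params()].
#' @return A `model_params` object.
#' @export
params_from_drives <- function(omega_tilde, alpha_tilde,
                               base = model_params(), ...) {
  stopifnot(inherits(base, "model_params"))
  args <- list(...)
  keep <- setdiff(names(formals(model_params)),
                  c("c_bulk", "c_rep", "c_adh", "c_repw", "c_adhw", "..."))
  base_args <- base[intersect(keep, names(base))]
  base_args$omega_cc <- omega_tilde * base$omega_cw
  base_args$alpha <- alpha_tilde * base$xi_fric * base$R0 / base$tau_pol
  base_args[names(args)] <- args
  do.call(model_params, base_args)
}

#' @export
print.model_params <- function(x, ...) {
  d <- drives(x)
  cat("Multi-phase-field monolayer parameters\n")
  cat(sprintf("  N = %d cells, R0 = %g (V0 = %.1f), grid %s\n",
              x$N, x$R0, x$V0, paste(x$grid, collapse = "x")))
  cat(sprintf("  E = %g, mu = %g, lam = %g, Gamma = %g\n",
              x$E, x$mu, x$lam, x$Gamma))
  cat(sprintf("  kappa_cc = %g, kappa_cw = %g, omega_cc = %g, omega_cw = %g\n",
              x$kappa_cc, x$kappa_cw, x$omega_cc, x$omega_cw))
  cat(sprintf("  xi = %g, alpha = %g, tau_pol = %g, Dr = %g\n",
              x$xi_fric, x$alpha, x$tau_pol, x$Dr))
  cat(sprintf("  drives: omega_tilde = %.3f, alpha_tilde = %.3f\n",
              d[1], d[2]))
  cat(sprintf("  dt = %g, n_sim = %d, n_relax = %d, seed = %d\n",
              x$dt, x$n_sim, x$n_relax, x$seed))
  invisible(x)
}

# internal: flat coefficient list handed to the C++ kernels
cpp_par <- function(p) {
  list(c_bulk = p$c_bulk, lam = p$lam, mu = p$mu, V0 = p$V0,
       c_rep = p$c_rep, c_adh = p$c_adh, c_repw = p$c_repw,
       c_adhw = p$c_adhw, Gamma = p$Gamma, xi_fric = p$xi_fric,
       alpha = p$alpha, tau_pol = p$tau_pol, Dr = p$Dr, dt = p$dt)
}
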