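# Coarse-grained stress fields and their scalar reductions.
#
# Tractions are coarse-grained onto the complementary (dual) lattice:
# sigma_i = (1/a0^3) sum_{j in N_i} r_ij (x) T_j, with N_i the eight
# original-lattice vertices of the dual cell at node i, symmetrized, and the
# z column contracted so the 2D analysis field embeds the out-of-plane
# component sigma_zz.

#' Per-node traction density of a monolayer state
#'
#' Sums, over cells, the passive traction density `-(dF/dphi_i) grad phi_i`
#' and the active force density `alpha * Fhat_pol * phi_i^2 / integral(phi_i^2)`
#' (so the per-cell integral of the active part recovers `alpha Fhat_pol`
#' exactly).  Summing the field over all nodes recovers
#' `sum_i (T_i + F_act_i)`.
#'
#' @param state a `monolayer_state`.
#' @param params a `model_params` object.
#' @return N_nodes x 3 matrix of traction density, plus the grid as
#'   attribute `"grid"`.
#' @export
nodal_traction_field <- function(state, params) {
  if (!identical(as.integer(prod(state$grid)), nrow(state$phi)))
    stop("state fields do not match the grid")
  td <- nodal_traction_cpp(state$phi, state$theta, state$wall, state$grid,
                           cpp_par(params))
  attr(td, "grid") <- state$grid
  td
}

#' Coarse-grained stress tensor on the complementary lattice
#'
#' Applies the dual-lattice moment formula to a nodal traction field and
#' contracts (sums) the z column, producing the 2D tensor field of extent
#' `(Lx+1) x (Ly+1)` analysed by the percolation stage.  The first and last
#' dual rows/columns are periodic duplicates.  By construction the map is
#' linear in the tractions and annihilates any globally uniform traction
#' (the stencil offsets sum to zero).
#'
#' @param traction N_nodes x 3 traction density with a `"grid"` attribute,
#'   as produced by [nodal_traction_field()].
#' @param grid integer `c(Lx, Ly, Lz)`; defaults to the attribute.
#' @return A [tensor_field2d()].
#' @export
coarse_grained_stress <- function(traction, grid = attr(traction, "grid")) {
  if (is.null(grid)) stop("traction field carries no grid; pass `grid`")
  sig <- coarse_stress_cpp(traction, as.integer(grid))
  tensor_field2d(sig, extent = c(grid[1] + 1L, grid[2] + 1L))
}

#' Time average of tensor fields
#'
#' Arithmetic mean of congruent tensor fields; the `n_frames_averaged`
#' counter accumulates so that averages of averages stay consistent.
#'
#' @param frames list of [tensor_field2d()] objects on the same lattice.
#' @return A [tensor_field2d()].
#' @export
time_average <- function(frames) {
  if (length(frames) < 1L) stop("time_average needs at least one frame")
  ext <- frames[[1]]$extent
  acc <- 0
  nfr <- 0L
  for (f in frames) {
    stopifnot(inherits(f, "tensor_field2d"))
    if (!identical(f$extent, ext)) stop("tensor fields have mismatched lattices")
    acc <- acc + f$values * f$n_frames_averaged
    nfr <- nfr + f$n_frames_averaged
  }
  tensor_field2d(acc / nfr, extent = ext, n_frames_averaged = nfr)
}

#' Isotropic stress field
#'
#' One third of the trace per node, `(sigma_xx + sigma_yy + sigma_zz) / 3`:
#' positive for expansion, negative for compression.  With
#' `normalize = TRUE` the field is divided by the maximum compressive
#' magnitude (sign preserved), the convention used for snapshot figures;
#' `normalize = "abs"` divides by the maximum absolute value instead.
#'
#' @param field a [tensor_field2d()].
#' @param normalize `FALSE`, `TRUE` (max compression) or `"abs"`.
#' @return A [scalar_field2d()] of kind `"iso"`.
#' @export
isotropic_stress <- function(field, normalize = FALSE) {
  stopifnot(inherits(field, "tensor_field2d"))
  v <- (field$values[, "xx"] + field$values[, "yy"] + field$values[, "zz"]) / 3
  m <- matrix(v, field$extent[1], field$extent[2])
  norm <- NULL
  if (!identical(normalize, FALSE)) {
    norm <- if (identical(normalize, "abs")) max(abs(m)) else {
      comp <- m[m < 0]
      if (length(comp)) max(abs(comp)) else max(abs(m))
    }
    if (!is.finite(norm) || norm == 0)
      stop("cannot normalize an identically zero isotropic stress field")
    m <- m / norm
  }
  scalar_field2d(m, spacing = field$spacing, kind = "iso",
                 normalization = norm)
}

#' Out-of-plane stress field
#'
#' Extracts `sigma_zz = e_z . sigma . e_z` per node; optionally normalized
#' by its maximum absolute value.
#'
#' @param field a [tensor_field2d()].
#' @param normalize divide by the maximum absolute value.
#' @return A [scalar_field2d()] of kind `"zz"`.
#' @export
out_of_plane_stress <- function(field, normalize = FALSE) {
  stopifnot(inherits(field, "tensor_field2d"))
  m <- matrix(field$values[, "zz"], field$extent[1], field$extent[2])
  norm <- NULL
  if (isTRUE(normalize)) {
    norm <- max(abs(m))
    if (norm == 0) stop("cannot normalize an identically zero field")
    m <- m / norm
  }
  scalar_field2d(m, spacing = field$spacing, kind = "zz", normalization = norm)
}

#' Maximum in-plane shear field
#'
#' Half the difference of the in-plane principal stresses,
#' `sigma_tau = (sigma_max - sigma_min) / 2 =
#' sqrt(((sigma_xx - sigma_yy)/2)^2 + sigma_xy^2)`, invariant under in-plane
#' rotations of the tensor.
#'
#' @param field a [tensor_field2d()].
#' @param normalize divide by the maximum value.
#' @return A [scalar_field2d()] of kind `"tau"`.
#' @export
max_inplane_shear <- function(field, normalize = FALSE) {
  stopifnot(inherits(field, "tensor_field2d"))
  v <- sqrt(((field$values[, "xx"] - field$values[, "yy"]) / 2)^2 +
              field$values[, "xy"]^2)
  m <- matrix(v, field$extent[1], field$extent[2])
  norm <- NULL
  if (isTRUE(normalize)) {
    norm <- max(m)
    if (norm == 0) stop("cannot normalize an identically zero field")
    m <- m / norm
  }
  scalar_field2d(m, spacing = field$spacing, kind = "tau", normalization = norm)
}

#' Field statistics across a control-parameter sweep
#'
#' For a set of scalar fields indexed by a control value (for example the
#' adhesion ratio or the dimensionless traction), computes the global mean
#' and the susceptibility of each field and normalizes both columns by
#' their value at a reference control point, mirroring how fluctuation
#' trends are reported along each drive.
#'
#' @param fields named list of [scalar_field2d()] (names parse as the
#'   control values) or a list plus explicit `controls`.
#' @param controls numeric control values; defaults to `as.numeric(names(fields))`.
#' @param reference control value used for normalization (default: the
#'   smallest).
#' @param use_abs take the absolute field mean (useful for signed stress
#'   components); default `TRUE`.
#' @return Data frame with columns `control`, `mean`, `chi`, `mean_rel`,
#'   `chi_rel`, sorted by control value.
#' @export
field_statistics_sweep <- function(fields, controls = NULL,
                                   reference = NULL, use_abs = TRUE) {
  if (is.null(controls)) controls <- as.numeric(names(fields))
  if (anyNA(controls) || length(controls) != length(fields))
    stop("control values missing or mismatched")
  if (is.null(reference)) reference <- min(controls)
  if (!any(abs(controls - reference) < 1e-12))
    stop(sprintf("reference control value %g is not in the sweep", reference))
  mu <- vapply(fields, function(f) {
    v <- if (inherits(f, "scalar_field2d")) f$values else f
    if (use_abs) mean(abs(v)) else mean(v)
  }, numeric(1))
  chi <- vapply(fields, susceptibility, numeric(1))
  ord <- order(controls)
  ref_i <- which(abs(controls - reference) < 1e-12)[1]
  data.frame(control = controls[ord], mean = mu[ord], chi = chi[ord],
             mean_rel = (mu / mu[ref_i])[ord],
             chi_rel = (chi / chi[ref_i])[ord],
             row.names = NULL)
}
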