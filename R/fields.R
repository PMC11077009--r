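# Lattice field containers for the 2D analysis stage.

#' 2D scalar field on the analysis lattice
#'
#' @param values numeric matrix of node values.
#' @param spacing lattice spacing (a0).
#' @param kind one of `"iso"`, `"zz"`, `"tau"`, `"other"`.
#' @param normalization the maximum used to normalize the field, if any.
#' @return A `scalar_field2d` object.
#' @export
scalar_field2d <- function(values, spacing = 1, kind = "other",
                           normalization = NULL) {
  stopifnot(is.matrix(values))
  kind <- match.arg(kind, c("iso", "zz", "tau", "other"))
  structure(list(values = values, spacing = spacing, kind = kind,
                 normalization = normalization),
            class = "scalar_field2d")
}

#' @export
print.scalar_field2d <- function(x, ...) {
  cat(sprintf("scalar_field2d [%s]: %d x %d nodes, range [%.4g, %.4g]%s\n",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values),
              if (!is.null(x$normalization))
                sprintf(", normalized by %.4g", x$normalization) else ""))
  invisible(x)
}

#' 2D symmetric tensor field on the complementary stress lattice
#'
#' Stores the six independent components of the (z-contracted) stress tensor
#' per node of the `(Lx+1) x (Ly+1)` analysis lattice, in the column order
#' `xx, yy, zz, xy, xz, yz`.
#'
#' @param values numeric matrix with `prod(extent)` rows and 6 columns, or a
#'   3D array `extent x 6`.
#' @param extent integer vector `c(mx, my)` of lattice extents.
#' @param spacing lattice spacing.
#' @param n_frames_averaged number of frames averaged into the field.
#' @return A `tensor_field2d` object.
#' @export
tensor_field2d <- function(values, extent, spacing = 1,
                           n_frames_averaged = 1L) {
  if (length(dim(values)) == 3L) {
    extent <- dim(values)[1:2]
    values <- matrix(values, prod(extent), 6)
  }
  stopifnot(is.matrix(values), ncol(values) == 6,
            nrow(values) == prod(extent))
  colnames(values) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  structure(list(values = values, extent = as.integer(extent),
                 spacing = spacing,
                 n_frames_averaged = as.integer(n_frames_averaged)),
            class = "tensor_field2d")
}

#' @export
print.tensor_field2d <- function(x, ...) {
  cat(sprintf("tensor_field2d: %d x %d nodes, %d frame(s) averaged\n",
              x$extent[1], x$extent[2], x$n_frames_averaged))
  invisible(x)
}

#' Susceptibility of a scalar field
#'
#' The extensive fluctuation measure `chi = n * (<x^2> - <x>^2)` with `n`
#' the number of lattice sites of the field (population variance times n).
#'
#' @param field a [scalar_field2d()] or numeric matrix/vector.
#' @return Scalar susceptibility.
#' @export
susceptibility <- function(field) {
  v <- if (inherits(field, "scalar_field2d")) field$values else field
  v <- as.numeric(v)
  n <- length(v)
  if (n < 1L) stop("susceptibility of an empty field is undefined")
  n * (mean(v^2) - mean(v)^2)
}
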