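# Solid/liquid structural diagnostics: in-plane pair correlation and the
# static structure factor of cell-centre configurations.

#' In-plane pair correlation function g(r)
#'
#' Minimum-image distance histogram of an in-plane point configuration in a
#' periodic box, normalized by the number density and the 2D annulus
#' measure so that an ideal-gas (Poisson) configuration gives `g = 1`.
#' Radii are reported in units of `R0`.  Multiple frames may be supplied;
#' counts are averaged over frames.
#'
#' @param positions N x 2 matrix of in-plane positions, or a list of such
#'   matrices (frames).
#' @param box periodic extents `c(Lx, Ly)`.
#' @param R0 cell radius used to scale the r axis.
#' @param bin_width histogram bin width in length units (default `R0/20`).
#' @param r_max maximum radius (default half the smaller box edge).
#' @return A `pair_correlation` object: list with `r_centers` (in units of
#'   R0), `g`, `n_pairs` (mean ordered-pair counts per bin), `rho`, `N`.
#' @export
pair_correlation <- function(positions, box, R0, bin_width = R0 / 20,
                             r_max = min(box) / 2) {
  frames <- if (is.list(positions)) positions else list(positions)
  N <- nrow(frames[[1]])
  if (is.null(N) || N < 2L) stop("pair_correlation needs at least 2 points")
  if (bin_width <= 0) stop("bin width must be positive")
  breaks <- seq(0, r_max + bin_width, by = bin_width)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  for (pos in frames) {
    stopifnot(nrow(pos) == N)
    dx <- min_image(outer(pos[, 1], pos[, 1], "-"), box[1])
    dy <- min_image(outer(pos[, 2], pos[, 2], "-"), box[2])
    d <- sqrt(dx^2 + dy^2)[upper.tri(dx)]
    d <- d[d < breaks[nb + 1L]]
    h <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE), nbins = nb)
    counts <- counts + 2 * h   # ordered pairs
  }
  counts <- counts / length(frames)
  rho <- N / prod(box)
  r_lo <- breaks[-(nb + 1L)]
  r_hi <- breaks[-1L]
  shell <- pi * (r_hi^2 - r_lo^2)
  g <- counts / (N * rho * shell)
  structure(list(r_centers = (r_lo + r_hi) / 2 / R0, g = g,
                 n_pairs = counts, rho = rho, N = N, R0 = R0),
            class = "pair_correlation")
}

#' @export
print.pair_correlation <- function(x, ...) {
  cat(sprintf("pair_correlation: N = %d, rho = %.4g, %d bins up to r/R0 = %.2f\n",
              x$N, x$rho, length(x$g), max(x$r_centers)))
  invisible(x)
}

#' Two-dimensional static structure factor
#'
#' `S(q) = |sum_j exp(i q . r_j)|^2 / N` on the wavevectors commensurate
#' with the periodic box, `q = 2 pi (nx/Lx, ny/Ly)`; `S(0) = N` by
#' convention.
#'
#' @param positions N x 2 matrix of in-plane positions.
#' @param box periodic extents `c(Lx, Ly)`.
#' @param n_modes number of modes per axis on each side of zero.
#' @return List with `qx`, `qy` (vectors) and `S` (matrix), plus the radial
#'   average as a data frame `radial` with columns `q`, `S`.
#' @export
structure_factor_2d <- function(positions, box, n_modes = 16L) {
  N <- nrow(positions)
  nx <- seq(-n_modes, n_modes)
  qx <- 2 * pi * nx / box[1]
  qy <- 2 * pi * nx / box[2]
  S <- matrix(NA_real_, length(qx), length(qy))
  for (a in seq_along(qx)) {
    phase_x <- qx[a] * positions[, 1]
    for (b in seq_along(qy)) {
      ph <- phase_x + qy[b] * positions[, 2]
      S[a, b] <- (sum(cos(ph))^2 + sum(sin(ph))^2) / N
    }
  }
  qq <- sqrt(outer(qx^2, qy^2, "+"))
  nz <- qq > 1e-12
  br <- seq(0, max(qq), length.out = 24)
  bin <- findInterval(qq[nz], br, rightmost.closed = TRUE)
  radial <- data.frame(q = tapply(qq[nz], bin, mean),
                       S = tapply(S[nz], bin, mean))
  list(qx = qx, qy = qy, S = S, radial = radial)
}

#' Classify a configuration as solid- or liquid-like from g(r)
#'
#' Smooths g(r) with a 3-bin moving average, finds local maxima above a
#' height threshold outside the self-overlap region (`r/R0 < r_self`), and
#' labels the configuration `"solid"` if the dominant peak sits near the
#' cell diameter (`r/R0` in `[1.6, 2.4]`), `"liquid"` if a peak well below
#' the diameter (`r/R0 < 1.2`) dominates, and `"indeterminate"` otherwise
#' (including featureless g).
#'
#' @param gr a [pair_correlation()] object.
#' @param height_min minimum smoothed peak height (default 1.05).
#' @param r_self lower cutoff excluding trivial self-overlap (default 0.2).
#' @param solid_window dominant-peak window labelled solid.
#' @param liquid_max dominant-peak position below which the label is liquid.
#' @return List with `label` and a data frame `peaks` (`r_over_R0`,
#'   `height`).
#' @export
classify_state <- function(gr, height_min = 1.05, r_self = 0.2,
                           solid_window = c(1.6, 2.4), liquid_max = 1.2) {
  stopifnot(inherits(gr, "pair_correlation"))
  g <- gr$g
  n <- length(g)
  gs <- g
  if (n >= 3L)
    gs <- c(g[1], (g[-c(1, n)] + g[-c(n - 1, n)] + g[-c(1, 2)]) / 3, g[n])
  r <- gr$r_centers
  keep <- r >= r_self
  is_peak <- logical(n)
  for (i in which(keep)) {
    lo <- if (i > 1) gs[i - 1] else -Inf
    hi <- if (i < n) gs[i + 1] else -Inf
    is_peak[i] <- gs[i] > lo && gs[i] >= hi && gs[i] >= height_min
  }
  peaks <- data.frame(r_over_R0 = r[is_peak], height = gs[is_peak])
  if (nrow(peaks) == 0L)
    return(list(label = "indeterminate", peaks = peaks))
  dom <- peaks[which.max(peaks$height), ]
  label <- if (dom$r_over_R0 >= solid_window[1] && dom$r_over_R0 <= solid_window[2])
    "solid"
  else if (dom$r_over_R0 < liquid_max)
    "liquid"
  else
    "indeterminate"
  list(label = label, peaks = peaks[order(-peaks$height), ],
       dominant = dom)
}
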