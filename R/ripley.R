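# Edge-corrected 3-D Ripley K analysis of particle centroids in a
# spherical study window, with CSR reference, Monte-Carlo envelopes, a
# clustering verdict, and projected density heatmaps.

#' 3-D point pattern
#'
#' @param points numeric matrix or data frame with columns/coordinates
#'   `(z, y, x)`; zero rows give an empty pattern.
#' @return Data frame of class `point_pattern3d` with columns `z, y, x`.
#' @export
point_pattern3d <- function(points) {
  if (is.null(points) || (is.matrix(points) && nrow(points) == 0L) ||
      (is.data.frame(points) && nrow(points) == 0L)) {
    df <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0))
  } else if (is.matrix(points)) {
    df <- data.frame(z = points[, 1], y = points[, 2], x = points[, 3])
  } else {
    df <- data.frame(z = points$z, y = points$y, x = points$x)
  }
  if (nrow(df) && !all(is.finite(as.matrix(df))))
    stopf("point coordinates must be finite")
  class(df) <- c("point_pattern3d", "data.frame")
  df
}

#' Spherical study window
#'
#' The region in which the K-function is estimated. In the OCT analysis
#' the radius is conventionally the lateral width of the image and the
#' center defaults to the centroid of the point pattern.
#'
#' @param center numeric `(z, y, x)` center.
#' @param radius positive radius.
#' @return An object of class `study_window`.
#' @export
study_window <- function(center = c(0, 0, 0), radius) {
  assert_scalar_num(radius, "radius", lower = 0, strict_lower = TRUE)
  if (length(center) != 3L || !all(is.finite(center)))
    stopf("`center` must be a finite (z, y, x) triple")
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "study_window")
}

window_volume <- function(window) 4 / 3 * pi * window$radius^3

#' Spherical-cap fraction for isotropic edge correction
#'
#' Fraction of the surface area of a sphere of radius `d` centered at a
#' point inside the window that lies inside the (spherical) window. With
#' `rho` the distance of the point from the window center and `R` the
#' window radius, the fraction is 1 when `rho + d <= R` and otherwise the
#' spherical-cap area fraction `(1 + (R^2 - rho^2 - d^2) / (2 rho d)) / 2`,
#' clamped to `(0, 1]`. The K estimator weights each pair by the inverse
#' of this fraction (isotropic correction, exact for a spherical window).
#'
#' @param point numeric `(z, y, x)`, inside the window.
#' @param d non-negative test-sphere radius (vectorized).
#' @param window a [study_window()].
#' @return Fractions in `(0, 1]`.
#' @examples
#' w <- study_window(c(0, 0, 0), radius = 10)
#' cap_fraction(c(0, 0, 5), d = 10, window = w)  # 0.375
#' @export
cap_fraction <- function(point, d, window) {
  stopifnot(inherits(window, "study_window"))
  if (any(d < 0)) stopf("`d` must be non-negative")
  rho <- sqrt(sum((as.numeric(point) - window$center)^2))
  if (rho > window$radius + 1e-9)
    stopf("`point` lies outside the study window")
  cap_fraction_rho(rho, d, window$radius)
}

# vectorized over rho and d
cap_fraction_rho <- function(rho, d, R) {
  frac <- rep(1, length(d))
  out <- rho + d > R
  if (any(out)) {
    rr <- if (length(rho) > 1) rho[out] else rho
    frac[out] <- 0.5 * (1 + (R^2 - rr^2 - d[out]^2) / (2 * rr * d[out]))
  }
  pmin(pmax(frac, .Machine$double.eps), 1)
}

#' Edge-corrected 3-D Ripley K estimate
#'
#' Estimates `K(r) = |W| / (n (n - 1)) * sum_i sum_{j != i}
#' 1{||x_i - x_j|| <= r} / c(x_i, ||x_i - x_j||)` over a spherical study
#' window `W`, with `c` the spherical-cap fraction ([cap_fraction()]).
#' Under complete spatial randomness `K(r) = 4 pi r^3 / 3`, which is
#' returned as the reference curve. Points outside the window are dropped
#' with a warning before estimation.
#'
#' @param points a `point_pattern3d` (or coercible matrix/data frame).
#' @param window a [study_window()]; by default a sphere centered at the
#'   pattern centroid must be supplied explicitly.
#' @param radii increasing non-negative radii at which to evaluate K;
#'   default 64 evenly spaced values in `(0, 70]` px, matching the
#'   conventional 0-70 px analysis range.
#' @param correction `"isotropic"` (default) or `"none"` (no edge
#'   correction; biased downward at large radii).
#' @return Object of class `ripley_estimate`: list with `radii`,
#'   `k_values`, `csr_reference`, `n`, `window`, `correction`, and
#'   (after [csr_envelope()]) `envelope_lo`, `envelope_hi`.
#' @export
ripley_k <- function(points, window, radii = default_radii(),
                     correction = c("isotropic", "none")) {
  correction <- match.arg(correction)
  points <- point_pattern3d(points)
  stopifnot(inherits(window, "study_window"))
  if (is.unsorted(radii, strictly = TRUE) || any(radii < 0))
    stopf("`radii` must be strictly increasing and non-negative")
  pts <- as.matrix(points[, c("z", "y", "x")])
  rho <- sqrt(colSums((t(pts) - window$center)^2))
  if (any(rho > window$radius)) {
    warning(sprintf("dropping %d point(s) outside the study window",
                    sum(rho > window$radius)))
    pts <- pts[rho <= window$radius, , drop = FALSE]
    rho <- rho[rho <= window$radius]
  }
  n <- nrow(pts)
  if (n < 2L) stopf("need at least 2 points inside the window")
  dm <- as.matrix(dist(pts))
  # ordered pairs (i, j): weight 1 / c(rho_i, d_ij)
  ii <- row(dm)[upper.tri(dm)]
  jj <- col(dm)[upper.tri(dm)]
  dd <- dm[upper.tri(dm)]
  d_all <- c(dd, dd)
  rho_all <- c(rho[ii], rho[jj])
  wts <- if (correction == "isotropic")
    1 / cap_fraction_rho(rho_all, d_all, window$radius)
  else rep(1, length(d_all))
  o <- order(d_all)
  d_sorted <- d_all[o]
  cw <- cumsum(wts[o])
  pos <- findInterval(radii, d_sorted)
  ksum <- ifelse(pos > 0, cw[pmax(pos, 1L)], 0)
  k <- window_volume(window) / (n * (n - 1)) * ksum
  structure(list(radii = radii, k_values = k,
                 csr_reference = 4 / 3 * pi * radii^3,
                 envelope_lo = NULL, envelope_hi = NULL,
                 n = n, window = window, correction = correction),
            class = "ripley_estimate")
}

default_radii <- function(n = 64L, r_max = 70) seq(r_max / n, r_max, length.out = n)

#' Pointwise CSR envelopes for the K-function
#'
#' Simulates `n_sim` CSR patterns of `n` points in the window, estimates K
#' for each, and returns pointwise lower/upper envelopes at the
#' `alpha / 2` and `1 - alpha / 2` order statistics (rank
#' `max(1, floor(n_sim * alpha / 2))` from each end, so `n_sim = 20`,
#' `alpha = 0.05` gives the min/max envelope).
#'
#' @param n number of points per simulation (>= 2).
#' @param window a [study_window()].
#' @param radii evaluation radii.
#' @param n_sim number of simulations (>= 20).
#' @param alpha two-sided envelope level.
#' @param seed integer seed; simulation `i` uses `seed + i`.
#' @param estimate optional `ripley_estimate` to attach the envelopes to.
#' @return If `estimate` is given, that estimate with `envelope_lo` and
#'   `envelope_hi` filled; otherwise a list with `envelope_lo`,
#'   `envelope_hi`.
#' @export
csr_envelope <- function(n, window, radii = default_radii(), n_sim = 100L,
                         alpha = 0.05, seed = 1L, estimate = NULL) {
  if (n < 2L) stopf("`n` must be >= 2")
  if (n_sim < 20L) stopf("`n_sim` must be >= 20")
  sims <- matrix(0, n_sim, length(radii))
  for (i in seq_len(n_sim)) {
    pp <- simulate_point_pattern("csr", n, window, seed = seed + i)
    sims[i, ] <- ripley_k(pp, window, radii)$k_values
  }
  k <- max(1L, floor(n_sim * alpha / 2))
  lo <- apply(sims, 2, function(v) sort(v)[k])
  hi <- apply(sims, 2, function(v) sort(v, decreasing = TRUE)[k])
  if (!is.null(estimate)) {
    estimate$envelope_lo <- lo
    estimate$envelope_hi <- hi
    estimate$n_sim <- n_sim
    estimate$alpha <- alpha
    return(estimate)
  }
  list(envelope_lo = lo, envelope_hi = hi)
}

#' Clustering verdict against CSR
#'
#' `TRUE` iff the estimated K exceeds the upper envelope (when envelopes
#' are attached, else the CSR reference `4 pi r^3 / 3`) at every tabulated
#' radius inside `r_range` — the pattern is consistently more aggregated
#' than complete spatial randomness over that range.
#'
#' @param estimate a `ripley_estimate`.
#' @param r_range `c(r_min, r_max)`.
#' @return Logical.
#' @export
clustering_verdict <- function(estimate, r_range) {
  stopifnot(inherits(estimate, "ripley_estimate"))
  sel <- estimate$radii >= r_range[1] & estimate$radii <= r_range[2]
  if (!any(sel)) stopf("`r_range` contains no tabulated radii")
  ref <- estimate$envelope_hi %||% estimate$csr_reference
  all(estimate$k_values[sel] > ref[sel])
}

#' Projected density heatmap of a point pattern
#'
#' Projects the pattern onto a coordinate plane and evaluates a Gaussian
#' kernel density on a regular grid. The grid covers the projected points
#' expanded by four bandwidths (or explicit `xlim`/`ylim`), and the
#' density integrates (cell sum times cell area) to the number of points
#' for patterns away from the border.
#'
#' @param points a `point_pattern3d`.
#' @param plane `"xy"` (the retina-surface projection), `"xz"` or `"yz"`.
#' @param grid_shape `c(nx, ny)` number of grid cells.
#' @param bandwidth positive kernel standard deviation.
#' @param xlim,ylim optional explicit grid limits.
#' @return Numeric `ny x nx` matrix of class `projection_density` with
#'   attributes `xgrid`, `ygrid` (cell centers) and `cell_area`.
#' @export
projection_density <- function(points, plane = c("xy", "xz", "yz"),
                               grid_shape = c(64L, 64L), bandwidth,
                               xlim = NULL, ylim = NULL) {
  plane <- match.arg(plane)
  points <- point_pattern3d(points)
  if (nrow(points) == 0L) stopf("cannot compute a density of no points")
  assert_scalar_num(bandwidth, "bandwidth", lower = 0, strict_lower = TRUE)
  uv <- switch(plane,
               xy = cbind(points$x, points$y),
               xz = cbind(points$x, points$z),
               yz = cbind(points$y, points$z))
  pad <- 4 * bandwidth
  xlim <- xlim %||% (range(uv[, 1]) + c(-pad, pad))
  ylim <- ylim %||% (range(uv[, 2]) + c(-pad, pad))
  nx <- grid_shape[1]; ny <- grid_shape[2]
  dx <- diff(xlim) / nx; dy <- diff(ylim) / ny
  xg <- xlim[1] + (seq_len(nx) - 0.5) * dx
  yg <- ylim[1] + (seq_len(ny) - 0.5) * dy
  dens <- matrix(0, ny, nx)
  for (i in seq_len(nrow(uv))) {
    kx <- dnorm(xg, uv[i, 1], bandwidth)
    ky <- dnorm(yg, uv[i, 2], bandwidth)
    dens <- dens + outer(ky, kx)
  }
  structure(dens, xgrid = xg, ygrid = yg, cell_area = dx * dy,
            class = c("projection_density", "matrix"))
}

#' @export
print.ripley_estimate <- function(x, ...) {
  cat(sprintf(
    "3-D Ripley K estimate: n = %d, window radius %.1f, %s correction\n",
    x$n, x$window$radius, x$correction))
  cat(sprintf("  radii: %d values in [%.2f, %.2f]%s\n", length(x$radii),
              min(x$radii), max(x$radii),
              if (!is.null(x$envelope_hi)) "; CSR envelopes attached" else ""))
  invisible(x)
}

#' Plot a Ripley K estimate against its CSR reference
#'
#' @param x a `ripley_estimate`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ripley_estimate <- function(x, ...) {
  ylim <- range(c(x$k_values, x$csr_reference, x$envelope_hi), na.rm = TRUE)
  graphics::plot(x$radii, x$k_values, type = "l", lwd = 2,
                 xlab = "r (px)", ylab = "K(r)", ylim = ylim, ...)
  graphics::lines(x$radii, x$csr_reference, lty = 2)
  if (!is.null(x$envelope_lo)) {
    graphics::lines(x$radii, x$envelope_lo, col = "grey60")
    graphics::lines(x$radii, x$envelope_hi, col = "grey60")
  }
  graphics::legend("topleft", legend = c("estimate", "CSR"),
                   lty = c(1, 2), lwd = c(2, 1), bty = "n")
  invisible(x)
}
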