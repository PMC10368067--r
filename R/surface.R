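# Classical retina-surface extraction from noisy B-scans: particle
# suppression, per-band grayscale normalization, thresholding with
# small-region removal and smoothing, largest-component cleanup, and
# per-column surface curve extraction.

#' Surface-extraction parameters
#'
#' @param column_width width in px of the vertical bands used for local
#'   grayscale normalization (default 10).
#' @param threshold binarization threshold in `(0, 1)` applied after
#'   normalization.
#' @param min_region_area 2-D connected components smaller than this (px)
#'   are removed before smoothing.
#' @param gaussian_sigma standard deviation (px) of the Gaussian smoothing
#'   applied to the cleaned mask.
#' @param inpaint_window side (px) of the neighborhood used to replace
#'   suppressed particle pixels by the local unmasked median.
#' @param closing_radius radius (px) of the box structuring element used to
#'   close pinholes in the final mask.
#' @return An object of class `surface_params`.
#' @export
surface_params <- function(column_width = 10L, threshold = 0.5,
                           min_region_area = 200L, gaussian_sigma = 3,
                           inpaint_window = 11L, closing_radius = 2L) {
  if (column_width < 1) stopf("`column_width` must be >= 1")
  assert_scalar_num(threshold, "threshold", lower = 0, upper = 1)
  if (threshold <= 0 || threshold >= 1) stopf("`threshold` must be in (0, 1)")
  if (min_region_area < 0) stopf("`min_region_area` must be >= 0")
  assert_scalar_num(gaussian_sigma, "gaussian_sigma", lower = 0,
                    strict_lower = TRUE)
  structure(list(column_width = as.integer(column_width),
                 threshold = threshold,
                 min_region_area = as.integer(min_region_area),
                 gaussian_sigma = gaussian_sigma,
                 inpaint_window = as.integer(inpaint_window),
                 closing_radius = as.integer(closing_radius)),
            class = "surface_params")
}

#' Suppress detected particles before surface extraction
#'
#' Replaces each masked pixel by the median of the unmasked pixels in a
#' centered `inpaint_window x inpaint_window` neighborhood (falling back to
#' the global unmasked median when the neighborhood is fully masked), so
#' bright vitreous particles do not leak into the binarized retina mask.
#'
#' @param image numeric matrix.
#' @param particle_mask logical matrix of the same shape.
#' @param inpaint_window odd neighborhood side in px.
#' @return The image with masked pixels replaced.
#' @export
suppress_particles <- function(image, particle_mask, inpaint_window = 11L) {
  assert_matrix_image(image)
  if (!identical(dim(particle_mask), dim(image)))
    stopf("`particle_mask` shape does not match the image")
  if (all(particle_mask))
    stopf("`particle_mask` covers the entire image")
  if (!any(particle_mask)) return(image)
  half <- max(1L, inpaint_window %/% 2L)
  global_med <- median(image[!particle_mask])
  out <- image
  idx <- which(particle_mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1]; c <- idx[k, 2]
    rr <- max(1L, r - half):min(nrow(image), r + half)
    cc <- max(1L, c - half):min(ncol(image), c + half)
    vals <- image[rr, cc][!particle_mask[rr, cc]]
    out[r, c] <- if (length(vals)) median(vals) else global_med
  }
  out
}

#' Normalize grayscale on small vertical bands
#'
#' Partitions the image into vertical bands of `column_width` columns (the
#' last band may be narrower) and rescales each band independently to
#' `[0, 1]` by robust min-max (1st/99th percentile clipping). Constant
#' bands map to 0. This removes lateral gain variation so that one global
#' threshold works across the B-scan.
#'
#' @param image numeric matrix.
#' @param column_width band width in px.
#' @return Normalized image in `[0, 1]`.
#' @export
normalize_columns <- function(image, column_width = 10L) {
  assert_matrix_image(image)
  if (column_width < 1) stopf("`column_width` must be >= 1")
  out <- image
  W <- ncol(image)
  starts <- seq.int(1L, W, by = column_width)
  for (s in starts) {
    cols <- s:min(W, s + column_width - 1L)
    band <- image[, cols, drop = FALSE]
    q <- quantile(band, c(0.01, 0.99), names = FALSE, type = 7)
    if (q[2] - q[1] <= .Machine$double.eps) {
      out[, cols] <- 0
    } else {
      out[, cols] <- pmin(pmax((band - q[1]) / (q[2] - q[1]), 0), 1)
    }
  }
  out
}

#' Binarize a normalized B-scan and clean the mask
#'
#' Thresholds the image, removes small 2-D connected components
#' (8-connectivity), then smooths the mask with a Gaussian filter and
#' re-thresholds at 0.5.
#'
#' @param image numeric matrix in `[0, 1]` (normalized).
#' @param params a [surface_params()] object.
#' @return Logical matrix.
#' @export
binarize_and_clean <- function(image, params = surface_params()) {
  assert_matrix_image(image)
  mask <- image >= params$threshold
  if (any(mask) && params$min_region_area > 0) {
    lab <- label_2d(mask)
    sizes <- tabulate(lab[lab > 0], nbins = attr(lab, "n_labels"))
    keep <- which(sizes >= params$min_region_area)
    mask <- matrix(lab %in% keep & lab > 0, nrow(image), ncol(image))
  }
  if (!any(mask)) return(mask)
  sm <- blur_gaussian(mask * 1, params$gaussian_sigma)
  sm >= 0.5
}

#' Extract the retina mask from a B-scan
#'
#' Full mask pipeline: particle suppression (when a particle mask is
#' given), per-band normalization, binarization with cleaning, keeping the
#' largest connected component, and morphological closing to fill
#' pinholes.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param particle_mask optional logical matrix of particles to suppress.
#' @param params a [surface_params()] object.
#' @return Logical retina mask.
#' @export
retina_mask <- function(image, particle_mask = NULL,
                        params = surface_params()) {
  img <- image
  if (!is.null(particle_mask))
    img <- suppress_particles(img, particle_mask, params$inpaint_window)
  img <- normalize_columns(img, params$column_width)
  mask <- binarize_and_clean(img, params)
  if (!any(mask)) stopf("no retina found: empty mask after cleaning")
  lab <- label_2d(mask)
  sizes <- tabulate(lab[lab > 0], nbins = attr(lab, "n_labels"))
  largest <- which.max(sizes)
  mask <- matrix(lab == largest, nrow(image), ncol(image))
  close_box(mask, params$closing_radius)
}

#' Per-column surface curve of a retina mask
#'
#' The surface row of a column is the smallest row index holding a mask
#' pixel (topmost: in a B-scan the vitreous lies above the retina).
#' Columns without mask pixels are linearly interpolated from the nearest
#' valid neighbors (nearest-value extension at the ends).
#'
#' @param mask logical matrix (non-empty).
#' @return Numeric vector of 0-based surface rows, one per column, of
#'   class `surface_curve`.
#' @export
surface_curve <- function(mask) {
  if (!any(mask)) stopf("cannot extract a surface from an empty mask")
  W <- ncol(mask)
  rows <- rep(NA_real_, W)
  for (c in seq_len(W)) {
    r <- which(mask[, c])
    if (length(r)) rows[c] <- r[1] - 1   # 0-based
  }
  if (anyNA(rows)) {
    ok <- which(!is.na(rows))
    rows <- approx(ok, rows[ok], xout = seq_len(W), rule = 2)$y
  }
  structure(rows, class = "surface_curve")
}

# logical mask of the vitreous: strictly above the surface curve
vitreous_mask <- function(curve, dims, margin = 2L) {
  mask <- matrix(FALSE, dims[1], dims[2])
  for (c in seq_len(dims[2])) {
    top <- floor(curve[c]) - margin   # 0-based exclusive bottom
    if (top >= 1) mask[seq_len(min(top, dims[1])), c] <- TRUE
  }
  mask
}
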