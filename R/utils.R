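# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All exported stochastic operations route through this so that
# seeded calls are reproducible and side-effect free.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a finite numeric scalar", name)
  if (strict_lower && x <= lower)
    stopf("`%s` must be > %s", name, lower)
  if (!strict_lower && x < lower)
    stopf("`%s` must be >= %s", name, lower)
  if (x > upper)
    stopf("`%s` must be <= %s", name, upper)
  invisible(x)
}

assert_matrix_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("`%s` must be a numeric matrix", name)
  if (!all(is.finite(x)))
    stopf("`%s` contains non-finite pixel values", name)
  invisible(x)
}

# clamped (edge-replicating) index vector for separable filters
clamp_idx <- function(n, offset) pmin(pmax(seq_len(n) + offset, 1L), n)

# Separable Gaussian blur with edge replication; works for any image size.
blur_gaussian <- function(img, sigma) {
  assert_scalar_num(sigma, "sigma", lower = 0, strict_lower = TRUE)
  radius <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq.int(-radius, radius), sd = sigma)
  k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  acc <- matrix(0, h, w)
  for (t in seq_along(k))
    acc <- acc + k[t] * img[clamp_idx(h, t - radius - 1L), , drop = FALSE]
  out <- matrix(0, h, w)
  for (t in seq_along(k))
    out <- out + k[t] * acc[, clamp_idx(w, t - radius - 1L), drop = FALSE]
  out
}

# Binary box dilation/erosion (radius in px). Outside the image is treated
# as background for dilation and as foreground for erosion, so closing does
# not eat the borders.
dilate_box <- function(mask, radius = 1L) {
  h <- nrow(mask); w <- ncol(mask)
  acc <- matrix(FALSE, h, w)
  for (dr in -radius:radius) {
    rows <- seq_len(h) + dr
    ok <- rows >= 1L & rows <= h
    shifted <- matrix(FALSE, h, w)
    shifted[ok, ] <- mask[rows[ok], , drop = FALSE]
    acc <- acc | shifted
  }
  out <- matrix(FALSE, h, w)
  for (dc in -radius:radius) {
    cols <- seq_len(w) + dc
    ok <- cols >= 1L & cols <= w
    shifted <- matrix(FALSE, h, w)
    shifted[, ok] <- acc[, cols[ok], drop = FALSE]
    out <- out | shifted
  }
  out
}

erode_box <- function(mask, radius = 1L) {
  !dilate_box(!mask, radius)
}

close_box <- function(mask, radius = 1L) {
  erode_box(dilate_box(mask, radius), radius)
}

# 2-D connected components, 8-connectivity (via the 3-D labeler on a
# single-slice volume under 26-connectivity).
label_2d <- function(mask) {
  lab <- .cc_label(as.logical(mask), c(dim(mask), 1L), 26L)
  n <- attr(lab, "n_labels")
  out <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  attr(out, "n_labels") <- n
  out
}
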