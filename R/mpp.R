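# Marked point process detection of bright vitreous particles.
#
# A B-scan is modelled as carrying a configuration of non-overlapping
# vertical rectangles; the detection result is the configuration minimizing
# an energy that sums a per-rectangle data term (a quality function of the
# rectangle/crown contrast statistic) under a hard non-overlap constraint.

#' MPP detector parameters
#'
#' @param x0 positive contrast threshold of the quality function: rectangles
#'   with contrast statistic above `x0` receive negative (rewarding) energy
#'   under the corrected quality form.
#' @param wmin,wmax,lmin,lmax integer bounds of rectangle width (lateral,
#'   px) and length (vertical, px).
#' @param crown_width width in px of the crown ring surrounding a rectangle
#'   footprint, used as the local background.
#' @param bright_only if `TRUE` (default) only rectangles brighter than
#'   their crown can score: detection targets the brightest spots, and the
#'   contrast statistic alone is sign-blind.
#' @param grid_stride stride in px of the candidate-center grid.
#' @param quality_form `"corrected"` (default, continuous at `x0`, negative
#'   beyond it) or `"printed"` (the discontinuous form; see [quality()]).
#' @param optimizer list of annealing settings: `max_iter`, initial and
#'   final temperatures `t0`, `t_end`, and `conv_window` (stop early after
#'   this many iterations without improvement).
#' @param max_candidates cap on the number of negative-energy candidates
#'   kept for stochastic optimization (best first).
#' @param seed integer RNG seed for the stochastic optimizer.
#' @return An object of class `mpp_params`.
#' @export
mpp_params <- function(x0 = 2.5, wmin = 3L, wmax = 7L, lmin = 3L, lmax = 9L,
                       crown_width = 2L, bright_only = TRUE,
                       grid_stride = 1L,
                       quality_form = c("corrected", "printed"),
                       optimizer = list(max_iter = 3000L, t0 = 1,
                                        t_end = 1e-3, conv_window = 1000L),
                       max_candidates = 5000L, seed = 1L) {
  quality_form <- match.arg(quality_form)
  assert_scalar_num(x0, "x0", lower = 0, strict_lower = TRUE)
  if (wmin > wmax || lmin > lmax) stopf("size bounds must be ordered")
  if (crown_width < 1) stopf("`crown_width` must be >= 1")
  if (grid_stride < 1) stopf("`grid_stride` must be >= 1")
  opt <- list(max_iter = 3000L, t0 = 1, t_end = 1e-3, conv_window = 1000L)
  opt[names(optimizer)] <- optimizer
  structure(list(x0 = x0, wmin = as.integer(wmin), wmax = as.integer(wmax),
                 lmin = as.integer(lmin), lmax = as.integer(lmax),
                 crown_width = as.integer(crown_width),
                 bright_only = isTRUE(bright_only),
                 grid_stride = as.integer(grid_stride),
                 quality_form = quality_form, optimizer = opt,
                 max_candidates = as.integer(max_candidates),
                 seed = as.integer(seed)),
            class = "mpp_params")
}

#' Construct a rectangle set (configuration)
#'
#' @param row,col integer 0-based center coordinates.
#' @param w,l integer width (lateral) and length (vertical) in px.
#' @return A data frame of class `mpp_config` with one rectangle per row.
#' @export
rectangles <- function(row = integer(0), col = integer(0),
                       w = integer(0), l = integer(0)) {
  df <- data.frame(row = as.integer(row), col = as.integer(col),
                   w = as.integer(w), l = as.integer(l))
  class(df) <- c("mpp_config", "data.frame")
  df
}

# Half-open 0-based footprint bounds of rectangles: the center (row, col)
# anchors the footprint at row0 = row - l %/% 2, col0 = col - w %/% 2.
rect_bounds <- function(rects) {
  r0 <- rects$row - rects$l %/% 2L
  c0 <- rects$col - rects$w %/% 2L
  data.frame(r0 = r0, r1 = r0 + rects$l, c0 = c0, c1 = c0 + rects$w)
}

assert_rect_inside <- function(rect, image) {
  b <- rect_bounds(rect)
  if (any(b$r0 < 0) || any(b$r1 > nrow(image)) ||
      any(b$c0 < 0) || any(b$c1 > ncol(image)))
    stopf("rectangle footprint lies outside the image")
  invisible(b)
}

#' Rectangle/crown contrast statistic
#'
#' Measures how strongly a rectangle's interior contrasts with its local
#' background: the squared difference of the interior and crown means
#' normalized by the sum of their (population) variances. The crown is the
#' ring of pixels within `crown_width` of the footprint, excluding the
#' footprint and clipped to the image.
#'
#' If both variances are zero, the statistic is `0` when the means are
#' equal and `Inf` (a perfect-contrast sentinel) otherwise.
#'
#' @param image numeric matrix (B-scan) with finite values.
#' @param rect single-row rectangle (see [rectangles()]).
#' @param crown_width crown ring width in px (>= 1).
#' @return Non-negative scalar (possibly `Inf`).
#' @examples
#' img <- matrix(0, 12, 12); img[5:6, 5:6] <- 1
#' contrast_statistic(img, rectangles(5, 5, 2, 2), crown_width = 2)
#' @export
contrast_statistic <- function(image, rect, crown_width = 2L) {
  assert_matrix_image(image)
  b <- assert_rect_inside(rect, image)
  inner <- image[(b$r0 + 1L):b$r1, (b$c0 + 1L):b$c1]
  o_r0 <- max(0L, b$r0 - crown_width); o_r1 <- min(nrow(image), b$r1 + crown_width)
  o_c0 <- max(0L, b$c0 - crown_width); o_c1 <- min(ncol(image), b$c1 + crown_width)
  sel <- matrix(FALSE, nrow(image), ncol(image))
  sel[(o_r0 + 1L):o_r1, (o_c0 + 1L):o_c1] <- TRUE
  sel[(b$r0 + 1L):b$r1, (b$c0 + 1L):b$c1] <- FALSE
  crown <- image[sel]
  if (length(crown) == 0L)
    stopf("crown is empty: rectangle fills the image")
  mu_r <- mean(inner); mu_c <- mean(crown)
  v_r <- mean(inner^2) - mu_r^2   # population variance
  v_c <- mean(crown^2) - mu_c^2
  denom <- max(v_r, 0) + max(v_c, 0)
  num <- (mu_r - mu_c)^2
  if (denom <= 0) {
    if (num <= .Machine$double.eps) return(0)
    return(Inf)
  }
  num / denom
}

#' Quality function mapping contrast to energy
#'
#' Maps a rectangle's contrast statistic `x` to its data-term energy. Two
#' forms are provided. The `"printed"` form is
#' `Q(x) = 1 - x / x0` for `x < x0` and `exp(-(x - x0) / x0)` otherwise; it
#' is discontinuous at `x0` and everywhere positive, which makes the empty
#' configuration the global energy minimizer. The `"corrected"` form (the
#' default used in detection) subtracts 1 in the second branch, giving a
#' function continuous at `x0`, non-increasing on `[0, Inf)`, with range
#' `(-1, 1]`: high contrast is rewarded with negative energy, the standard
#' MPP quality-function convention.
#'
#' @param x non-negative contrast statistic (vectorized).
#' @param x0 positive contrast threshold.
#' @param form `"corrected"` or `"printed"`.
#' @return Numeric vector of quality values.
#' @examples
#' quality(c(0, 1, 2), x0 = 1)
#' quality(c(0, 1, 2), x0 = 1, form = "printed")
#' @export
quality <- function(x, x0, form = c("corrected", "printed")) {
  form <- match.arg(form)
  assert_scalar_num(x0, "x0", lower = 0, strict_lower = TRUE)
  if (any(x < 0, na.rm = TRUE)) stopf("`x` must be non-negative")
  out <- ifelse(x < x0, 1 - x / x0, exp(-(x - x0) / x0))
  if (form == "corrected")
    out <- ifelse(x < x0, 1 - x / x0, exp(-(x - x0) / x0) - 1)
  out
}

#' Data term (energy) of a single rectangle
#'
#' `D(r) = Q(x(r))` with `x` the contrast statistic and `Q` the quality
#' function. With `bright_only` (the default), rectangles not brighter than
#' their crown receive the worst quality value 1 regardless of contrast.
#'
#' @inheritParams contrast_statistic
#' @param params an [mpp_params()] object.
#' @return Scalar energy in `(-1, 1]` (corrected form).
#' @export
rectangle_energy <- function(image, rect, params = mpp_params()) {
  b <- assert_rect_inside(rect, image)
  if (params$bright_only) {
    inner <- image[(b$r0 + 1L):b$r1, (b$c0 + 1L):b$c1]
    o_r0 <- max(0L, b$r0 - params$crown_width)
    o_r1 <- min(nrow(image), b$r1 + params$crown_width)
    o_c0 <- max(0L, b$c0 - params$crown_width)
    o_c1 <- min(ncol(image), b$c1 + params$crown_width)
    sel <- matrix(FALSE, nrow(image), ncol(image))
    sel[(o_r0 + 1L):o_r1, (o_c0 + 1L):o_c1] <- TRUE
    sel[(b$r0 + 1L):b$r1, (b$c0 + 1L):b$c1] <- FALSE
    if (!any(sel)) stopf("crown is empty: rectangle fills the image")
    if (mean(inner) <= mean(image[sel])) return(1)
  }
  x <- contrast_statistic(image, rect, params$crown_width)
  quality(x, params$x0, params$quality_form)
}

#' Do two rectangles overlap?
#'
#' Overlap is intersection of the half-open pixel footprints; footprints
#' sharing only an edge do not overlap. The infinite non-overlap penalty of
#' the energy model is realized as a hard constraint: overlapping
#' configurations are inadmissible and never evaluated arithmetically.
#'
#' @param ri,rj single-row rectangles.
#' @return `TRUE` iff the footprints intersect.
#' @export
overlaps <- function(ri, rj) {
  a <- rect_bounds(ri); b <- rect_bounds(rj)
  a$r0 < b$r1 && b$r0 < a$r1 && a$c0 < b$c1 && b$c0 < a$c1
}

# n x n logical overlap matrix for a rectangle data frame
overlap_matrix <- function(rects) {
  b <- rect_bounds(rects)
  n <- nrow(b)
  if (n == 0L) return(matrix(FALSE, 0, 0))
  ov <- outer(b$r0, b$r1, `<`) & outer(b$r1, b$r0, `>`) &
    outer(b$c0, b$c1, `<`) & outer(b$c1, b$c0, `>`)
  diag(ov) <- FALSE
  ov
}

#' Total energy of an admissible configuration
#'
#' Sum of rectangle data terms. Configurations with an overlapping pair are
#' inadmissible and raise an error (the hard-core realization of the
#' infinite interaction penalty); the empty configuration has energy 0.
#'
#' @param image numeric matrix.
#' @param config an `mpp_config` data frame.
#' @param params an [mpp_params()] object.
#' @return Scalar energy.
#' @export
configuration_energy <- function(image, config, params = mpp_params()) {
  if (nrow(config) == 0L) return(0)
  if (any(overlap_matrix(config)))
    stopf("inadmissible configuration: overlapping rectangles")
  sum(vapply(seq_len(nrow(config)), function(i)
    rectangle_energy(image, config[i, , drop = FALSE], params), numeric(1)))
}

# canonical rectangle ordering for deterministic output and tie-breaking
order_config <- function(config) {
  if (nrow(config) == 0L) return(config)
  config[order(config$row, config$col, config$w, config$l), , drop = FALSE]
}

# lexicographic comparison of two canonically ordered configs; -1/0/1
compare_config <- function(a, b) {
  va <- as.numeric(t(as.matrix(a[, c("row", "col", "w", "l")])))
  vb <- as.numeric(t(as.matrix(b[, c("row", "col", "w", "l")])))
  n <- min(length(va), length(vb))
  if (n > 0) {
    d <- va[seq_len(n)] - vb[seq_len(n)]
    i <- which(d != 0)
    if (length(i)) return(sign(d[i[1]]))
  }
  sign(length(va) - length(vb))
}

#' Score all grid candidates of a B-scan
#'
#' Enumerates rectangle candidates (centers on an integer grid with the
#' configured stride, all width/length combinations within bounds, footprint
#' inside the image) and computes each candidate's data term using summed
#' area tables, so the cost is independent of rectangle size.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param params an [mpp_params()] object.
#' @param roi_mask optional logical matrix; only candidates whose center
#'   lies in the mask are kept.
#' @return Data frame `row, col, w, l, D` (0-based centers).
#' @export
score_candidates <- function(image, params = mpp_params(), roi_mask = NULL) {
  assert_matrix_image(image)
  if (!is.null(roi_mask) && !identical(dim(roi_mask), dim(image)))
    stopf("`roi_mask` shape does not match the image")
  H <- nrow(image); W <- ncol(image)
  sat1 <- rbind(0, cbind(0, t(apply(apply(image, 2, cumsum), 1, cumsum))))
  sat2 <- rbind(0, cbind(0, t(apply(apply(image^2, 2, cumsum), 1, cumsum))))
  boxsum <- function(S, r0, r1, c0, c1) {
    # half-open 0-based [r0, r1) x [c0, c1); arguments are equal-length
    # vectors (rows) and (cols) combined on a grid
    S[cbind(r1 + 1L, c1 + 1L)] - S[cbind(r0 + 1L, c1 + 1L)] -
      S[cbind(r1 + 1L, c0 + 1L)] + S[cbind(r0 + 1L, c0 + 1L)]
  }
  cw <- params$crown_width
  out <- vector("list", 0L)
  for (w in params$wmin:params$wmax) {
    for (l in params$lmin:params$lmax) {
      if (l > H || w > W) next
      r0s <- seq.int(0L, H - l, by = params$grid_stride)
      c0s <- seq.int(0L, W - w, by = params$grid_stride)
      grid <- expand.grid(r0 = r0s, c0 = c0s)
      r0 <- grid$r0; c0 <- grid$c0
      r1 <- r0 + l; c1 <- c0 + w
      a_in <- w * l
      s1_in <- boxsum(sat1, r0, r1, c0, c1)
      s2_in <- boxsum(sat2, r0, r1, c0, c1)
      o_r0 <- pmax(0L, r0 - cw); o_r1 <- pmin(H, r1 + cw)
      o_c0 <- pmax(0L, c0 - cw); o_c1 <- pmin(W, c1 + cw)
      a_out <- (o_r1 - o_r0) * (o_c1 - o_c0)
      s1_out <- boxsum(sat1, o_r0, o_r1, o_c0, o_c1)
      s2_out <- boxsum(sat2, o_r0, o_r1, o_c0, o_c1)
      a_cr <- a_out - a_in
      mu_in <- s1_in / a_in
      mu_cr <- (s1_out - s1_in) / a_cr
      v_in <- pmax(s2_in / a_in - mu_in^2, 0)
      v_cr <- pmax((s2_out - s2_in) / a_cr - mu_cr^2, 0)
      denom <- v_in + v_cr
      num <- (mu_in - mu_cr)^2
      x <- ifelse(denom > 0, num / denom,
                  ifelse(num <= .Machine$double.eps, 0, Inf))
      D <- quality(x, params$x0, params$quality_form)
      if (params$bright_only) D[mu_in <= mu_cr] <- 1
      keep <- a_cr > 0
      if (!is.null(roi_mask)) {
        rc <- r0 + l %/% 2L; cc <- c0 + w %/% 2L
        keep <- keep & roi_mask[cbind(rc + 1L, cc + 1L)]
      }
      out[[length(out) + 1L]] <- data.frame(
        row = (r0 + l %/% 2L)[keep], col = (c0 + w %/% 2L)[keep],
        w = w, l = l, D = D[keep])
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(row = integer(0), col = integer(0), w = integer(0),
                      l = integer(0), D = numeric(0))
  res
}

#' Greedy baseline configuration
#'
#' Sorts candidates by data term ascending and accepts each negative-energy
#' candidate that does not overlap an already accepted one. Serves as the
#' deterministic lower bar that the stochastic optimizer must never fall
#' below.
#'
#' @param candidates data frame `row, col, w, l, D` (e.g. from
#'   [score_candidates()]).
#' @return An `mpp_config` with attribute `energy`.
#' @export
greedy_baseline <- function(candidates) {
  cand <- candidates[candidates$D < 0, , drop = FALSE]
  cand <- cand[order(cand$D, cand$row, cand$col, cand$w, cand$l), ,
               drop = FALSE]
  sel <- integer(0)
  b <- rect_bounds(cand)
  for (i in seq_len(nrow(cand))) {
    if (length(sel) == 0L) { sel <- i; next }
    ov <- b$r0[i] < b$r1[sel] & b$r0[sel] < b$r1[i] &
      b$c0[i] < b$c1[sel] & b$c0[sel] < b$c1[i]
    if (!any(ov)) sel <- c(sel, i)
  }
  cfg <- order_config(cand[sel, c("row", "col", "w", "l", "D"), drop = FALSE])
  rownames(cfg) <- NULL
  class(cfg) <- c("mpp_config", "data.frame")
  attr(cfg, "energy") <- sum(cfg$D)
  cfg
}

#' Exhaustive energy minimization over a small candidate set
#'
#' Enumerates all admissible (non-overlapping) subsets of the candidates
#' and returns one with globally minimal energy; ties are broken by fewer
#' rectangles, then lexicographic rectangle order. Intended as the exact
#' oracle for the stochastic optimizer on small instances; the candidate
#' count is capped because enumeration is exponential.
#'
#' @param image numeric matrix.
#' @param candidates data frame of rectangles (`row, col, w, l`); data
#'   terms are computed if a `D` column is absent.
#' @param params an [mpp_params()] object.
#' @param cap maximum number of candidates (default 20).
#' @return An `mpp_config` with attribute `energy`.
#' @export
brute_force_minimize <- function(image, candidates, params = mpp_params(),
                                 cap = 20L) {
  if (nrow(candidates) > cap)
    stopf("candidate count %d exceeds the exhaustive-search cap %d",
          nrow(candidates), cap)
  if (is.null(candidates$D))
    candidates$D <- vapply(seq_len(nrow(candidates)), function(i)
      rectangle_energy(image, candidates[i, , drop = FALSE], params),
      numeric(1))
  # only negative data terms can be part of a minimal configuration
  # (dropping a non-negative rectangle never increases the energy, and the
  # fewer-rectangles tie-break removes zero-energy ones)
  cand <- candidates[candidates$D < 0, , drop = FALSE]
  rownames(cand) <- NULL
  n <- nrow(cand)
  best_cfg <- rectangles()
  best_cfg$D <- numeric(0)
  best_e <- 0
  if (n > 0L) {
    ov <- overlap_matrix(cand)
    sel <- logical(n)
    recurse <- function(i, energy) {
      if (i > n) {
        if (energy < best_e - 1e-12 ||
            (abs(energy - best_e) <= 1e-12 && {
              cur <- order_config(cand[sel, , drop = FALSE])
              (nrow(cur) < nrow(best_cfg)) ||
                (nrow(cur) == nrow(best_cfg) &&
                   compare_config(cur, best_cfg) < 0)
            })) {
          best_cfg <<- order_config(cand[sel, , drop = FALSE])
          best_e <<- energy
        }
        return(invisible())
      }
      # include i if admissible
      if (!any(sel & ov[i, ])) {
        sel[i] <<- TRUE
        recurse(i + 1L, energy + cand$D[i])
        sel[i] <<- FALSE
      }
      recurse(i + 1L, energy)
    }
    recurse(1L, 0)
  }
  cfg <- best_cfg[, intersect(c("row", "col", "w", "l", "D"),
                              names(best_cfg)), drop = FALSE]
  rownames(cfg) <- NULL
  class(cfg) <- c("mpp_config", "data.frame")
  attr(cfg, "energy") <- best_e
  cfg
}

#' Stochastic energy minimization (multiple births and deaths)
#'
#' Minimizes the configuration energy with a seeded birth-and-death sampler
#' under geometric annealing: each iteration proposes either the death of a
#' current rectangle or the birth of a grid candidate with eviction of the
#' rectangles it overlaps, accepting energy-increasing moves with Boltzmann
#' probability. The chain starts from the greedy baseline and the
#' best-so-far configuration is returned, so the result is never worse than
#' the baseline.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param params an [mpp_params()] object (its `seed` drives the sampler).
#' @param roi_mask optional logical matrix restricting candidate centers.
#' @param candidates optional pre-scored candidate data frame
#'   (`row, col, w, l, D`); scored from the grid when omitted.
#' @return An `mpp_config` with attributes `energy` and `greedy_energy`.
#' @export
minimize_energy <- function(image, params = mpp_params(), roi_mask = NULL,
                            candidates = NULL) {
  if (is.null(candidates))
    candidates <- score_candidates(image, params, roi_mask)
  neg <- candidates[candidates$D < 0, , drop = FALSE]
  if (nrow(neg) > params$max_candidates) {
    neg <- neg[order(neg$D), , drop = FALSE]
    neg <- neg[seq_len(params$max_candidates), , drop = FALSE]
  }
  rownames(neg) <- NULL
  greedy <- greedy_baseline(neg)
  g_e <- attr(greedy, "energy")
  n <- nrow(neg)
  if (n == 0L) {
    attr(greedy, "greedy_energy") <- g_e
    return(greedy)
  }
  b <- rect_bounds(neg)
  # membership of the greedy config among candidates (exact match on marks)
  key <- paste(neg$row, neg$col, neg$w, neg$l)
  cur <- match(paste(greedy$row, greedy$col, greedy$w, greedy$l), key)
  cur_e <- g_e
  best <- cur; best_e <- cur_e
  opt <- params$optimizer
  n_iter <- opt$max_iter
  temp <- opt$t0
  cool <- (opt$t_end / opt$t0)^(1 / max(1, n_iter))
  since_best <- 0L
  with_seed(params$seed, {
    for (it in seq_len(n_iter)) {
      k <- sample.int(n, 1L)
      if (k %in% cur) {
        d_e <- -neg$D[k]
        if (d_e <= 0 || runif(1) < exp(-d_e / temp)) {
          cur <- setdiff(cur, k)
          cur_e <- cur_e + d_e
        }
      } else {
        ov <- cur[b$r0[k] < b$r1[cur] & b$r0[cur] < b$r1[k] &
                    b$c0[k] < b$c1[cur] & b$c0[cur] < b$c1[k]]
        d_e <- neg$D[k] - sum(neg$D[ov])
        if (d_e <= 0 || runif(1) < exp(-d_e / temp)) {
          cur <- c(setdiff(cur, ov), k)
          cur_e <- cur_e + d_e
        }
      }
      if (cur_e < best_e - 1e-12) {
        best <- cur; best_e <- cur_e; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= opt$conv_window) break
      }
      temp <- temp * cool
    }
  })
  cfg <- order_config(neg[best, c("row", "col", "w", "l", "D"),
                          drop = FALSE])
  rownames(cfg) <- NULL
  class(cfg) <- c("mpp_config", "data.frame")
  attr(cfg, "energy") <- best_e
  attr(cfg, "greedy_energy") <- g_e
  cfg
}

#' Detect particles in one B-scan
#'
#' Runs [minimize_energy()] with candidate centers restricted to a region
#' of interest (typically the vitreous, above the retina surface) and
#' returns both the fitted configuration and its rasterized binary mask.
#'
#' @inheritParams minimize_energy
#' @return List with elements `config` (an `mpp_config`) and `mask`
#'   (logical matrix of the union of rectangle footprints).
#' @export
detect_slice <- function(image, params = mpp_params(), roi_mask = NULL) {
  if (!is.null(roi_mask)) {
    if (!identical(dim(roi_mask), dim(image)))
      stopf("`roi_mask` shape does not match the image")
    if (!any(roi_mask)) {
      cfg <- rectangles(); cfg$D <- numeric(0)
      attr(cfg, "energy") <- 0
      return(list(config = cfg,
                  mask = matrix(FALSE, nrow(image), ncol(image))))
    }
  }
  cfg <- minimize_energy(image, params, roi_mask)
  list(config = cfg, mask = rasterize_config(cfg, dim(image)))
}

#' Rasterize a rectangle configuration to a binary mask
#'
#' @param config an `mpp_config`.
#' @param dims `c(H, W)` output mask shape.
#' @return Logical matrix.
#' @export
rasterize_config <- function(config, dims) {
  mask <- matrix(FALSE, dims[1], dims[2])
  if (nrow(config) == 0L) return(mask)
  bb <- rect_bounds(config)
  for (i in seq_len(nrow(config)))
    mask[(bb$r0[i] + 1L):bb$r1[i], (bb$c0[i] + 1L):bb$c1[i]] <- TRUE
  mask
}

#' @export
print.mpp_config <- function(x, ...) {
  cat(sprintf("MPP configuration: %d rectangle(s), energy %.4f\n",
              nrow(x), attr(x, "energy") %||% NA_real_))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}
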