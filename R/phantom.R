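#' Particle specification for the OCT phantom
#'
#' Describes the bright vitreous particles planted in a synthetic volume.
#' Particles are rendered as axis-aligned bright boxes spanning a contiguous
#' range of slices, so the vertical-rectangle model of the MPP detector is
#' exactly recoverable from the ground truth.
#'
#' @param n_particles number of particles to plant (>= 0).
#' @param width_range integer `c(min, max)` lateral extent in px.
#' @param length_range integer `c(min, max)` axial (row) extent in px.
#' @param depth_range integer `c(min, max)` extent in slices.
#' @param intensity particle intensity in `[0, 1]` before speckle; must
#'   exceed the vitreous background level of the phantom.
#' @param placement `"csr"` for uniform placement in the vitreous or
#'   `"thomas"` for a clustered (Poisson parents, Gaussian offspring)
#'   placement.
#' @param thomas_params list with `n_parents`, `mean_offspring` and
#'   `cluster_sd` (px), used when `placement = "thomas"`. Under Thomas
#'   placement `n_particles` is ignored; the realized count is random.
#' @return An object of class `particle_spec`.
#' @export
particle_spec <- function(n_particles = 15L,
                          width_range = c(3L, 6L),
                          length_range = c(4L, 8L),
                          depth_range = c(2L, 4L),
                          intensity = 0.9,
                          placement = c("csr", "thomas"),
                          thomas_params = list(n_parents = 4L,
                                               mean_offspring = 5,
                                               cluster_sd = 12)) {
  placement <- match.arg(placement)
  if (n_particles < 0) stopf("`n_particles` must be >= 0")
  for (rg in list(width_range, length_range, depth_range)) {
    if (length(rg) != 2L || rg[1] > rg[2] || rg[1] < 1)
      stopf("size ranges must be ordered pairs of positive integers")
  }
  assert_scalar_num(intensity, "intensity", lower = 0, upper = 1)
  structure(list(n_particles = as.integer(n_particles),
                 width_range = as.integer(width_range),
                 length_range = as.integer(length_range),
                 depth_range = as.integer(depth_range),
                 intensity = intensity,
                 placement = placement,
                 thomas_params = thomas_params),
            class = "particle_spec")
}

#' Parameters of the synthetic OCT phantom
#'
#' The phantom emulates the geometry of a murine retinal OCT volume: a
#' bright, smoothly curved retina band over a dark vitreous, small bright
#' particles placed strictly above the retina surface, and multiplicative
#' gamma speckle (mean 1) applied after the geometry is rendered. Defaults
#' describe a compact volume sized for routine analysis and testing; the
#' slice geometry (curved band, vitreous above) mirrors real B-scans.
#'
#' @param height_px,width_px,n_slices volume dimensions (>= 1).
#' @param surface_profile list of smooth-curve parameters, all in px:
#'   `baseline_row` (mean surface depth), `poly_amp` (amplitude of a
#'   centered parabola across the B-scan), `sine_amp` and `sine_cycles`
#'   (lateral sine modulation), `z_tilt` (linear drift across slices).
#'   Missing entries take defaults proportional to `height_px`.
#' @param retina_thickness_px thickness of the bright retina band.
#' @param background_level vitreous intensity in `[0, 1]` before speckle.
#' @param retina_level retina band intensity; must exceed
#'   `background_level`.
#' @param speckle_shape shape of the mean-1 multiplicative gamma speckle
#'   (larger = less noisy); must be > 0.
#' @param particles a [particle_spec()].
#' @param seed integer RNG seed; the phantom is bit-reproducible per seed.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(height_px = 256L, width_px = 256L, n_slices = 16L,
                           surface_profile = list(),
                           retina_thickness_px = 48L,
                           background_level = 0.08,
                           retina_level = 0.7,
                           speckle_shape = 6,
                           particles = particle_spec(),
                           seed = 1L) {
  assert_scalar_num(height_px, "height_px", lower = 1)
  assert_scalar_num(width_px, "width_px", lower = 1)
  assert_scalar_num(n_slices, "n_slices", lower = 1)
  assert_scalar_num(background_level, "background_level", lower = 0, upper = 1)
  assert_scalar_num(retina_level, "retina_level", lower = 0, upper = 1)
  if (retina_level <= background_level)
    stopf("`retina_level` must exceed `background_level`")
  assert_scalar_num(speckle_shape, "speckle_shape", lower = 0,
                    strict_lower = TRUE)
  stopifnot(inherits(particles, "particle_spec"))
  h <- as.integer(height_px)
  prof <- list(baseline_row = round(0.60 * h),
               poly_amp = round(0.08 * h),
               sine_amp = round(0.03 * h),
               sine_cycles = 1,
               z_tilt = round(0.04 * h))
  prof[names(surface_profile)] <- surface_profile
  structure(list(height_px = h, width_px = as.integer(width_px),
                 n_slices = as.integer(n_slices),
                 surface_profile = prof,
                 retina_thickness_px = as.integer(retina_thickness_px),
                 background_level = background_level,
                 retina_level = retina_level,
                 speckle_shape = speckle_shape,
                 particles = particles,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Ground-truth surface rows (0-based, one per column) for one slice.
phantom_surface_rows <- function(params, slice) {
  p <- params$surface_profile
  w <- params$width_px
  u <- if (w > 1) (seq_len(w) - 1) / (w - 1) else 0.5
  zfrac <- if (params$n_slices > 1) (slice - 1) / (params$n_slices - 1) else 0.5
  rows <- p$baseline_row +
    p$poly_amp * (2 * u - 1)^2 +
    p$sine_amp * sin(2 * pi * p$sine_cycles * u) +
    p$z_tilt * (zfrac - 0.5)
  pmin(pmax(rows, 1), params$height_px - 2)
}

# Sample one axis-aligned particle box. Returns NULL if the candidate does
# not fit above the surface with the required clearance.
try_place_box <- function(params, center_cx = NULL, center_z = NULL,
                          center_ry = NULL, min_gap = 3L) {
  spec <- params$particles
  w <- sample(spec$width_range[1]:spec$width_range[2], 1L)
  l <- sample(spec$length_range[1]:spec$length_range[2], 1L)
  dp <- sample(spec$depth_range[1]:spec$depth_range[2], 1L)
  if (dp > params$n_slices) return(NULL)
  W <- params$width_px
  if (is.null(center_cx)) {
    c0 <- sample.int(W - w + 1L, 1L) - 1L           # 0-based col of footprint
  } else {
    c0 <- as.integer(round(center_cx)) - w %/% 2L
    if (c0 < 0L || c0 + w > W) return(NULL)
  }
  if (is.null(center_z)) {
    s0 <- sample.int(params$n_slices - dp + 1L, 1L)  # 1-based first slice
  } else {
    s0 <- as.integer(round(center_z)) + 1L - dp %/% 2L
    if (s0 < 1L || s0 + dp - 1L > params$n_slices) return(NULL)
  }
  # vitreous ceiling over the lateral/slice extent of the box
  min_surf <- Inf
  for (s in s0:(s0 + dp - 1L)) {
    rows <- phantom_surface_rows(params, s)
    min_surf <- min(min_surf, rows[(c0 + 1L):(c0 + w)])
  }
  top_max <- floor(min_surf) - min_gap - l   # highest allowed 0-based row0
  if (top_max < 2L) return(NULL)
  if (is.null(center_ry)) {
    r0 <- sample.int(top_max - 1L, 1L) + 1L  # 0-based row0 in [2, top_max]
  } else {
    r0 <- as.integer(round(center_ry)) - l %/% 2L
    if (r0 < 2L || r0 > top_max) return(NULL)
  }
  list(r0 = r0, c0 = c0, w = w, l = l, s0 = s0, dp = dp)
}

boxes_separated <- function(b, boxes, sep = 2L) {
  for (o in boxes) {
    if (b$r0 < o$r0 + o$l + sep && o$r0 < b$r0 + b$l + sep &&
        b$c0 < o$c0 + o$w + sep && o$c0 < b$c0 + b$w + sep &&
        b$s0 < o$s0 + o$dp + 1L && o$s0 < b$s0 + b$dp + 1L)
      return(FALSE)
  }
  TRUE
}

#' Generate a synthetic OCT phantom volume with ground truth
#'
#' Renders the retina band and planted particles, then applies
#' multiplicative mean-1 gamma speckle and clips to `[0, 1]`. Placement is
#' by rejection sampling with a retry cap; an error naming the non-overlap
#' constraint is raised if the requested particles cannot be placed.
#'
#' @param params a [phantom_params()] object.
#' @param max_tries rejection-sampling retry cap per particle.
#' @return An object of class `oct_phantom`: a list with elements
#'   `volume` (`H x W x S` array in `[0, 1]`), `params`, `gt_surface`
#'   (`W x S` matrix of 0-based surface rows per column and slice),
#'   `gt_particle_mask` (logical `H x W x S` array), `gt_centroids`
#'   (data frame `z, y, x, label`, 0-based voxel-center coordinates) and
#'   `gt_rectangles` (data frame `slice, row, col, w, l, label`, 0-based,
#'   one row per particle and occupied slice).
#' @examples
#' ph <- generate_phantom(phantom_params(n_slices = 4L, seed = 7L,
#'   particles = particle_spec(n_particles = 5L)))
#' dim(ph$volume)
#' nrow(ph$gt_centroids)
#' @export
generate_phantom <- function(params, max_tries = 1000L) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(params$seed, {
    H <- params$height_px; W <- params$width_px; S <- params$n_slices
    spec <- params$particles

    boxes <- list()
    if (spec$placement == "csr") {
      if (spec$n_particles > 0) {
        for (i in seq_len(spec$n_particles)) {
          placed <- FALSE
          for (t in seq_len(max_tries)) {
            b <- try_place_box(params)
            if (!is.null(b) && boxes_separated(b, boxes)) {
              boxes[[length(boxes) + 1L]] <- b
              placed <- TRUE
              break
            }
          }
          if (!placed)
            stopf(paste("could not place %d non-overlapping particles above",
                        "the retina surface within %d tries per particle",
                        "(non-overlap / vitreous-clearance constraint)"),
                  spec$n_particles, max_tries)
        }
      }
    } else {
      tp <- spec$thomas_params
      n_par <- tp$n_parents
      parents <- lapply(seq_len(n_par), function(i) {
        s <- sample.int(S, 1L)
        rows <- phantom_surface_rows(params, s)
        cx <- runif(1, 0, W - 1)
        ceiling_row <- min(rows[max(1, floor(cx)):min(W, ceiling(cx) + 1)])
        list(z = s - 1, x = cx, y = runif(1, 4, max(5, ceiling_row - 12)))
      })
      for (p in parents) {
        n_off <- rpois(1L, tp$mean_offspring)
        for (k in seq_len(n_off)) {
          for (t in seq_len(max_tries %/% 10L)) {
            cx <- p$x + rnorm(1, 0, tp$cluster_sd)
            cz <- p$z + rnorm(1, 0, tp$cluster_sd / 4)
            cy <- p$y + rnorm(1, 0, tp$cluster_sd)
            b <- try_place_box(params, center_cx = cx, center_z = cz,
                               center_ry = cy)
            if (!is.null(b) && boxes_separated(b, boxes)) {
              boxes[[length(boxes) + 1L]] <- b
              break
            }
          }
          # offspring that cannot be placed (outside the volume or onto
          # occupied space) are dropped: the realized count is random
          # under Thomas placement
        }
      }
    }

    vol <- array(params$background_level, dim = c(H, W, S))
    gt_surface <- matrix(0, W, S)
    mask <- array(FALSE, dim = c(H, W, S))
    for (s in seq_len(S)) {
      rows <- phantom_surface_rows(params, s)
      gt_surface[, s] <- rows
      top <- as.integer(floor(rows)) + 1L  # 1-based first retina row
      bot <- pmin(top + params$retina_thickness_px - 1L, H)
      for (c in seq_len(W)) vol[top[c]:bot[c], c, s] <- params$retina_level
    }
    for (b in boxes) {
      rr <- (b$r0 + 1L):(b$r0 + b$l)
      cc <- (b$c0 + 1L):(b$c0 + b$w)
      ss <- b$s0:(b$s0 + b$dp - 1L)
      vol[rr, cc, ss] <- spec$intensity
      mask[rr, cc, ss] <- TRUE
    }

    speckle <- array(rgamma(length(vol), shape = params$speckle_shape,
                            rate = params$speckle_shape), dim = dim(vol))
    vol <- pmin(vol * speckle, 1)

    if (length(boxes)) {
      cent <- do.call(rbind, lapply(seq_along(boxes), function(i) {
        b <- boxes[[i]]
        data.frame(z = b$s0 - 1 + (b$dp - 1) / 2,
                   y = b$r0 + (b$l - 1) / 2,
                   x = b$c0 + (b$w - 1) / 2,
                   label = i)
      }))
      rects <- do.call(rbind, lapply(seq_along(boxes), function(i) {
        b <- boxes[[i]]
        data.frame(slice = (b$s0:(b$s0 + b$dp - 1L)) - 1L,
                   row = b$r0 + b$l %/% 2L,
                   col = b$c0 + b$w %/% 2L,
                   w = b$w, l = b$l, label = i)
      }))
    } else {
      cent <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                         label = integer(0))
      rects <- data.frame(slice = integer(0), row = integer(0),
                          col = integer(0), w = integer(0), l = integer(0),
                          label = integer(0))
    }

    structure(list(volume = vol, params = params, gt_surface = gt_surface,
                   gt_particle_mask = mask, gt_centroids = cent,
                   gt_rectangles = rects),
              class = "oct_phantom")
  })
}

#' @export
print.oct_phantom <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("OCT phantom: %d x %d px, %d slices, %d planted particles\n",
              d[1], d[2], d[3], nrow(x$gt_centroids)))
  invisible(x)
}

#' Simulate a 3-D point pattern in a spherical study window
#'
#' Complete spatial randomness (`csr`) draws points i.i.d. uniformly in the
#' window volume. The Thomas process (`thomas`) draws parents uniformly in
#' the window, a Poisson(`mean_offspring`) number of offspring per parent
#' displaced isotropically with standard deviation `cluster_sd`, and
#' discards offspring falling outside the window.
#'
#' @param kind `"csr"` or `"thomas"`.
#' @param n_or_params for `csr`, the number of points (>= 0); for `thomas`,
#'   a list with `n_parents`, `mean_offspring`, `cluster_sd`.
#' @param window a [study_window()].
#' @param seed integer RNG seed.
#' @return A `point_pattern3d` (data frame with columns `z, y, x`).
#' @examples
#' w <- study_window(center = c(0, 0, 0), radius = 70)
#' pp <- simulate_point_pattern("csr", 100, w, seed = 1)
#' nrow(pp)
#' @export
simulate_point_pattern <- function(kind = c("csr", "thomas"), n_or_params,
                                   window, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(window, "study_window"))
  with_seed(seed, {
    if (kind == "csr") {
      n <- n_or_params
      if (!is.numeric(n) || length(n) != 1L || n < 0)
        stopf("`n_or_params` must be a count >= 0 for csr")
      pts <- runif_sphere(as.integer(n), window)
    } else {
      p <- n_or_params
      if (!is.list(p) || is.null(p$n_parents) || is.null(p$mean_offspring) ||
          is.null(p$cluster_sd))
        stopf("thomas parameters need `n_parents`, `mean_offspring`, `cluster_sd`")
      parents <- runif_sphere(as.integer(p$n_parents), window)
      kids <- lapply(seq_len(nrow(parents)), function(i) {
        m <- rpois(1L, p$mean_offspring)
        if (m == 0L) return(NULL)
        sweep(matrix(rnorm(3L * m, sd = p$cluster_sd), ncol = 3L), 2L,
              as.numeric(parents[i, ]), `+`)
      })
      pts <- do.call(rbind, kids)
      if (is.null(pts)) pts <- matrix(numeric(0), ncol = 3L)
      d <- sqrt(colSums((t(pts) - window$center)^2))
      pts <- pts[d <= window$radius, , drop = FALSE]
    }
    point_pattern3d(pts)
  })
}

# n uniform points in the spherical window, as an n x 3 matrix (z, y, x)
runif_sphere <- function(n, window) {
  if (n == 0L) return(matrix(numeric(0), ncol = 3L))
  dir <- matrix(rnorm(3L * n), ncol = 3L)
  dir <- dir / sqrt(rowSums(dir^2))
  rad <- window$radius * runif(n)^(1 / 3)
  sweep(dir * rad, 2L, window$center, `+`)
}
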