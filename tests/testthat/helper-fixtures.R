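# Shared fixtures, built in code at test time.

# small phantom sized for fast pipeline tests
small_phantom_params <- function(seed = 1L, n_particles = 6L,
                                 placement = "csr") {
  phantom_params(height_px = 128L, width_px = 128L, n_slices = 6L,
                 retina_thickness_px = 24L,
                 particles = particle_spec(n_particles = n_particles,
                                           placement = placement),
                 seed = seed)
}

# vitreous ROI from the ground-truth surface of a phantom slice
gt_roi <- function(ph, slice, margin = 2L) {
  d <- dim(ph$volume)
  roi <- matrix(FALSE, d[1], d[2])
  for (c in seq_len(d[2])) {
    top <- floor(ph$gt_surface[c, slice]) - margin
    if (top >= 1) roi[seq_len(min(top, d[1])), c] <- TRUE
  }
  roi
}

# image with a 2x2 interior (mean 11, population variance 1) and a
# 12-pixel crown (mean 5, population variance 4): contrast statistic
# x = 36 / 5 = 7.2
contrast_fixture <- function(background = 5) {
  img <- matrix(background, 8, 8)
  img[3:6, 3:6] <- rep(c(3, 7), 8)        # ring values, overwritten inside
  img[4:5, 4:5] <- c(10, 10, 12, 12)      # interior
  ring <- img[3:6, 3:6]
  ring_vals <- ring[-c(6, 7, 10, 11)]     # the 12 crown pixels
  stopifnot(mean(ring_vals) == 5, mean((ring_vals - 5)^2) == 4)
  img
}

# seeded 64x64 MPP instance with 12 hand-listed candidates: for each of
# four planted blobs two overlapping size-matched rectangles (a genuine
# subset-selection problem), plus four noise rectangles
mpp_small_instance <- function(sd) {
  set.seed(sd)
  img <- matrix(runif(64 * 64, 0, 0.15), 64, 64)
  centers <- list()
  for (k in 1:4) {
    r <- 8 + 14 * ((k - 1) %% 2) + sample(0:6, 1)
    c <- 8 + 18 * ((k - 1) %/% 2) + sample(0:6, 1)
    img[(r - 1):(r + 2), (c - 1):(c + 1)] <- runif(1, 0.6, 0.9)
    centers[[k]] <- c(r, c)
  }
  cand <- do.call(rbind, lapply(centers, function(rc)
    data.frame(row = rc[1] - 1L + c(0L, 1L), col = rc[2] - 1L,
               w = 3L, l = 4L)))
  cand <- rbind(cand,
                data.frame(row = c(40L, 50L, 55L, 45L),
                           col = c(40L, 50L, 20L, 10L), w = 3L, l = 4L))
  params <- mpp_params(wmin = 3L, wmax = 3L, lmin = 4L, lmax = 4L, seed = sd)
  list(img = img, cand = cand, params = params)
}

# independent plain-loop K estimator used as a summation oracle
ripley_reference <- function(pts, window, radii) {
  n <- nrow(pts)
  vol <- 4 / 3 * pi * window$radius^3
  k <- numeric(length(radii))
  for (a in seq_along(radii)) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
        if (d <= radii[a])
          acc <- acc + 1 / cap_fraction(pts[i, ], d, window)
      }
    }
    k[a] <- vol / (n * (n - 1)) * acc
  }
  k
}
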