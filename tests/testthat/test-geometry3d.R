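# 3-D reconstruction: stacking, labeling, filtering, centroids, distances.

test_that("mask stacking preserves order and voxel counts", {
  empty <- matrix(FALSE, 8, 8)
  v0 <- stack_masks(list(empty, empty, empty))
  expect_identical(sum(v0), 0L)

  m1 <- empty; m1[1:5, 1] <- TRUE
  m3 <- empty; m3[2, 1:7] <- TRUE
  v <- stack_masks(list(m1, empty, m3))
  expect_identical(sum(v), 12L)
  expect_identical(v[, , 1], m1)
  expect_identical(v[, , 3], m3)
  expect_error(stack_masks(list(m1, matrix(FALSE, 4, 4))), "shape")

  ph <- generate_phantom(small_phantom_params(seed = 8L))
  slices <- lapply(seq_len(dim(ph$volume)[3]),
                   function(s) ph$gt_particle_mask[, , s])
  expect_identical(stack_masks(slices)[, , ],
                   ph$gt_particle_mask[, , ])
})

test_that("labeling respects connectivity and raster order", {
  v <- array(FALSE, dim = c(4, 4, 1))
  expect_identical(attr(label_components(v), "n_labels"), 0L)

  diag2 <- array(FALSE, dim = c(4, 4, 2))
  diag2[2, 2, 1] <- TRUE
  diag2[3, 3, 2] <- TRUE    # touches only corner-diagonally across slices
  expect_identical(attr(label_components(diag2, 26L), "n_labels"), 1L)
  expect_identical(attr(label_components(diag2, 6L), "n_labels"), 2L)

  # deterministic raster-order labels
  two <- array(FALSE, dim = c(5, 5, 1))
  two[1, 1, 1] <- TRUE
  two[5, 5, 1] <- TRUE
  lab <- label_components(two)
  expect_identical(lab[1, 1, 1], 1L)
  expect_identical(lab[5, 5, 1], 2L)
})

test_that("slice-extent filtering removes single-slice speckle exactly", {
  ph <- generate_phantom(phantom_params(
    seed = 77L, particles = particle_spec(n_particles = 15L,
                                          depth_range = c(2L, 4L))))
  vol <- ph$gt_particle_mask
  # plant 20 single-voxel single-slice speckles in free vitreous space
  set.seed(99)
  planted <- 0L
  while (planted < 20L) {
    r <- sample(3:60, 1); c <- sample(2:255, 1); s <- sample(1:16, 1)
    rr <- max(1, r - 2):min(128, r + 2)
    cc <- max(1, c - 2):min(256, c + 2)
    if (!any(vol[rr, cc, max(1, s - 1):min(16, s + 1)])) {
      vol[r, c, s] <- TRUE
      planted <- planted + 1L
    }
  }
  lab <- label_components(vol, 26L)
  expect_identical(attr(lab, "n_labels"), 35L)
  filt <- filter_particles(lab, min_slices = 2L)
  expect_identical(attr(filt, "n_labels"), 15L)
  # min_slices = 1 with no boxes is the identity on labels
  expect_identical(attr(filter_particles(lab, min_slices = 1L), "n_labels"),
                   35L)
})

test_that("box gating keeps only particles with a voxel inside a box", {
  ph <- generate_phantom(small_phantom_params(seed = 13L))
  lab <- label_components(ph$gt_particle_mask)
  n_all <- attr(lab, "n_labels")
  # boxes covering the left half of every slice
  boxes <- data.frame(slice = 0:5, y0 = 0L, x0 = 0L, y1 = 128L, x1 = 64L)
  filt <- filter_particles(lab, min_slices = 1L, boxes = boxes)
  left <- sum(ph$gt_centroids$x < 64 - max(ph$params$particles$width_range))
  right <- sum(ph$gt_centroids$x > 64 + max(ph$params$particles$width_range))
  expect_lte(attr(filt, "n_labels"), n_all - right)
  expect_gte(attr(filt, "n_labels"), left)
})

test_that("particle summaries report counts, extents and centroids", {
  v <- array(FALSE, dim = c(30, 30, 6))
  v[11, 21, 4] <- TRUE                 # 0-based (z, y, x) = (3, 10, 20)
  v[1:2, 1:2, 1:2] <- TRUE             # 2x2x2 cube at the origin
  tab <- particle_summaries(label_components(v))
  cube <- tab[tab$voxel_count == 8, ]
  expect_equal(unlist(cube[, c("z", "y", "x")]),
               c(z = 0.5, y = 0.5, x = 0.5))
  expect_identical(cube$slice_extent, 2L)
  single <- tab[tab$voxel_count == 1, ]
  expect_equal(unlist(single[, c("z", "y", "x")]), c(z = 3, y = 10, x = 20))

  ph <- generate_phantom(small_phantom_params(seed = 17L))
  gt <- ph$gt_centroids
  got <- particle_summaries(label_components(ph$gt_particle_mask))
  sc <- match_centers(got[, c("z", "y", "x")], gt[, c("z", "y", "x")],
                      tol = 0.5)
  expect_identical(sc$tp, nrow(gt))
})

test_that("distance map matches brute force and slab geometry", {
  adj <- array(FALSE, dim = c(5, 5, 5))
  adj[3, 3, 3] <- TRUE
  dm <- distance_map(adj)
  expect_identical(dm[3, 3, 3], 0)
  expect_identical(dm[2, 3, 3], 1)
  expect_equal(dm[2, 2, 3], sqrt(2))

  slab <- array(FALSE, dim = c(128, 16, 3))
  slab[101:128, , ] <- TRUE
  dms <- distance_map(slab)
  expect_identical(dms[61, 8, 2], 40)   # 0-based row 60, slab starts at 100

  set.seed(5)
  for (t in 1:6) {
    m <- array(runif(16^3) < 0.03, dim = c(16, 16, 16))
    if (!any(m)) next
    dm <- distance_map(m)
    idx <- which(m, arr.ind = TRUE)
    probes <- arrayInd(sample(16^3, 40), c(16, 16, 16))
    for (k in seq_len(nrow(probes))) {
      p <- probes[k, ]
      bf <- min((idx[, 1] - p[1])^2 + (idx[, 2] - p[2])^2 +
                  (idx[, 3] - p[3])^2)
      expect_equal(dm[p[1], p[2], p[3]]^2, bf, tolerance = 1e-9)
    }
  }
  expect_error(distance_map(array(FALSE, dim = c(4, 4, 4))), "empty")
})

test_that("anisotropic spacing scales distances", {
  m <- array(FALSE, dim = c(8, 8, 8))
  m[4, 4, 4] <- TRUE
  dm <- distance_map(m, spacing = c(2, 1, 1))  # (dz, dy, dx)
  expect_identical(dm[4, 4, 5], 2)   # one step in z costs 2
  expect_identical(dm[5, 4, 4], 1)   # one step in y costs 1
})

test_that("particle distances sample the map at centroids", {
  slab <- array(FALSE, dim = c(128, 16, 4))
  slab[101:128, , ] <- TRUE
  dm <- distance_map(slab)
  parts <- data.frame(label = 1:2, voxel_count = c(8L, 8L),
                      slice_extent = c(2L, 2L),
                      z = c(1, 2), y = c(60.5, 100), x = c(8, 8))
  out <- particle_distances(parts, dm)
  expect_equal(out$distance_to_surface[1], 100 - 60.5, tolerance = 1)
  expect_equal(out$distance_to_surface[2], 0)
  expect_identical(out$label, parts$label)

  empty <- parts[0, ]
  expect_identical(nrow(particle_distances(empty, dm)), 0L)
  oob <- parts
  oob$y <- c(300, 100)
  expect_error(particle_distances(oob, dm), "bounds")
})
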