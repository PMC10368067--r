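# 3-D particle reconstruction: stacking per-slice masks, connected
# component labeling, shape filtering, centroid extraction, and
# particle-to-surface distances via a Euclidean distance transform.

#' Stack per-slice binary masks into a 3-D volume
#'
#' @param masks list of logical matrices, all the same shape, in slice
#'   order.
#' @param spacing voxel size `c(dz, dy, dx)` (default 1 px each).
#' @return Logical `H x W x S` array with attribute `spacing`.
#' @export
stack_masks <- function(masks, spacing = c(1, 1, 1)) {
  if (!length(masks)) stopf("`masks` must be a non-empty list")
  d <- dim(masks[[1]])
  for (i in seq_along(masks)) {
    if (!identical(dim(masks[[i]]), d))
      stopf("mask %d has shape %s, expected %s", i,
            paste(dim(masks[[i]]), collapse = "x"),
            paste(d, collapse = "x"))
  }
  vol <- array(FALSE, dim = c(d, length(masks)))
  for (i in seq_along(masks)) vol[, , i] <- as.logical(masks[[i]])
  attr(vol, "spacing") <- as.numeric(spacing)
  vol
}

#' Label 3-D connected components
#'
#' Deterministic labeling (labels follow the raster order of each
#' component's first voxel) under 6- (faces) or 26- (faces, edges,
#' corners) connectivity.
#'
#' @param volume logical 3-D array (a 2-D matrix is treated as one slice).
#' @param connectivity 6 or 26 (default 26, which merges diagonal
#'   contacts).
#' @return Integer array of the same shape with attribute `n_labels`
#'   (0 = background), of class `labeled_volume`.
#' @export
label_components <- function(volume, connectivity = 26L) {
  if (is.matrix(volume)) volume <- array(volume, dim = c(dim(volume), 1L))
  if (length(dim(volume)) != 3L) stopf("`volume` must be a 3-D array")
  lab <- .cc_label(as.logical(volume), dim(volume), as.integer(connectivity))
  out <- array(as.integer(lab), dim = dim(volume))
  attr(out, "n_labels") <- attr(lab, "n_labels")
  attr(out, "spacing") <- attr(volume, "spacing") %||% c(1, 1, 1)
  class(out) <- "labeled_volume"
  out
}

# per-label list of voxel array indices (r, c, s), in raster order
label_voxels <- function(labeled) {
  n <- attr(labeled, "n_labels")
  idx <- which(unclass(labeled) > 0L)
  if (!length(idx))
    return(list())
  labs <- unclass(labeled)[idx]
  d <- dim(labeled)
  s <- (idx - 1L) %/% (d[1] * d[2])
  rem <- (idx - 1L) %% (d[1] * d[2])
  c <- rem %/% d[1]
  r <- rem %% d[1]
  split(data.frame(r = r + 1L, c = c + 1L, s = s + 1L), labs)[as.character(seq_len(n))]
}

#' Filter labeled particles by slice extent and bounding boxes
#'
#' Removes labels occupying fewer than `min_slices` distinct slices
#' (single-slice detections are typically speckle or false positives given
#' the axial size of a real particle) and, when `boxes` is given, labels
#' with no voxel inside any box. Survivors are relabeled compactly,
#' preserving raster order.
#'
#' @param labeled a `labeled_volume` from [label_components()].
#' @param min_slices minimum number of distinct slices (>= 1).
#' @param boxes optional data frame `slice, y0, x0, y1, x1` (0-based,
#'   half-open) of per-slice gating boxes from any detector.
#' @return A filtered `labeled_volume`.
#' @export
filter_particles <- function(labeled, min_slices = 2L, boxes = NULL) {
  if (min_slices < 1) stopf("`min_slices` must be >= 1")
  vox <- label_voxels(labeled)
  keep <- vapply(vox, function(v) length(unique(v$s)) >= min_slices,
                 logical(1))
  if (!is.null(boxes) && nrow(boxes) > 0) {
    in_box <- vapply(vox, function(v) {
      for (i in seq_len(nrow(boxes))) {
        bx <- boxes[i, ]
        hit <- v$s - 1L == bx$slice &
          v$r - 1L >= bx$y0 & v$r - 1L < bx$y1 &
          v$c - 1L >= bx$x0 & v$c - 1L < bx$x1
        if (any(hit)) return(TRUE)
      }
      FALSE
    }, logical(1))
    keep <- keep & in_box
  }
  old <- unclass(labeled)
  out <- array(0L, dim = dim(old))
  new_id <- 0L
  for (lab in which(keep)) {
    new_id <- new_id + 1L
    v <- vox[[lab]]
    out[cbind(v$r, v$c, v$s)] <- new_id
  }
  attr(out, "n_labels") <- new_id
  attr(out, "spacing") <- attr(labeled, "spacing") %||% c(1, 1, 1)
  class(out) <- "labeled_volume"
  out
}

#' Summarize labeled particles
#'
#' One row per label with voxel count, slice extent, and the
#' arithmetic-mean centroid in 0-based `(z, y, x)` coordinates scaled by
#' the voxel spacing.
#'
#' @param labeled a `labeled_volume`.
#' @return Data frame `label, voxel_count, slice_extent, z, y, x` of class
#'   `particle_table`.
#' @export
particle_summaries <- function(labeled) {
  sp <- attr(labeled, "spacing") %||% c(1, 1, 1)
  vox <- label_voxels(labeled)
  out <- do.call(rbind, lapply(seq_along(vox), function(i) {
    v <- vox[[i]]
    data.frame(label = i,
               voxel_count = nrow(v),
               slice_extent = length(unique(v$s)),
               z = mean(v$s - 1) * sp[1],
               y = mean(v$r - 1) * sp[2],
               x = mean(v$c - 1) * sp[3])
  }))
  if (is.null(out))
    out <- data.frame(label = integer(0), voxel_count = integer(0),
                      slice_extent = integer(0), z = numeric(0),
                      y = numeric(0), x = numeric(0))
  class(out) <- c("particle_table", "data.frame")
  out
}

#' Euclidean distance map to a retina mask
#'
#' For every voxel, the Euclidean distance (respecting the voxel spacing)
#' to the nearest retina-mask voxel; 0 on the mask itself. Computed with
#' the separable lower-envelope distance transform, so exact in the
#' squared-distance sense.
#'
#' @param retina_mask logical 3-D array (non-empty); a matrix is treated
#'   as a single slice.
#' @param spacing voxel size `c(dz, dy, dx)`; defaults to the mask's
#'   `spacing` attribute or unit voxels.
#' @param squared return squared distances (exact in integer arithmetic at
#'   unit spacing) instead of distances.
#' @return Numeric array of distances with the same shape.
#' @export
distance_map <- function(retina_mask, spacing = NULL, squared = FALSE) {
  if (is.matrix(retina_mask))
    retina_mask <- array(retina_mask, dim = c(dim(retina_mask), 1L))
  if (!any(retina_mask)) stopf("`retina_mask` is empty")
  sp <- spacing %||% attr(retina_mask, "spacing") %||% c(1, 1, 1)
  d2 <- .edt_squared(as.logical(retina_mask), dim(retina_mask),
                     as.numeric(sp))
  out <- array(if (squared) d2 else sqrt(d2), dim = dim(retina_mask))
  attr(out, "spacing") <- as.numeric(sp)
  out
}

#' Sample particle-to-surface distances at centroids
#'
#' Appends a `distance_to_surface` column: the distance map sampled at
#' each centroid, by trilinear interpolation (default) or at the nearest
#' voxel. Centroids are 0-based voxel-center coordinates in the map's
#' voxel units.
#'
#' @param particles a `particle_table` from [particle_summaries()].
#' @param dmap distance volume from [distance_map()].
#' @param method `"trilinear"` or `"nearest"`.
#' @return The particle table with `distance_to_surface` added, input
#'   order preserved.
#' @export
particle_distances <- function(particles, dmap,
                               method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (nrow(particles) == 0L) {
    particles$distance_to_surface <- numeric(0)
    return(particles)
  }
  d <- dim(dmap)
  sp <- attr(dmap, "spacing") %||% c(1, 1, 1)
  # voxel-grid coordinates (0-based, continuous)
  gz <- particles$z / sp[1]; gy <- particles$y / sp[2]; gx <- particles$x / sp[3]
  if (any(gz < 0 | gz > d[3] - 1 | gy < 0 | gy > d[1] - 1 |
          gx < 0 | gx > d[2] - 1))
    stopf("centroid outside the distance-map bounds")
  out <- numeric(nrow(particles))
  for (i in seq_len(nrow(particles))) {
    if (method == "nearest") {
      out[i] <- dmap[round(gy[i]) + 1, round(gx[i]) + 1, round(gz[i]) + 1]
    } else {
      z0 <- floor(gz[i]); y0 <- floor(gy[i]); x0 <- floor(gx[i])
      z1 <- min(z0 + 1, d[3] - 1); y1 <- min(y0 + 1, d[1] - 1)
      x1 <- min(x0 + 1, d[2] - 1)
      fz <- gz[i] - z0; fy <- gy[i] - y0; fx <- gx[i] - x0
      v <- 0
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        wz <- if (dz == 0) 1 - fz else fz
        wy <- if (dy == 0) 1 - fy else fy
        wx <- if (dx == 0) 1 - fx else fx
        if (wz * wy * wx > 0) {
          zz <- if (dz == 0) z0 else z1
          yy <- if (dy == 0) y0 else y1
          xx <- if (dx == 0) x0 else x1
          v <- v + wz * wy * wx * dmap[yy + 1, xx + 1, zz + 1]
        }
      }
      out[i] <- v
    }
  }
  particles$distance_to_surface <- out
  particles
}
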