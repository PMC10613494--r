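#' Seed specification for region growing
#'
#' @param points n x 3 matrix (or length-3 vector) of world-space seed points
#'   in mm; at least one, each inside the target grid when used.
#' @param lower,upper Intensity window bounds, `lower <= upper`.
#' @param label Structure name for the resulting mask.
#' @return Object of class `seed_spec`.
#' @export
seed_spec <- function(points, lower, upper, label = "OTHER") {
  points <- as_points(points)
  if (nrow(points) < 1L) stop("at least one seed point is required")
  if (!is.finite(lower) || !is.finite(upper) || lower > upper)
    stop("`lower` must be <= `upper` and both finite")
  structure(list(points = points, lower = lower, upper = upper, label = label),
            class = "seed_spec")
}

#' Homomorphic bias-field correction
#'
#' Divides the volume by a heavily Gaussian-smoothed copy of itself (the
#' low-frequency bias estimate) and rescales so the overall mean is
#' preserved. This flattens the slow multiplicative shading that contrast
#' coils impose on angiography volumes, so that a single global intensity
#' window suffices for region growing. The smoothing scale is expressed in
#' world millimetres and should sit well above the chamber wall thickness and
#' well below the field of view.
#'
#' @param vol A [scalar_volume] with nonnegative values.
#' @param scale_mm Standard deviation of the Gaussian bias estimate in mm
#'   (default 25).
#' @return A corrected [scalar_volume]; an all-zero input is returned
#'   unchanged with a warning.
#' @export
bias_correct <- function(vol, scale_mm = 25) {
  if (!inherits(vol, "scalar_volume")) stop("`vol` must be a scalar_volume")
  if (any(vol$values < 0)) stop("bias correction expects nonnegative values")
  if (all(vol$values == 0)) {
    warning("all-zero volume: bias correction skipped")
    return(vol)
  }
  sigma_vox <- scale_mm / vol$grid$spacing
  smooth <- cpp_gauss_smooth(as.numeric(vol$values), vol$grid$shape, sigma_vox)
  eps <- 1e-6 * max(smooth)
  ratio <- as.numeric(vol$values) / pmax(smooth, eps)
  out <- ratio * mean(vol$values) / mean(ratio)
  scalar_volume(array(out, vol$grid$shape), vol$grid)
}

# Face-adjacency (6) or full-neighborhood (26) integer offsets.
connectivity_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ad <- rowSums(abs(off))
  if (connectivity == 6) off <- off[ad == 1, , drop = FALSE]
  else if (connectivity == 26) off <- off[ad > 0, , drop = FALSE]
  else stop("connectivity must be 6 or 26")
  storage.mode(off) <- "integer"
  off
}

# Offsets inside an ellipsoid with per-axis voxel radii (structuring element).
ball_offsets <- function(radius_vox) {
  r <- pmax(1L, as.integer(radius_vox))
  off <- as.matrix(expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3]))
  keep <- (off[, 1] / r[1])^2 + (off[, 2] / r[2])^2 + (off[, 3] / r[3])^2 <= 1
  off <- off[keep, , drop = FALSE]
  storage.mode(off) <- "integer"
  off
}

# 0-based voxel index of world points, rounded half away from zero; errors
# when a point falls outside the grid.
nearest_index <- function(grid, world, what = "point") {
  idx <- index_from_world(grid, world)
  r <- trunc(idx + 0.5 * sign(idx))
  bad <- r < 0 | r > matrix(grid$shape - 1, nrow(r), 3, byrow = TRUE)
  if (any(bad))
    stop(sprintf("%s %s lies outside the image grid", what,
                 paste(which(rowSums(bad) > 0), collapse = ", ")))
  storage.mode(r) <- "integer"
  r
}

#' Seeded region growing within an intensity window
#'
#' Breadth-first flood fill from the seed points through face-adjacent
#' (6-connected) voxels whose intensities all lie in the seed window — the
#' classic seed-and-grow segmentation of angiography volumes. Face adjacency
#' is used deliberately: it is conservative against leaks through diagonal
#' voxel corners between touching structures.
#'
#' @param vol A [scalar_volume] (typically bias-corrected CE-MRA).
#' @param seeds A [seed_spec]; every seed voxel's intensity must lie inside
#'   the window, otherwise a seed-rejection error names the offending seed.
#' @param connectivity Voxel adjacency for growth (6, the default, or 26).
#' @return A [binary_mask] labelled from the seed spec.
#' @export
region_grow <- function(vol, seeds, connectivity = 6) {
  if (!inherits(vol, "scalar_volume")) stop("`vol` must be a scalar_volume")
  if (!inherits(seeds, "seed_spec")) stop("`seeds` must be a seed_spec")
  idx <- nearest_index(vol$grid, seeds$points, "seed")
  lin0 <- idx[, 1] + vol$grid$shape[1] * (idx[, 2] + vol$grid$shape[2] * idx[, 3])
  iv <- vol$values[lin0 + 1]
  bad <- iv < seeds$lower | iv > seeds$upper
  if (any(bad))
    stop(sprintf(
      "seed %s rejected: intensity %s outside window [%g, %g]",
      paste(which(bad), collapse = ", "),
      paste(signif(iv[bad], 5), collapse = ", "), seeds$lower, seeds$upper))
  eligible <- vol$values >= seeds$lower & vol$values <= seeds$upper
  grown <- cpp_flood_fill(as.logical(eligible), vol$grid$shape,
                          as.integer(lin0), as.integer(connectivity))
  binary_mask(array(grown, vol$grid$shape), vol$grid, label = seeds$label)
}

#' Median + closing refinement of a segmentation
#'
#' Applies a binary median filter followed by a morphological closing
#' (dilation then erosion), both with an ellipsoidal structuring element of
#' world radius `kernel_mm` (per-axis voxel radius
#' `max(1, round(kernel_mm / spacing))`, anisotropy-aware). The median
#' removes speckle and thin leak bridges; the closing fills interior holes
#' and smooths the surface — the standard cleanup after seed-and-grow.
#' Voxels outside the volume are treated as background.
#'
#' @param mask A [binary_mask].
#' @param kernel_mm Structuring-element radius in mm (default 3).
#' @return A refined [binary_mask] with the same label.
#' @export
refine_segment <- function(mask, kernel_mm = 3) {
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask")
  r <- pmax(1L, as.integer(round(kernel_mm / mask$grid$spacing)))
  off <- ball_offsets(r)
  no <- nrow(off)
  dims <- mask$grid$shape
  v <- as.logical(mask$values)
  # median: strict majority of the (centered, self-inclusive) neighborhood
  cnt <- cpp_count_neighbors(v, dims, off)
  med <- 2L * cnt > no
  # closing: dilation then erosion with the same element
  cnt <- cpp_count_neighbors(med, dims, off)
  dil <- cnt >= 1L
  cnt <- cpp_count_neighbors(dil, dims, off)
  clo <- cnt == no
  binary_mask(array(clo, dims), mask$grid, label = mask$label)
}

#' Split a mask at a plane (e.g. the left-atrial-appendage orifice)
#'
#' Voxels on the `keep_point` side of the plane (tie voxels exactly on the
#' plane are kept) are retained and then restricted to the 6-connected
#' component containing `keep_point`; everything else goes to `removed`.
#' `kept` and `removed` always partition the input mask exactly.
#'
#' @param mask A [binary_mask].
#' @param plane_point A world point (mm) on the cutting plane.
#' @param plane_normal Nonzero plane normal.
#' @param keep_point World point (mm) inside the mask marking the side (and
#'   component) to keep.
#' @return List with [binary_mask] fields `kept` and `removed`.
#' @export
cut_at_plane <- function(mask, plane_point, plane_normal, keep_point) {
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask")
  n <- as.numeric(plane_normal)
  if (sqrt(sum(n^2)) < 1e-12) stop("`plane_normal` must be nonzero")
  n <- n / sqrt(sum(n^2))
  kp_idx <- nearest_index(mask$grid, keep_point, "keep point")
  kp_lin0 <- kp_idx[1, 1] + mask$grid$shape[1] *
    (kp_idx[1, 2] + mask$grid$shape[2] * kp_idx[1, 3])
  if (!mask$values[kp_lin0 + 1]) stop("`keep_point` is not inside the mask")
  s_keep <- sum((as.numeric(keep_point) - as.numeric(plane_point)) * n)
  side_sign <- if (s_keep >= 0) 1 else -1
  centers <- voxel_centers(mask$grid)
  s <- drop(sweep(centers, 2, as.numeric(plane_point), "-") %*% n)
  on_side <- array(side_sign * s >= 0, mask$grid$shape)
  cand <- mask$values & on_side
  comp <- cpp_flood_fill(as.logical(cand), mask$grid$shape,
                         as.integer(kp_lin0), 6L)
  kept <- array(comp, mask$grid$shape)
  removed <- mask$values & !kept
  list(kept = binary_mask(kept, mask$grid, label = mask$label),
       removed = binary_mask(removed, mask$grid, label = mask$label))
}
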