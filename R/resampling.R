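#' Resample a binary mask through a rigid transform onto a target grid
#'
#' For every target voxel center p, the mask is looked up at the source voxel
#' index of `t(p)` (the pull-back convention shared with registration) by
#' nearest-neighbor interpolation, which keeps the output strictly binary —
#' the standard way to carry a segmentation between voxel grids. Fractional
#' indices are rounded half away from zero (stated explicitly because
#' voxel-boundary ties otherwise differ across platforms); points mapping
#' outside the source volume become background.
#'
#' @param mask Source [binary_mask].
#' @param t [rigid_transform] mapping target world to source world; use the
#'   transform returned by registration to carry CE-MRA segments into the
#'   4D-flow frame.
#' @param target Target [image_grid] (e.g. the 4D-flow grid).
#' @return A [binary_mask] on `target` with the source label.
#' @export
resample_mask <- function(mask, t, target) {
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask")
  centers <- voxel_centers(target)
  src_world <- apply_rigid(t, centers)
  src_idx <- index_from_world(mask$grid, as_points(src_world))
  hit <- cpp_nn_mask_lookup(as.logical(mask$values), mask$grid$shape, src_idx)
  binary_mask(array(hit, target$shape), target, label = mask$label)
}

#' Resample a scalar volume through a rigid transform onto a target grid
#'
#' Trilinear interpolation of the source volume at the transform-mapped
#' target voxel centers; out-of-bounds points become 0. Used for overlays
#' and for verifying registration alignment on intensities.
#'
#' @param vol Source [scalar_volume].
#' @param t [rigid_transform] mapping target world to source world.
#' @param target Target [image_grid].
#' @return A [scalar_volume] on `target`.
#' @export
resample_scalar <- function(vol, t, target) {
  if (!inherits(vol, "scalar_volume")) stop("`vol` must be a scalar_volume")
  centers <- voxel_centers(target)
  src_world <- apply_rigid(t, centers)
  src_idx <- index_from_world(vol$grid, as_points(src_world))
  v <- cpp_trilinear(as.numeric(vol$values), vol$grid$shape, src_idx, 0)
  scalar_volume(array(v, target$shape), target)
}
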