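check_hemo_inputs <- function(series, mask) {
  if (!inherits(series, "flow_series")) stop("`series` must be a flow_series")
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask")
  if (!grids_equal(series$grid, mask$grid))
    stop("mask grid does not match the flow series grid")
  if (!any(mask$values)) stop("mask is empty")
}

# (n_mask x n_frames) matrix of speeds at mask voxels.
mask_speeds <- function(series, mask) {
  sel <- as.logical(mask$values)
  n <- series$n_frames
  out <- matrix(0, sum(sel), n)
  for (i in seq_len(n)) {
    sp <- sqrt(series$velocity[, , , 1, i]^2 +
               series$velocity[, , , 2, i]^2 +
               series$velocity[, , , 3, i]^2)
    out[, i] <- sp[sel]
  }
  out
}

#' Mean velocity within a mask
#'
#' Mean velocity magnitude pooled over all (voxel in mask, frame) pairs,
#' reported in cm/s. Pooled averaging is identical to per-frame means of
#' means for a time-constant mask, and is stated to remove the ambiguity.
#'
#' @param series A [flow_series] (velocities in m/s).
#' @param mask A non-empty [binary_mask] on the series grid.
#' @return Mean speed in cm/s.
#' @export
mean_velocity <- function(series, mask) {
  check_hemo_inputs(series, mask)
  mean(mask_speeds(series, mask)) * 100
}

#' Stasis within a mask
#'
#' For each voxel, the fraction of cardiac-cycle frames in which the
#' velocity magnitude stays strictly below `threshold`; stasis is the mean
#' of that fraction over the mask, expressed in percent (0-100). The default
#' 0.1 m/s threshold is the conventional cut-off for blood considered
#' effectively stagnant — the regime where thrombus formation in the
#' fibrillating atrium is of clinical concern.
#'
#' @param series A [flow_series] (velocities in m/s).
#' @param mask A non-empty [binary_mask] on the series grid.
#' @param threshold Speed threshold in m/s (default 0.1, strict `<`).
#' @return Stasis percentage in `[0, 100]`.
#' @export
stasis <- function(series, mask, threshold = 0.1) {
  check_hemo_inputs(series, mask)
  sp <- mask_speeds(series, mask)
  mean(rowMeans(sp < threshold)) * 100
}

#' Per-voxel stasis map
#'
#' The voxelwise time-fraction below threshold backing the [stasis()]
#' summary: values in `[0, 1]` inside the mask, 0 outside. The mask-mean of
#' the map times 100 equals `stasis()` exactly.
#'
#' @inheritParams stasis
#' @return A [scalar_volume] of stasis fractions.
#' @export
stasis_map <- function(series, mask, threshold = 0.1) {
  check_hemo_inputs(series, mask)
  sel <- as.logical(mask$values)
  frac <- rowMeans(mask_speeds(series, mask) < threshold)
  out <- array(0, series$grid$shape)
  out[sel] <- frac
  scalar_volume(out, series$grid)
}
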