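#' Derive a phase-contrast MR angiogram (PC-MRA) from a 4D-flow series
#'
#' Computes, for every voxel r, the time average of magnitude times speed,
#' \deqn{PCMRA(r) = \frac{1}{N} \sum_{i=1}^{N} I_i^{Mag}(r)
#'   \sqrt{v_{x,i}^2(r) + v_{y,i}^2(r) + v_{z,i}^2(r)},}
#' which lights up voxels that are both signal-rich and moving — the standard
#' angiogram surrogate used to delineate chambers on 4D-flow when no separate
#' angiography is available. No rescaling or clipping is applied; intensity
#' normalization for registration happens downstream.
#'
#' @param series A [flow_series].
#' @return A [scalar_volume] on the series grid; values are nonnegative
#'   whenever magnitudes are.
#' @examples
#' g <- image_grid(c(4, 4, 4), spacing = c(3, 3, 3))
#' mag <- array(2, c(4, 4, 4, 1))
#' vel <- array(0, c(4, 4, 4, 3, 1)); vel[, , , 1, ] <- 0.3; vel[, , , 3, ] <- 0.4
#' fs <- flow_series(g, mag, vel)
#' range(compute_pcmra(fs)$values) # 1.0 everywhere: 2 * |(0.3, 0, 0.4)|
#' @export
compute_pcmra <- function(series) {
  if (!inherits(series, "flow_series")) stop("`series` must be a flow_series")
  n <- series$n_frames
  acc <- array(0, dim = series$grid$shape)
  for (i in seq_len(n)) {
    sp <- sqrt(series$velocity[, , , 1, i]^2 +
               series$velocity[, , , 2, i]^2 +
               series$velocity[, , , 3, i]^2)
    acc <- acc + series$magnitude[, , , i] * sp
  }
  scalar_volume(acc / n, series$grid)
}

#' Voxelwise speed of one frame of a 4D-flow series
#'
#' @param series A [flow_series].
#' @param frame Frame number, 1-based, in `1..n_frames`.
#' @return A [scalar_volume] of velocity magnitudes (m/s).
#' @export
speed_volume <- function(series, frame) {
  if (!inherits(series, "flow_series")) stop("`series` must be a flow_series")
  frame <- as.integer(frame)
  if (length(frame) != 1L || is.na(frame) || frame < 1L || frame > series$n_frames)
    stop(sprintf("`frame` must be in 1..%d", series$n_frames))
  sp <- sqrt(series$velocity[, , , 1, frame]^2 +
             series$velocity[, , , 2, frame]^2 +
             series$velocity[, , , 3, frame]^2)
  scalar_volume(array(sp, series$grid$shape), series$grid)
}
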