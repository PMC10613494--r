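#' Mask volume in millilitres
#'
#' Foreground voxel count times the voxel volume `|det(affine[1:3, 1:3])|`
#' in mm^3, divided by 1000.
#'
#' @param mask A [binary_mask].
#' @return Volume in ml.
#' @export
volume_ml <- function(mask) {
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask")
  sum(mask$values) * abs(det(mask$grid$affine[1:3, 1:3])) / 1000
}

#' Dice similarity coefficient of two masks
#'
#' `DSC(A, B) = 2 |A intersect B| / (|A| + |B|)`: the standard volumetric
#' overlap of two segmentations, 1 for identical non-empty masks and 0 for
#' disjoint ones. Two empty masks are an error, not 1 — a silent degenerate
#' "success" would hide upstream failures.
#'
#' @param a,b [binary_mask] objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!inherits(a, "binary_mask") || !inherits(b, "binary_mask"))
    stop("both arguments must be binary_mask objects")
  if (!grids_equal(a$grid, b$grid)) stop("masks are on different grids")
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0L) stop("Dice undefined: both masks are empty")
  2 * sum(a$values & b$values) / (na + nb)
}

#' Surface voxels of a mask
#'
#' Foreground voxels with at least one background (or out-of-volume)
#' neighbor under the stated connectivity. The 26-connected surface is
#' always a superset of the 6-connected one. The ratio of surface to total
#' voxels is the natural gauge of how much a boundary disagreement can move
#' volume-derived quantities.
#'
#' @param mask A non-empty [binary_mask].
#' @param connectivity 6 (face neighbors) or 26 (full neighborhood).
#' @return A [binary_mask] of the surface voxels (subset of `mask`).
#' @export
surface_voxels <- function(mask, connectivity = 6) {
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask")
  if (!any(mask$values)) stop("surface of an empty mask is undefined")
  off <- connectivity_offsets(connectivity)
  cnt <- cpp_count_neighbors(as.logical(mask$values), mask$grid$shape, off)
  surf <- mask$values & array(cnt < nrow(off), mask$grid$shape)
  binary_mask(surf, mask$grid, label = mask$label)
}

#' Average symmetric surface distance (ASSD)
#'
#' \deqn{ASSD(A, B) = \frac{\sum_{a \in S(A)} \min_{b \in S(B)} \|a - b\| +
#'   \sum_{b \in S(B)} \min_{a \in S(A)} \|a - b\|}{|S(A)| + |S(B)|}}
#' with `S(.)` the 6-connected surface voxel sets and distances measured
#' between voxel centers in world mm. Symmetric, nonnegative, and 0 exactly
#' when the two surfaces coincide.
#'
#' @param a,b Non-empty [binary_mask] objects on the same grid.
#' @return Distance in mm.
#' @export
assd <- function(a, b) {
  if (!inherits(a, "binary_mask") || !inherits(b, "binary_mask"))
    stop("both arguments must be binary_mask objects")
  if (!grids_equal(a$grid, b$grid)) stop("masks are on different grids")
  if (!any(a$values) || !any(b$values))
    stop("ASSD undefined for empty masks")
  sa <- surface_voxels(a, 6)
  sb <- surface_voxels(b, 6)
  ca <- voxel_centers(a$grid)
  pa <- ca[as.logical(sa$values), , drop = FALSE]
  pb <- ca[as.logical(sb$values), , drop = FALSE]
  dab <- cpp_min_dists(pa, pb)
  dba <- cpp_min_dists(pb, pa)
  (sum(dab) + sum(dba)) / (nrow(pa) + nrow(pb))
}

#' Bland-Altman agreement and Pearson correlation of paired measurements
#'
#' Differences are taken as `x - y`; limits of agreement are
#' `mean(d) +/- 1.96 * sd(d)` with the sample (n - 1) standard deviation.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Object of class `agreement_stats` with fields `mean_difference`,
#'   `loa_low`, `loa_high`, `pearson_r`, `n`.
#' @export
bland_altman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("at least 3 pairs are required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  d <- x - y
  m <- mean(d)
  s <- sd(d)
  if (sd(x) == 0 || sd(y) == 0)
    stop("Pearson correlation undefined: a series has zero variance")
  structure(list(mean_difference = m, loa_low = m - 1.96 * s,
                 loa_high = m + 1.96 * s, pearson_r = cor(x, y),
                 n = length(x)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "agreement_stats (n = %d): mean difference %.4g, LoA [%.4g, %.4g], r = %.3f\n",
    x$n, x$mean_difference, x$loa_low, x$loa_high, x$pearson_r))
  invisible(x)
}
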