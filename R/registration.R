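#' Registration configuration
#'
#' @param sample_fraction Fraction of eligible fixed-image voxels used as
#'   metric samples, in (0, 1]. The global first round uses 0.2; the
#'   ROI-restricted second round uses 1.0.
#' @param histogram_bins Number of intensity bins per axis of the joint
#'   histogram (default 32, minimum 8).
#' @param max_iterations Cap on objective evaluations (default 1500).
#' @param seed Integer seed controlling sample drawing; fixes the objective
#'   so the whole registration is deterministic.
#' @param roi Optional [roi_box] restricting the fixed-image samples.
#' @param convergence_tol Relative metric-change tolerance for the optimizer
#'   (default 1e-5).
#' @return Object of class `registration_config`.
#' @export
registration_config <- function(sample_fraction = 0.2, histogram_bins = 32,
                                max_iterations = 1500, seed = 1,
                                roi = NULL, convergence_tol = 1e-5) {
  if (!(sample_fraction > 0 && sample_fraction <= 1))
    stop("`sample_fraction` must be in (0, 1]")
  histogram_bins <- as.integer(histogram_bins)
  if (histogram_bins < 8L) stop("`histogram_bins` must be >= 8")
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 1L) stop("`max_iterations` must be positive")
  if (!is.null(roi) && !inherits(roi, "roi_box"))
    stop("`roi` must be an roi_box or NULL")
  structure(list(sample_fraction = sample_fraction,
                 histogram_bins = histogram_bins,
                 max_iterations = max_iterations,
                 seed = as.integer(seed), roi = roi,
                 convergence_tol = convergence_tol),
            class = "registration_config")
}

#' Axis-aligned world-space region of interest
#'
#' A simple cube/box ROI in world mm, used to restrict second-round
#' registration samples to the upper chambers while excluding the aortic
#' arch.
#'
#' @param min_corner,max_corner Length-3 world coordinates (mm),
#'   `min_corner < max_corner` componentwise.
#' @return Object of class `roi_box`.
#' @export
roi_box <- function(min_corner, max_corner) {
  min_corner <- as.numeric(min_corner); max_corner <- as.numeric(max_corner)
  stopifnot(length(min_corner) == 3, length(max_corner) == 3)
  if (!all(min_corner < max_corner))
    stop("`min_corner` must be strictly below `max_corner` componentwise")
  structure(list(min_corner = min_corner, max_corner = max_corner),
            class = "roi_box")
}

#' ROI box around segmented structures
#'
#' Axis-aligned world bounding box of the union of the segments' foreground
#' voxel centers, expanded by a margin on every side. When the segments live
#' in the moving image's frame (the usual case: CE-MRA segments used to
#' focus a second registration round on the fixed PC-MRA), pass the
#' fixed-to-moving `transform` from the first round; voxel centers are then
#' mapped through its inverse into the fixed frame before the box is taken.
#'
#' @param segments List of [binary_mask] objects (e.g. LA and PV).
#' @param margin_mm Margin added per side in mm (default 20).
#' @param transform Optional fixed-to-moving [rigid_transform]; segment voxel
#'   centers are mapped through `invert_rigid(transform)`.
#' @return An [roi_box].
#' @export
roi_from_segments <- function(segments, margin_mm = 20, transform = NULL) {
  if (inherits(segments, "binary_mask")) segments <- list(segments)
  if (length(segments) == 0L) stop("at least one segment is required")
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  any_fg <- FALSE
  for (m in segments) {
    if (!inherits(m, "binary_mask")) stop("segments must be binary_mask objects")
    if (!any(m$values)) next
    any_fg <- TRUE
    pts <- voxel_centers(m$grid)[as.logical(m$values), , drop = FALSE]
    if (!is.null(transform)) pts <- apply_rigid(invert_rigid(transform), pts)
    # voxels are little boxes, not points: pad by the half-voxel extent
    half <- rowSums(abs(m$grid$affine[1:3, 1:3])) / 2
    lo <- pmin(lo, apply(pts, 2, min) - half)
    hi <- pmax(hi, apply(pts, 2, max) + half)
  }
  if (!any_fg) stop("all segments are empty")
  roi_box(lo - margin_mm, hi + margin_mm)
}

#' Draw metric sample points from a fixed-image grid
#'
#' Uniform random subset, without replacement, of the voxel centers lying
#' inside the grid (and inside `roi` when given); the subset is fixed for a
#' whole registration round, which makes the mutual-information objective a
#' deterministic function of the transform.
#'
#' @param grid Fixed-image [image_grid].
#' @param roi Optional [roi_box]; errors if it contains no voxel center.
#' @param fraction Sampling fraction in (0, 1]; the returned count is
#'   `max(1, round(fraction * eligible))`.
#' @param seed Integer seed; equal seeds give identical sample sets.
#' @return n x 3 matrix of world points (mm).
#' @export
draw_samples <- function(grid, roi = NULL, fraction = 0.2, seed = 1) {
  if (!(fraction > 0 && fraction <= 1)) stop("`fraction` must be in (0, 1]")
  centers <- voxel_centers(grid)
  if (!is.null(roi)) {
    keep <- centers[, 1] >= roi$min_corner[1] & centers[, 1] <= roi$max_corner[1] &
            centers[, 2] >= roi$min_corner[2] & centers[, 2] <= roi$max_corner[2] &
            centers[, 3] >= roi$min_corner[3] & centers[, 3] <= roi$max_corner[3]
    if (!any(keep)) stop("ROI is disjoint from the image grid")
    centers <- centers[keep, , drop = FALSE]
  }
  n <- nrow(centers)
  k <- max(1L, as.integer(round(fraction * n)))
  if (k >= n) return(centers)
  sel <- with_seed(seed, sample.int(n, k))
  centers[sort(sel), , drop = FALSE]
}

# Robust intensity range for histogram binning: 0.5th-99.5th percentiles,
# computed once per registration round, taming contrast-agent hot spots.
intensity_clip <- function(values, probs = c(0.005, 0.995)) {
  q <- quantile(values, probs = probs, names = FALSE, type = 7)
  if (q[2] <= q[1]) q[2] <- q[1] + 1e-12
  q
}

bin_intensities <- function(x, clip, bins) {
  b <- floor((x - clip[1]) / (clip[2] - clip[1]) * bins) + 1
  pmin(pmax(b, 1L), bins)
}

entropy_nats <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Mutual information between fixed and moving images under a transform
#'
#' Joint-histogram mutual information in nats:
#' `MI = H(F) + H(M) - H(F, M)`, estimated over the sample points. The fixed
#' intensity is taken at each sample; the moving intensity at the
#' transform-mapped point via trilinear interpolation. Samples mapping
#' outside the moving volume are dropped; fewer than 2 surviving samples is
#' an overlap failure. Intensities are binned linearly between the supplied
#' (or per-call) robust 0.5th-99.5th percentile ranges. Mutual information
#' is invariant to within-bin-order-preserving intensity remaps, which is
#' what makes it usable across modalities with unrelated contrast.
#'
#' @param fixed,moving [scalar_volume] objects.
#' @param t A [rigid_transform] mapping fixed world to moving world.
#' @param samples n x 3 matrix of fixed-image world points (see
#'   [draw_samples()]).
#' @param bins Histogram bins per axis (default 32).
#' @param clip_fixed,clip_moving Optional length-2 intensity ranges; when
#'   omitted they are computed from the full volumes. Pass precomputed
#'   ranges when evaluating repeatedly inside an optimizer loop.
#' @return Mutual information in nats (>= 0 up to rounding).
#' @export
mutual_information <- function(fixed, moving, t, samples, bins = 32,
                               clip_fixed = NULL, clip_moving = NULL) {
  if (is.null(clip_fixed)) clip_fixed <- intensity_clip(fixed$values)
  if (is.null(clip_moving)) clip_moving <- intensity_clip(moving$values)
  fi <- index_from_world(fixed$grid, samples)
  fv <- cpp_trilinear(as.numeric(fixed$values), fixed$grid$shape, fi, NA_real_)
  mp <- apply_rigid(t, samples)
  mi <- index_from_world(moving$grid, as_points(mp))
  mv <- cpp_trilinear(as.numeric(moving$values), moving$grid$shape, mi, NA_real_)
  ok <- !is.na(fv) & !is.na(mv)
  if (sum(ok) < 2L)
    stop("overlap failure: fewer than 2 samples fall inside the moving image")
  fb <- bin_intensities(fv[ok], clip_fixed, bins)
  mb <- bin_intensities(mv[ok], clip_moving, bins)
  joint <- tabulate(fb + bins * (mb - 1L), nbins = bins * bins)
  hf <- entropy_nats(tabulate(fb, nbins = bins))
  hm <- entropy_nats(tabulate(mb, nbins = bins))
  hfm <- entropy_nats(joint)
  hf + hm - hfm
}

# Pack/unpack the 6 optimizer parameters. Rotations are scaled by a 50 mm
# characteristic lever so a unit step means ~50 mm of arc, comparable to a
# translation step.
.rot_scale <- 50

par_from_transform <- function(t) {
  c(t$translation, t$angles * .rot_scale)
}

transform_from_par <- function(par, center) {
  rigid_transform(angles = par[4:6] / .rot_scale, translation = par[1:3],
                  center = center)
}

#' Rigid mutual-information registration
#'
#' Maximizes joint-histogram mutual information over the six rigid
#' parameters with a derivative-free Nelder-Mead search (with simplex
#' restarts until the metric stops improving). Sample points are drawn once
#' per call and held fixed across iterations, so the objective — and hence
#' the whole registration — is deterministic given `cfg$seed`. The rotation
#' center is the world center of the fixed grid.
#'
#' The result's `quality` record replaces the visual accept/reject of an
#' interactive workflow: a registration is flagged when the metric gain is
#' negligible (< 1e-3 nats) or the recovered translation exceeds half the
#' fixed field of view; final acceptance remains the user's decision.
#'
#' @param fixed Fixed [scalar_volume] (the PC-MRA).
#' @param moving Moving [scalar_volume] (the CE-MRA).
#' @param cfg A [registration_config].
#' @param init Initial [rigid_transform] (default identity about the fixed
#'   grid center).
#' @return Object of class `registration_result`: fields `transform`,
#'   `mi_initial`, `mi_final`, `iterations`, `converged`, `round_index`,
#'   `quality`.
#' @export
register_rigid <- function(fixed, moving, cfg = registration_config(),
                           init = NULL) {
  center <- grid_center(fixed$grid)
  if (is.null(init)) init <- rigid_transform(center = center)
  samples <- draw_samples(fixed$grid, roi = cfg$roi,
                          fraction = cfg$sample_fraction, seed = cfg$seed)
  bins <- cfg$histogram_bins

  # Two-level pyramid: a Gaussian-smoothed level (sigma of one fixed voxel)
  # widens the capture basin and irons histogram-quantization plateaus out
  # of the metric; the full-resolution level recovers the sharp optimum.
  smooth_level <- function(vol, sigma_vox) {
    scalar_volume(array(cpp_gauss_smooth(as.numeric(vol$values),
                                         vol$grid$shape,
                                         rep(sigma_vox, 3)),
                        vol$grid$shape), vol$grid)
  }
  sigma_mm <- max(fixed$grid$spacing)
  levels <- list(
    list(fixed = smooth_level(fixed, sigma_mm / max(fixed$grid$spacing)),
         moving = smooth_level(moving, sigma_mm / max(moving$grid$spacing)),
         scales = c(5, 5, 2)),
    list(fixed = fixed, moving = moving, scales = c(1, 1, 0.5, 0.2))
  )

  make_objective <- function(f, m) {
    clip_f <- intensity_clip(f$values)
    clip_m <- intensity_clip(m$values)
    function(par) {
      t <- transform_from_par(par, center)
      val <- tryCatch(
        mutual_information(f, m, t, samples, bins,
                           clip_fixed = clip_f, clip_moving = clip_m),
        error = function(e) NA_real_)
      if (!is.finite(val)) return(1e6) # overlap lost: strongly penalized
      -val
    }
  }
  neg_mi_full <- make_objective(fixed, moving)

  # express init about the fixed-grid center so par_from_transform is valid
  init_c <- rigid_from_matrix(rigid_matrix(init), center = center)
  par <- par_from_transform(init_c)
  f0 <- neg_mi_full(par)
  if (f0 >= 1e6)
    stop("overlap failure: initial transform leaves no common field of view")
  mi_initial <- -f0
  total_iter <- 0L
  best_par <- par
  converged <- FALSE
  for (level in levels) {
    neg_mi <- make_objective(level$fixed, level$moving)
    best_f <- neg_mi(best_par)
    # Nelder-Mead restarts, coarse-to-fine: parscale sets the initial
    # simplex extent (mm of translation, mm of arc for scaled rotations);
    # restarting until the metric stops improving guards against premature
    # simplex collapse.
    for (scale in level$scales) {
      budget <- cfg$max_iterations - total_iter
      if (budget < 10L) break
      fit <- optim(best_par, neg_mi, method = "Nelder-Mead",
                   control = list(maxit = budget,
                                  reltol = cfg$convergence_tol,
                                  parscale = rep(scale, 6)))
      total_iter <- total_iter + fit$counts[["function"]]
      improved <- best_f - fit$value
      if (fit$value < best_f) {
        best_f <- fit$value
        best_par <- fit$par
      }
      converged <- fit$convergence == 0
      if (converged && scale <= 0.5 &&
          improved < max(1e-4, cfg$convergence_tol))
        break
    }
  }
  best_f <- neg_mi_full(best_par)
  if (best_f > f0) { best_par <- par; best_f <- f0 } # never worse than start
  t_best <- transform_from_par(best_par, center)
  mi_final <- -best_f
  fov <- fixed$grid$shape * fixed$grid$spacing
  tmag <- sqrt(sum((apply_rigid(t_best, center) - center)^2))
  flagged <- (mi_final - mi_initial) < 1e-3 || tmag > 0.5 * max(fov)
  structure(list(transform = t_best, mi_initial = mi_initial,
                 mi_final = mi_final,
                 iterations = min(total_iter, cfg$max_iterations),
                 converged = converged, round_index = 1L,
                 quality = list(mi_gain = mi_final - mi_initial,
                                displacement_mm = tmag, flagged = flagged,
                                n_samples = nrow(samples))),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "registration_result (round %d): MI %.4f -> %.4f in %d evaluations%s\n",
    x$round_index, x$mi_initial, x$mi_final, x$iterations,
    if (x$quality$flagged) " [FLAGGED]" else ""))
  print(x$transform)
  invisible(x)
}

#' Two-round registration with an ROI second round
#'
#' Round 1 registers globally with a 0.2 sample fraction. When the global
#' round latches onto the wrong structure — typically the aorta, whose
#' position relative to the chambers differs between a time-averaged PC-MRA
#' and a single-phase CE-MRA — a second round restarts from the round-1
#' transform with samples restricted to a box around the chamber segments
#' (LA and PV) and a 1.0 sample fraction. The returned result is the
#' last executed round, with `round_index` set accordingly and the earlier
#' round kept in `$rounds`.
#'
#' @param fixed,moving [scalar_volume] objects (PC-MRA, CE-MRA).
#' @param segments List of [binary_mask] segments in the moving frame (LA,
#'   PV) used to build the second-round ROI.
#' @param cfg1 Round-1 [registration_config] (global, fraction 0.2).
#' @param cfg2 Round-2 [registration_config] (fraction 1.0); its `roi`, when
#'   `NULL`, is derived from the segments via the round-1 transform with a
#'   20 mm margin.
#' @param run_round2 `"always"` (default), `"never"`, or `"auto"` (only when
#'   the round-1 quality flag is raised).
#' @param margin_mm ROI margin around the segments (default 20).
#' @param init Optional initial transform for round 1.
#' @return A `registration_result` with `round_index` 1 or 2 and a `rounds`
#'   list holding every executed round.
#' @export
two_round_register <- function(fixed, moving, segments,
                               cfg1 = registration_config(sample_fraction = 0.2),
                               cfg2 = registration_config(sample_fraction = 1.0),
                               run_round2 = c("always", "auto", "never"),
                               margin_mm = 20, init = NULL) {
  run_round2 <- match.arg(run_round2)
  r1 <- register_rigid(fixed, moving, cfg1, init = init)
  r1$round_index <- 1L
  do2 <- switch(run_round2, always = TRUE, never = FALSE,
                auto = r1$quality$flagged)
  if (!do2) {
    r1$rounds <- list(r1)
    return(r1)
  }
  cfg2$roi <- if (is.null(cfg2$roi))
    roi_from_segments(segments, margin_mm = margin_mm,
                      transform = r1$transform)
  else cfg2$roi
  r2 <- register_rigid(fixed, moving, cfg2, init = r1$transform)
  r2$round_index <- 2L
  r2$rounds <- list(r1, r2)
  r2
}
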