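#' Specification of the synthetic cardiac phantom
#'
#' The phantom emulates the paired acquisition the pipeline is built for: a
#' ~1.2 mm isotropic contrast-enhanced angiography volume and a ~3 mm,
#' 25-phase 4D-flow series of an ellipsoidal left atrium with an appendage
#' lobe, four pulmonary-vein tubes, an aortic-arch decoy, and a left
#' ventricle. The angiography scene is posed at a known rigid misalignment
#' relative to the flow scene, carries a smooth multiplicative bias field and
#' Gaussian noise, and maps tissue classes to intensities through a
#' deliberately non-monotone inter-modality relationship (contrast-enhanced
#' blood is the brightest class on angiography but, emulating contrast-agent
#' wash-out, not on the flow magnitude) so that mutual information succeeds
#' where correlation-based metrics would not. The left-atrial velocity field
#' is a closed-form swirl with a low-speed boundary layer, so stasis and
#' mean velocity inside the truth mask have analytic values.
#'
#' @param ce_spacing Angiography voxel size, mm isotropic (default 1.2).
#' @param flow_spacing 4D-flow voxel size, mm isotropic (default 3.0).
#' @param n_frames Number of cardiac phases (default 25).
#' @param la_semiaxes Left-atrium ellipsoid semiaxes in mm
#'   (default `c(30, 25, 20)`).
#' @param true_transform Ground-truth [rigid_transform] posing the
#'   angiography scene relative to the flow scene (fixed-to-moving
#'   pull-back, the package-wide convention). Default: 6, -4, 8 mm
#'   translation with 5, -3, 2 degree rotations.
#' @param decoy_offset_mm Extra displacement (mm, along +z) of the aorta in
#'   the angiography scene only, reproducing the failure mode in which
#'   global registration latches onto the aorta (default 0).
#' @param noise_sd Additive Gaussian noise SD: intensity units on the
#'   angiography and magnitude images, m/s on background velocities
#'   (default 0.02).
#' @param bias_amplitude Relative amplitude of the multiplicative bias ramp
#'   on the angiography volume (default 0.2).
#' @param seed Integer seed; the phantom is bit-reproducible given it.
#' @param ce_fov_mm,flow_fov_mm Fields of view in mm (defaults 132 and 144).
#' @param venc Velocity-encoding limit stored with the series, m/s
#'   (default 1.5).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(ce_spacing = 1.2, flow_spacing = 3.0, n_frames = 25,
                         la_semiaxes = c(30, 25, 20),
                         true_transform = rigid_transform(
                           angles = c(5, -3, 2) * pi / 180,
                           translation = c(6, -4, 8)),
                         decoy_offset_mm = 0, noise_sd = 0.02,
                         bias_amplitude = 0.2, seed = 1,
                         ce_fov_mm = 132, flow_fov_mm = 144, venc = 1.5) {
  if (ce_spacing <= 0 || flow_spacing <= 0) stop("spacings must be positive")
  if (n_frames < 1) stop("`n_frames` must be >= 1")
  if (any(la_semiaxes <= 0)) stop("`la_semiaxes` must be positive")
  if (!inherits(true_transform, "rigid_transform"))
    stop("`true_transform` must be a rigid_transform")
  structure(list(ce_spacing = ce_spacing, flow_spacing = flow_spacing,
                 n_frames = as.integer(n_frames),
                 la_semiaxes = as.numeric(la_semiaxes),
                 true_transform = true_transform,
                 decoy_offset_mm = decoy_offset_mm, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude, seed = as.integer(seed),
                 ce_fov_mm = ce_fov_mm, flow_fov_mm = flow_fov_mm,
                 venc = venc),
            class = "phantom_spec")
}

# Fixed scene geometry in the flow frame (mm), LA centered at the origin.
# Flow-speed constants: la_omega in (m/s)/mm; pv/aorta speeds in m/s.
phantom_geometry <- function(spec) {
  s <- spec$la_semiaxes
  dirs <- rbind(c(0.75, 0.55, 0.35), c(0.75, -0.55, 0.35),
                c(-0.75, 0.55, 0.35), c(-0.75, -0.55, 0.35))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  t_surf <- 1 / sqrt(rowSums(sweep(dirs, 2, s, "/")^2))
  anchors <- dirs * (0.95 * t_surf)
  list(
    la_semiaxes = s,
    la_shell = 1.25,          # myocardium shell; swirl tail ends here
    la_w_core = 0.85,         # full-speed core in ellipsoidal rho
    la_w_wall = 0.2,          # residual speed fraction at the wall (rho = 1)
    la_omega = 0.014,
    laa_center = c(34, 10, 6), laa_semiaxes = c(12, 7, 7),
    pv_anchors = anchors, pv_dirs = dirs, pv_len = 30, pv_radius = 6,
    pv_speed = 0.35,
    ao_center = c(0, -42, 10), ao_major = 30, ao_tube = 9, ao_speed = 0.6,
    lv_center = c(5, 40, -20), lv_semiaxes = c(24, 18, 18),
    lv_shell = 1.2, lv_omega = 0.012,
    int_ce = c(bg = 0.05, myo = 0.35, lv = 0.9, pv = 0.95, la = 1.0,
               laa = 1.0, ao = 1.05),
    int_mag = c(bg = 0.30, myo = 0.50, blood = 0.42),
    ce_gamma = 0.8
  )
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Low-speed boundary-layer profile of the atrial swirl: full speed in the
# core, linear decay to a small residual at the wall (partial-volume voxels
# just outside the blood pool still move slowly, as tissue-adjacent blood
# does), then decay to zero across the myocardium shell.
la_speed_profile <- function(rho, geom) {
  w <- rep(0, length(rho))
  core <- rho <= geom$la_w_core
  wall <- rho > geom$la_w_core & rho <= 1
  shell <- rho > 1 & rho <= geom$la_shell
  w[core] <- 1
  w[wall] <- 1 + (geom$la_w_wall - 1) *
    (rho[wall] - geom$la_w_core) / (1 - geom$la_w_core)
  w[shell] <- geom$la_w_wall * (geom$la_shell - rho[shell]) /
    (geom$la_shell - 1)
  w
}

# Structure membership and velocity basis at points x (n x 3, flow frame).
# decoy_shift displaces the aorta (angiography scene only).
phantom_scene <- function(x, geom, decoy_shift = c(0, 0, 0)) {
  s <- geom$la_semiaxes
  rho_la <- sqrt((x[, 1] / s[1])^2 + (x[, 2] / s[2])^2 + (x[, 3] / s[3])^2)
  la <- rho_la <= 1
  la_quiet <- rho_la > 1 & rho_la <= geom$la_shell
  xr <- sweep(x, 2, geom$laa_center)
  rho_laa <- sqrt((xr[, 1] / geom$laa_semiaxes[1])^2 +
                  (xr[, 2] / geom$laa_semiaxes[2])^2 +
                  (xr[, 3] / geom$laa_semiaxes[3])^2)
  laa <- rho_laa <= 1 & !la
  pv <- rep(FALSE, nrow(x))
  pv_which <- integer(nrow(x))
  for (k in seq_len(nrow(geom$pv_anchors))) {
    rel <- sweep(x, 2, geom$pv_anchors[k, ])
    t <- pmin(pmax(rel %*% geom$pv_dirs[k, ], 0), geom$pv_len)
    closest <- outer(drop(t), geom$pv_dirs[k, ])
    d <- sqrt(rowSums((rel - closest)^2))
    ink <- d <= geom$pv_radius & !la & !laa
    pv_which[ink & !pv] <- k
    pv <- pv | ink
  }
  ac <- geom$ao_center + decoy_shift
  rxz <- sqrt((x[, 1] - ac[1])^2 + (x[, 3] - ac[3])^2)
  ao <- sqrt((rxz - geom$ao_major)^2 + (x[, 2] - ac[2])^2) <= geom$ao_tube &
    x[, 3] >= ac[3]
  lr <- sweep(x, 2, geom$lv_center)
  rho_lv <- sqrt((lr[, 1] / geom$lv_semiaxes[1])^2 +
                 (lr[, 2] / geom$lv_semiaxes[2])^2 +
                 (lr[, 3] / geom$lv_semiaxes[3])^2)
  lv <- rho_lv <= 1
  myo <- (la_quiet | (rho_lv > 1 & rho_lv <= geom$lv_shell)) &
    !la & !laa & !pv & !ao & !lv
  list(la = la, la_quiet = la_quiet, laa = laa, pv = pv, pv_which = pv_which,
       ao = ao, lv = lv, myo = myo, rho_la = rho_la, rho_lv = rho_lv,
       rxz = rxz, ac = ac)
}

# Per-voxel velocity basis vb (n x 3, m/s at unit cardiac modulation) and a
# quiet flag marking voxels that carry no velocity noise. Frame i velocity is
# vb * s_i plus noise where allowed.
phantom_velocity_basis <- function(x, geom, sc) {
  n <- nrow(x)
  vb <- matrix(0, n, 3)
  quiet <- sc$la_quiet | sc$laa
  # LA swirl about the z axis with a low-speed boundary layer extending
  # into the wall shell (see la_speed_profile)
  w <- la_speed_profile(sc$rho_la, geom)
  i <- which((sc$la | sc$la_quiet) & !sc$laa)
  vb[i, 1] <- -geom$la_omega * x[i, 2] * w[i]
  vb[i, 2] <- geom$la_omega * x[i, 1] * w[i]
  # pulmonary-vein plug flow along each tube axis
  i <- which(sc$pv)
  vb[i, ] <- geom$pv_speed * geom$pv_dirs[sc$pv_which[i], , drop = FALSE]
  # aortic tangential flow along the arch
  i <- which(sc$ao & !sc$la & !sc$pv)
  rxz <- pmax(sc$rxz[i], 1e-9)
  vb[i, 1] <- -geom$ao_speed * (x[i, 3] - sc$ac[3]) / rxz
  vb[i, 3] <- geom$ao_speed * (x[i, 1] - sc$ac[1]) / rxz
  # ventricular swirl about the x axis
  i <- which(sc$lv & !sc$la & !sc$pv & !sc$ao)
  wl <- clamp01((1 - sc$rho_lv[i]) / (1 - geom$la_w_core))
  vb[i, 2] <- -geom$lv_omega * (x[i, 3] - geom$lv_center[3]) * wl
  vb[i, 3] <- geom$lv_omega * (x[i, 2] - geom$lv_center[2]) * wl
  has_flow <- sc$la | sc$la_quiet | sc$pv | sc$ao | sc$lv
  list(vb = vb, quiet = quiet | has_flow)
}

# Cardiac modulation of frame i out of n: |sin| over one cycle.
frame_scaling <- function(n) abs(sin(2 * pi * (seq_len(n) - 0.5) / n))

centered_grid <- function(fov, spacing) {
  n <- max(2L, as.integer(round(fov / spacing)))
  image_grid(c(n, n, n), spacing = rep(spacing, 3),
             origin = rep(-(n - 1) / 2 * spacing, 3))
}

#' Generate a paired angiography / 4D-flow phantom with ground truth
#'
#' Builds the scene described in [phantom_spec()]: a fine-grid angiography
#' volume (bright blood classes, myocardium shells, bias field, noise) posed
#' at `spec$true_transform` relative to the flow scene, and a coarse-grid
#' flow series whose left-atrial velocities follow a closed-form swirl so
#' that the returned truth record carries analytic stasis and mean-velocity
#' values. The truth flow-grid LA mask is constructed by nearest-neighbor
#' resampling of the fine-grid LA mask through the true transform — exactly
#' the operation the pipeline itself uses — so downstream comparisons are
#' free of an extra discretization convention.
#'
#' @param spec A [phantom_spec].
#' @return List with elements `ce` ([scalar_volume]), `flow`
#'   ([flow_series]), and `truth` (class `phantom_truth`): fields
#'   `transform`, `la_mask_ce`, `laa_mask_ce`, `pv_mask_ce`,
#'   `aorta_mask_ce`, `la_mask_flow`, `analytic_stasis`,
#'   `analytic_mean_velocity`, `la_volume_ml`.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' ph$truth$la_volume_ml
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  geom <- phantom_geometry(spec)
  ce_grid <- centered_grid(spec$ce_fov_mm, spec$ce_spacing)
  flow_grid <- centered_grid(spec$flow_fov_mm, spec$flow_spacing)

  # the posed LA must stay inside the angiography field of view
  s <- geom$la_semiaxes
  corners <- as.matrix(expand.grid(c(-1, 1) * s[1], c(-1, 1) * s[2],
                                   c(-1, 1) * s[3]))
  posed <- apply_rigid(spec$true_transform, corners)
  half_fov <- (ce_grid$shape - 1) / 2 * ce_grid$spacing
  if (any(abs(posed) > matrix(half_fov, nrow(posed), 3, byrow = TRUE)))
    stop("left atrium extends outside the angiography field of view")

  n_frames <- spec$n_frames
  si <- frame_scaling(n_frames)

  # ---- angiography scene: evaluate geometry at the pulled-back position
  yc <- voxel_centers(ce_grid)
  xc <- apply_rigid(invert_rigid(spec$true_transform), yc)
  sc_ce <- phantom_scene(xc, geom,
                         decoy_shift = c(0, 0, spec$decoy_offset_mm))
  cls <- rep(geom$int_ce[["bg"]], nrow(xc))
  cls[sc_ce$myo] <- geom$int_ce[["myo"]]
  cls[sc_ce$lv] <- geom$int_ce[["lv"]]
  cls[sc_ce$pv] <- geom$int_ce[["pv"]]
  cls[sc_ce$la] <- geom$int_ce[["la"]]
  cls[sc_ce$laa] <- geom$int_ce[["laa"]]
  cls[sc_ce$ao] <- geom$int_ce[["ao"]]
  cls <- cls^geom$ce_gamma
  u <- sweep(yc, 2, half_fov, "/") # normalized [-1, 1] coordinates
  bias <- 1 + spec$bias_amplitude * 0.5 * (u[, 1] + u[, 2])

  # ---- flow scene on the coarse grid
  pf <- voxel_centers(flow_grid)
  sc_fl <- phantom_scene(pf, geom)
  vbas <- phantom_velocity_basis(pf, geom, sc_fl)
  blood <- sc_fl$la | sc_fl$laa | sc_fl$pv | sc_fl$ao | sc_fl$lv
  mag_base <- rep(geom$int_mag[["bg"]], nrow(pf))
  mag_base[sc_fl$myo] <- geom$int_mag[["myo"]]
  mag_base[blood] <- geom$int_mag[["blood"]]
  noisy_vel <- which(!vbas$quiet)

  nvox <- nrow(pf)
  magnitude <- array(0, c(flow_grid$shape, n_frames))
  velocity <- array(0, c(flow_grid$shape, 3, n_frames))
  ce_values <- with_seed(spec$seed, {
    ce_noise <- rnorm(nrow(yc), sd = spec$noise_sd)
    for (i in seq_len(n_frames)) {
      magnitude[, , , i] <- mag_base + rnorm(nvox, sd = spec$noise_sd)
      vi <- vbas$vb * si[i]
      vi[noisy_vel, ] <- matrix(rnorm(3 * length(noisy_vel),
                                      sd = spec$noise_sd), ncol = 3)
      velocity[, , , , i] <- vi
    }
    pmax(cls * bias + ce_noise, 0)
  })
  ce <- scalar_volume(array(ce_values, ce_grid$shape), ce_grid)
  flow <- flow_series(flow_grid, magnitude, velocity, venc = spec$venc)

  # ---- ground truth
  la_ce <- binary_mask(array(sc_ce$la, ce_grid$shape), ce_grid, "LA")
  laa_ce <- binary_mask(array(sc_ce$laa, ce_grid$shape), ce_grid, "LAA")
  pv_ce <- binary_mask(array(sc_ce$pv, ce_grid$shape), ce_grid, "PV")
  ao_ce <- binary_mask(array(sc_ce$ao, ce_grid$shape), ce_grid, "AORTA")
  la_flow <- resample_mask(la_ce, spec$true_transform, flow_grid)

  # analytic hemodynamics from the closed-form swirl at the truth-mask voxels
  sel <- as.logical(la_flow$values)
  pm <- pf[sel, , drop = FALSE]
  rho <- sqrt((pm[, 1] / s[1])^2 + (pm[, 2] / s[2])^2 + (pm[, 3] / s[3])^2)
  w <- la_speed_profile(rho, geom)
  amp <- geom$la_omega * sqrt(pm[, 1]^2 + pm[, 2]^2) * w # peak speed, m/s
  speeds <- outer(amp, si)                               # voxel x frame
  analytic_stasis <- mean(rowMeans(speeds < 0.1)) * 100
  analytic_mean_velocity <- mean(speeds) * 100

  truth <- structure(list(
    transform = spec$true_transform,
    la_mask_ce = la_ce, laa_mask_ce = laa_ce, pv_mask_ce = pv_ce,
    aorta_mask_ce = ao_ce, la_mask_flow = la_flow,
    analytic_stasis = analytic_stasis,
    analytic_mean_velocity = analytic_mean_velocity,
    la_volume_ml = volume_ml(la_ce)), class = "phantom_truth")
  list(ce = ce, flow = flow, truth = truth)
}

#' Perturb a mask to a target Dice overlap
#'
#' Randomly flips boundary voxels (adding background neighbors, removing
#' surface voxels) until the Dice coefficient against the input lands within
#' 0.02 of `target_dice`, adapting the flip fraction by bisection when a
#' step overshoots. Used to build surrogate segmentations of controlled
#' overlap for boundary-sensitivity experiments.
#'
#' @param mask A non-empty [binary_mask].
#' @param target_dice Target Dice in (0, 1) (exclusive: 1 would be the
#'   unperturbed mask).
#' @param seed Integer seed; the perturbation is deterministic given it.
#' @param max_attempts Bound on flip rounds before giving up (default 200).
#' @return A perturbed [binary_mask] on the same grid.
#' @export
perturb_mask <- function(mask, target_dice, seed = 1, max_attempts = 200) {
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask")
  if (!(target_dice > 0 && target_dice < 1))
    stop("`target_dice` must lie strictly between 0 and 1")
  if (!any(mask$values)) stop("mask is empty")
  off6 <- connectivity_offsets(6)
  dims <- mask$grid$shape
  with_seed(seed, {
    cur <- mask$values
    frac <- 0.3
    for (attempt in seq_len(max_attempts)) {
      d <- dice(binary_mask(cur, mask$grid), mask)
      if (abs(d - target_dice) <= 0.02)
        return(binary_mask(cur, mask$grid, label = mask$label))
      if (d < target_dice) { # overshot: retreat and take finer steps
        frac <- frac / 2
        cur <- last_ok
        next
      }
      cnt <- cpp_count_neighbors(as.logical(cur), dims, off6)
      surf <- which(cur & array(cnt < 6L, dims))
      halo <- which(!cur & array(cnt > 0L, dims))
      add <- halo[runif(length(halo)) < frac]
      rem <- surf[runif(length(surf)) < frac]
      last_ok <- cur
      cur[add] <- TRUE
      cur[rem] <- FALSE
      if (!any(cur)) { cur <- last_ok; frac <- frac / 2 }
    }
    stop(sprintf("target Dice %.2f not reached within %d attempts",
                 target_dice, max_attempts))
  })
}
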