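test_that("sample drawing is exhaustive at fraction 1 and exact at 0.2", {
  g <- unit_grid(c(10, 10, 10))
  all_pts <- draw_samples(g, fraction = 1, seed = 1)
  expect_identical(nrow(all_pts), 1000L)
  expect_identical(nrow(unique(all_pts)), 1000L)
  sub <- draw_samples(g, fraction = 0.2, seed = 3)
  expect_identical(nrow(sub), 200L)
  expect_identical(nrow(unique(sub)), 200L)
  expect_identical(draw_samples(g, fraction = 0.2, seed = 3), sub)
  expect_false(identical(draw_samples(g, fraction = 0.2, seed = 4), sub))
  far <- roi_box(c(100, 100, 100), c(120, 120, 120))
  expect_error(draw_samples(g, roi = far, fraction = 0.5, seed = 1),
               "disjoint")
})

test_that("self mutual information equals the marginal entropy", {
  g <- unit_grid(c(16, 16, 16))
  set.seed(5)
  vol <- scalar_volume(array(runif(16^3), c(16, 16, 16)), g)
  samples <- draw_samples(g, fraction = 1, seed = 1)
  mi <- mutual_information(vol, vol, rigid_transform(), samples)
  expect_lt(abs(mi - entropy_oracle(vol$values)), 1e-9)
})

test_that("mutual information of independent noise is near zero", {
  g <- unit_grid(c(16, 16, 16))
  samples <- draw_samples(g, fraction = 1, seed = 1)
  for (s in 1:10) {
    set.seed(s)
    a <- scalar_volume(array(runif(16^3), c(16, 16, 16)), g)
    b <- scalar_volume(array(runif(16^3), c(16, 16, 16)), g)
    hf <- entropy_oracle(a$values)
    mi <- mutual_information(a, b, rigid_transform(), samples)
    expect_lt(mi, 0.05 * hf)
  }
})

test_that("mutual information survives order-preserving intensity remaps and swaps", {
  g <- unit_grid(c(16, 16, 16))
  set.seed(9)
  a <- scalar_volume(array(runif(16^3, 1, 2), c(16, 16, 16)), g)
  remapped <- scalar_volume(3 * a$values + 7, g) # affine: bin order intact
  samples <- draw_samples(g, fraction = 1, seed = 2)
  self_mi <- mutual_information(a, a, rigid_transform(), samples)
  expect_lt(abs(mutual_information(a, remapped, rigid_transform(), samples) -
                self_mi), 1e-6)
  # histogram-axis symmetry on identical sample pairs
  set.seed(10)
  b <- scalar_volume(array(runif(16^3), c(16, 16, 16)), g)
  expect_lt(abs(mutual_information(a, b, rigid_transform(), samples) -
                mutual_information(b, a, rigid_transform(), samples)), 1e-12)
  expect_error(
    mutual_information(a, b, rigid_transform(translation = c(500, 0, 0)),
                       samples),
    "overlap")
})

test_that("alignment is a local maximum of mutual information", {
  pc <- default_pcmra()
  ph <- default_phantom()
  samples <- draw_samples(pc$grid, fraction = 0.2, seed = 6)
  mi0 <- mutual_information(pc, pc, rigid_transform(), samples)
  for (shift in c(5, 10, 15)) {
    mi_s <- mutual_information(
      pc, pc, rigid_transform(translation = c(shift, 0, 0)), samples)
    expect_gt(mi0, mi_s)
  }
})

test_that("self-registration stays at the identity", {
  pc <- default_pcmra()
  res <- register_rigid(pc, pc,
                        registration_config(sample_fraction = 0.2, seed = 3))
  d <- transform_difference(res$transform, rigid_transform(),
                            point = grid_center(pc$grid))
  expect_lt(d$translation_mm, 0.1)
  expect_lt(d$rotation_deg, 0.1)
  expect_lte(res$iterations, 1500L)
  expect_gte(res$mi_final, res$mi_initial - 1e-9)
})

test_that("registration recovers the phantom's known misalignment", {
  ph <- default_phantom()
  pc <- default_pcmra()
  res <- register_rigid(pc, ph$ce,
                        registration_config(sample_fraction = 0.2, seed = 8))
  d <- transform_difference(res$transform, ph$truth$transform,
                            point = grid_center(pc$grid))
  expect_lt(d$translation_mm, 1.5)
  expect_lt(d$rotation_deg, 1)
  la <- resample_mask(ph$truth$la_mask_ce, res$transform, ph$flow$grid)
  expect_gt(dice(la, ph$truth$la_mask_flow), 0.90)
})

test_that("registration is bit-reproducible under a fixed seed", {
  ph <- default_phantom()
  pc <- default_pcmra()
  cfg <- registration_config(sample_fraction = 0.1, seed = 12,
                             max_iterations = 400)
  r1 <- register_rigid(pc, ph$ce, cfg)
  r2 <- register_rigid(pc, ph$ce, cfg)
  expect_identical(r1$transform, r2$transform)
  expect_identical(r1$mi_final, r2$mi_final)
  expect_identical(r1$iterations, r2$iterations)
})

test_that("a hopeless start raises the quality flag instead of pretending", {
  g <- image_grid(c(24, 24, 24), spacing = c(2, 2, 2),
                  origin = c(-23, -23, -23))
  centers <- voxel_centers(g)
  blob <- function(c0) array(exp(-rowSums(sweep(centers, 2, c0)^2) / 50),
                             c(24, 24, 24))
  fixed <- scalar_volume(blob(c(-12, 0, 0)), g)
  moving <- scalar_volume(blob(c(28, 0, 0)), g) # 40 mm apart: no shared anatomy
  res <- register_rigid(fixed, moving,
                        registration_config(sample_fraction = 0.5, seed = 2,
                                            max_iterations = 150))
  expect_true(res$quality$flagged || !res$converged)
})

test_that("segment boxes include the half-voxel rim, margins and unions", {
  g <- unit_grid(c(5, 5, 5), origin = c(-2, -2, -2)) # voxel centers -2..2
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE # world (0, 0, 0)
  roi <- roi_from_segments(binary_mask(one, g), margin_mm = 20)
  expect_equal(roi$min_corner, c(-20.5, -20.5, -20.5))
  expect_equal(roi$max_corner, c(20.5, 20.5, 20.5))
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  roi0 <- roi_from_segments(binary_mask(cube, g), margin_mm = 0)
  expect_equal(roi0$min_corner, c(-1.5, -1.5, -1.5))
  expect_equal(roi0$max_corner, c(1.5, 1.5, 1.5))
  two_a <- array(FALSE, c(5, 5, 5)); two_a[1, 1, 1] <- TRUE
  two_b <- array(FALSE, c(5, 5, 5)); two_b[5, 5, 5] <- TRUE
  roi2 <- roi_from_segments(list(binary_mask(two_a, g), binary_mask(two_b, g)),
                            margin_mm = 0)
  expect_equal(roi2$min_corner, c(-2.5, -2.5, -2.5))
  expect_equal(roi2$max_corner, c(2.5, 2.5, 2.5))
  empty <- binary_mask(array(FALSE, c(5, 5, 5)), g)
  expect_error(roi_from_segments(empty), "empty")
})

test_that("both rounds agree on a clean phantom and reject disjoint ROIs", {
  ph <- default_phantom() # no decoy structure offset
  pc <- default_pcmra()
  segs <- list(ph$truth$la_mask_ce, ph$truth$pv_mask_ce)
  res <- two_round_register(
    pc, ph$ce, segs,
    cfg1 = registration_config(sample_fraction = 0.2, seed = 31),
    cfg2 = registration_config(sample_fraction = 1.0, seed = 31))
  expect_identical(res$round_index, 2L)
  expect_length(res$rounds, 2)
  d <- transform_difference(res$rounds[[1]]$transform,
                            res$rounds[[2]]$transform,
                            point = grid_center(pc$grid))
  expect_lt(d$translation_mm, 1)
  expect_lt(d$rotation_deg, 1)
  bad <- registration_config(
    sample_fraction = 1.0, seed = 31,
    roi = roi_box(c(500, 500, 500), c(600, 600, 600)))
  expect_error(two_round_register(pc, ph$ce, segs, cfg2 = bad), "disjoint")
})
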