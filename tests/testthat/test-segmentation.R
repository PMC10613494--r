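test_that("bias correction flattens multiplicative shading and keeps flat fields", {
  g <- image_grid(c(100, 100, 100), spacing = c(2, 2, 2))
  flat <- scalar_volume(array(3, c(100, 100, 100)), g)
  out <- bias_correct(flat)
  expect_lt(max(abs(out$values - 3)) / 3, 1e-6)
  # constant object under a 0.5 -> 1.5 multiplicative ramp across the FOV
  ramp <- array(rep(seq(0.5, 1.5, length.out = 100), times = 100^2),
                c(100, 100, 100))
  v <- scalar_volume(ramp, g)
  corr <- bias_correct(v)
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(v$values) / cv(corr$values), 5)
  # overall intensity scale is preserved
  expect_equal(mean(corr$values), mean(v$values), tolerance = 1e-12)
  zero <- scalar_volume(array(0, c(100, 100, 100)), g)
  expect_warning(z <- bias_correct(zero), "all-zero")
  expect_equal(z$values, zero$values)
})

test_that("region growing floods exactly the seeded bright component", {
  g <- unit_grid(c(20, 20, 20))
  vals <- array(0, c(20, 20, 20))
  vals[3:8, 3:8, 3:8] <- 10      # blob 1
  vals[13:18, 13:18, 13:18] <- 10 # blob 2, separated by dark gap
  vol <- scalar_volume(vals, g)
  sp <- seed_spec(c(4, 4, 4), lower = 5, upper = 15, label = "LA")
  m <- region_grow(vol, sp)
  expected <- array(FALSE, c(20, 20, 20))
  expected[3:8, 3:8, 3:8] <- TRUE
  expect_identical(m$values, expected)
  expect_identical(m$label, "LA")
  # uniform volume: everything is connected to the seed
  uni <- scalar_volume(array(7, c(20, 20, 20)), g)
  full <- region_grow(uni, seed_spec(c(10, 10, 10), 0, 10))
  expect_true(all(full$values))
  # seed in the dark gap is rejected by name
  expect_error(region_grow(vol, seed_spec(c(10.5, 10.5, 10.5), 5, 15)),
               "seed 1 rejected")
})

test_that("region growing agrees with a brute-force flood-fill oracle", {
  g <- unit_grid(c(12, 12, 12))
  for (s in 1:8) {
    set.seed(s)
    vals <- array(runif(12^3), c(12, 12, 12))
    eligible <- vals >= 0.4 & vals <= 1
    seed_lin <- sample(which(eligible), 1)
    seed_idx <- arrayInd(seed_lin, c(12, 12, 12)) - 1 # 0-based
    seed_world <- drop(world_from_index(g, seed_idx))
    got <- region_grow(scalar_volume(vals, g),
                       seed_spec(seed_world, 0.4, 1))
    expect_identical(got$values, flood_oracle(eligible, seed_lin))
  }
})

test_that("median/closing refinement preserves solids, fills holes, removes specks", {
  g <- unit_grid(c(28, 28, 28))
  cube <- array(FALSE, c(28, 28, 28))
  cube[5:24, 5:24, 5:24] <- TRUE
  refined <- refine_segment(binary_mask(cube, g), kernel_mm = 3)
  expect_lt(abs(sum(refined$values) - sum(cube)) / sum(cube), 0.05)
  # interior hole is closed
  holed <- cube
  holed[14, 14, 14] <- FALSE
  filled <- refine_segment(binary_mask(holed, g), kernel_mm = 3)
  expect_true(filled$values[14, 14, 14])
  # an isolated voxel is a median minority and disappears
  speck <- array(FALSE, c(28, 28, 28))
  speck[14, 14, 14] <- TRUE
  expect_false(any(refine_segment(binary_mask(speck, g), 3)$values))
})

test_that("refinement is near-idempotent on chamber-scale convex shapes", {
  # atrium-sized ellipsoid at angiography resolution: after one pass the
  # filter has settled (binary medians act as curvature flow, so perfect
  # idempotence is only approached when the kernel is small relative to the
  # surface curvature radius, as it is for real chambers)
  g <- image_grid(c(64, 64, 64), spacing = c(1.2, 1.2, 1.2),
                  origin = rep(-37.8, 3))
  centers <- voxel_centers(g)
  ell <- array((centers[, 1] / 30)^2 + (centers[, 2] / 25)^2 +
                 (centers[, 3] / 20)^2 <= 1, c(64, 64, 64))
  once <- refine_segment(binary_mask(ell, g), 3)
  twice <- refine_segment(once, 3)
  changed <- sum(xor(once$values, twice$values))
  expect_lt(changed / sum(once$values), 0.01)
})

test_that("plane cuts partition the mask and keep one component", {
  g <- unit_grid(c(12, 12, 24))
  box <- array(FALSE, c(12, 12, 24))
  box[2:11, 2:11, 3:22] <- TRUE # 10 x 10 x 20 solid box
  m <- binary_mask(box, g)
  # mid-plane along z between voxel indices 12 and 13 (world 11.5 and 12.5)
  cut <- cut_at_plane(m, plane_point = c(0, 0, 12), plane_normal = c(0, 0, 1),
                      keep_point = c(6, 6, 20))
  expect_identical(sum(cut$kept$values), 1000L)
  expect_identical(sum(cut$removed$values), 1000L)
  # partition: kept and removed tile the input exactly
  expect_identical(cut$kept$values | cut$removed$values, box)
  expect_false(any(cut$kept$values & cut$removed$values))
  # plane outside the bounding box: no-op
  all_cut <- cut_at_plane(m, c(0, 0, -5), c(0, 0, 1), c(6, 6, 20))
  expect_identical(all_cut$kept$values, box)
  expect_false(any(all_cut$removed$values))
  expect_error(cut_at_plane(m, c(0, 0, 12), c(0, 0, 1), c(0, 0, 0)),
               "not inside")
})

test_that("cutting a dumbbell at the neck leaves one connected lobe", {
  g <- unit_grid(c(30, 12, 12))
  v <- array(FALSE, c(30, 12, 12))
  v[2:12, 2:11, 2:11] <- TRUE   # lobe A
  v[18:28, 2:11, 2:11] <- TRUE  # lobe B
  v[13:17, 6:7, 6:7] <- TRUE    # thin neck
  m <- binary_mask(v, g)
  cut <- cut_at_plane(m, plane_point = c(15, 0, 0), plane_normal = c(1, 0, 0),
                      keep_point = c(5, 5, 5))
  labs <- unique(as.integer(
    atrialign:::cpp_label_components(as.logical(cut$kept$values),
                                     g$shape, 6L)))
  expect_identical(sort(setdiff(labs, 0L)), 1L)
  expect_identical(cut$kept$values | cut$removed$values, v)
})
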