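test_that("mask volume follows voxel count and voxel size", {
  g <- unit_grid(c(10, 10, 10))
  full <- binary_mask(array(TRUE, c(10, 10, 10)), g)
  expect_equal(volume_ml(full), 1.0)
  empty <- binary_mask(array(FALSE, c(10, 10, 10)), g)
  expect_equal(volume_ml(empty), 0)
  # digitized ellipsoid vs closed form 4/3 pi abc
  ge <- image_grid(c(70, 60, 50), spacing = c(1, 1, 1))
  centers <- voxel_centers(ge)
  rel <- sweep(centers, 2, c(34.5, 29.5, 24.5))
  inside <- (rel[, 1] / 30)^2 + (rel[, 2] / 25)^2 + (rel[, 3] / 20)^2 <= 1
  ell <- binary_mask(array(inside, c(70, 60, 50)), ge)
  expect_lt(abs(volume_ml(ell) - 4 / 3 * pi * 30 * 25 * 20 / 1000) /
            (4 / 3 * pi * 30 * 25 * 20 / 1000), 0.02)
  # anisotropic voxels scale the volume by the voxel determinant
  g2 <- image_grid(c(10, 10, 10), spacing = c(2, 2, 2))
  full2 <- binary_mask(array(TRUE, c(10, 10, 10)), g2)
  expect_equal(volume_ml(full2), 8.0)
})

test_that("Dice matches set arithmetic and rejects degenerate input", {
  g <- unit_grid(c(10, 10, 10))
  a <- array(FALSE, c(10, 10, 10)); a[1:4, , ] <- TRUE
  expect_equal(dice(binary_mask(a, g), binary_mask(a, g)), 1.0)
  b <- array(FALSE, c(10, 10, 10)); b[6:9, , ] <- TRUE
  expect_equal(dice(binary_mask(a, g), binary_mask(b, g)), 0.0)
  # |A| = |B| = 100, |A intersect B| = 50
  a2 <- array(FALSE, c(10, 10, 10)); a2[1:10, 1:10, 1] <- TRUE
  b2 <- array(FALSE, c(10, 10, 10)); b2[1:10, 1:10, 2] <- TRUE
  b2[1:10, 1:5, 2] <- FALSE; b2[1:10, 1:5, 1] <- TRUE
  expect_identical(sum(a2), 100L); expect_identical(sum(b2), 100L)
  expect_identical(sum(a2 & b2), 50L)
  expect_equal(dice(binary_mask(a2, g), binary_mask(b2, g)), 0.5)
  empty <- binary_mask(array(FALSE, c(10, 10, 10)), g)
  expect_error(dice(empty, empty), "empty")
  g2 <- unit_grid(c(10, 10, 10), origin = c(5, 0, 0))
  expect_error(dice(binary_mask(a, g), binary_mask(a, g2)), "grids")
})

test_that("surface voxels are the exposed shell, growing with connectivity", {
  g <- unit_grid(c(5, 5, 5))
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  s6 <- surface_voxels(binary_mask(cube, g), 6)
  expect_identical(sum(s6$values), 26L) # all but the center of 3^3
  expect_false(s6$values[3, 3, 3])
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  s1 <- surface_voxels(binary_mask(one, g), 6)
  expect_identical(s1$values, one)
  g10 <- unit_grid(c(14, 14, 14))
  big <- array(FALSE, c(14, 14, 14)); big[3:12, 3:12, 3:12] <- TRUE
  m10 <- binary_mask(big, g10)
  s6b <- surface_voxels(m10, 6)$values
  s26b <- surface_voxels(m10, 26)$values
  expect_true(all(s26b[s6b]))      # 26-surface contains the 6-surface
  # on curved (staircased) boundaries the 26-surface is strictly larger
  g20 <- unit_grid(c(20, 20, 20))
  centers <- voxel_centers(g20)
  ball <- binary_mask(array(rowSums(sweep(centers, 2, rep(9.5, 3))^2) <= 49,
                            c(20, 20, 20)), g20)
  sb6 <- surface_voxels(ball, 6)$values
  sb26 <- surface_voxels(ball, 26)$values
  expect_true(all(sb26[sb6]))
  expect_gt(sum(sb26), sum(sb6))
  expect_error(surface_voxels(binary_mask(array(FALSE, c(5, 5, 5)), g)),
               "empty")
})

test_that("surface agrees with the exhaustive neighbor-check oracle", {
  g <- unit_grid(c(12, 12, 12))
  for (s in 1:6) {
    m <- random_mask(g, s + 40)
    expect_identical(surface_voxels(m, 6)$values,
                     surface_oracle(m$values))
  }
})

test_that("surface distance handles the closed-form two-voxel case", {
  g <- image_grid(c(8, 8, 8), spacing = c(1, 1, 1))
  a <- array(FALSE, c(8, 8, 8)); a[2, 2, 2] <- TRUE
  b <- array(FALSE, c(8, 8, 8)); b[5, 2, 2] <- TRUE # 3 mm apart along x
  expect_equal(assd(binary_mask(a, g), binary_mask(b, g)), 3.0)
  expect_equal(assd(binary_mask(a, g), binary_mask(a, g)), 0.0)
  expect_error(assd(binary_mask(a, g),
                    binary_mask(array(FALSE, c(8, 8, 8)), g)), "empty")
})

test_that("surface distance matches the brute-force oracle and is symmetric", {
  g <- unit_grid(c(12, 12, 12))
  for (s in 1:5) {
    a <- random_mask(g, s)
    b <- random_mask(g, s + 100)
    expect_lt(abs(assd(a, b) - assd_oracle(a, b)), 1e-9)
    expect_lt(abs(assd(a, b) - assd(b, a)), 1e-12)
  }
})

test_that("doubling the voxel size doubles distances and octuples volumes", {
  g1 <- unit_grid(c(12, 12, 12))
  g2 <- image_grid(c(12, 12, 12), spacing = c(2, 2, 2))
  a1 <- random_mask(g1, 7); b1 <- random_mask(g1, 8)
  a2 <- binary_mask(a1$values, g2); b2 <- binary_mask(b1$values, g2)
  expect_equal(assd(a2, b2), 2 * assd(a1, b1))
  expect_equal(volume_ml(a2), 8 * volume_ml(a1))
})

test_that("agreement statistics recover constant offsets and perfect linearity", {
  x <- c(10, 12, 15, 18, 22)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_difference, 0)
  expect_equal(ba0$loa_low, 0); expect_equal(ba0$loa_high, 0)
  expect_equal(ba0$pearson_r, 1)
  ba <- bland_altman(x, x + 5)
  expect_equal(ba$mean_difference, -5)
  expect_equal(ba$loa_low, -5); expect_equal(ba$loa_high, -5)
  expect_equal(bland_altman(x, 2 * x + 1)$pearson_r, 1)
  expect_error(bland_altman(x, x[1:3]), "equal length")
  expect_error(bland_altman(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(bland_altman(c(1, 2), c(1, 2)), "at least 3")
})

test_that("Dice is symmetric and bounded on random mask pairs", {
  g <- unit_grid(c(10, 10, 10))
  for (s in 1:50) {
    a <- random_mask(g, s); b <- random_mask(g, s + 1000)
    d1 <- dice(a, b)
    expect_identical(d1, dice(b, a))
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
})
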