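test_that("image_grid validates geometry and values", {
  g <- image_grid(array(0, c(4, 4, 2)), spacing = c(1, 1, 2),
                  origin = c(-1, -1, 0), unit = "HU")
  expect_identical(dim(g), c(4L, 4L, 2L))
  expect_error(image_grid(array(0, c(4, 4, 2)), spacing = c(1, 1, 0)),
               "spacing")
  expect_error(image_grid(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)), "finite")
  expect_error(image_grid(matrix(0, 2, 2), c(1, 1, 1)), "3D")
  ax <- grid_axes(g)
  expect_equal(ax$x, c(-1, 0, 1, 2))
  expect_equal(ax$z, c(0, 2))
})

test_that("NIfTI round trip preserves shape, spacing, origin, values, unit", {
  set.seed(42)
  vals <- array(rnorm(10 * 10 * 10), c(10, 10, 10))
  g <- image_grid(vals, spacing = c(1, 1, 2), origin = c(-10, -20, 5),
                  unit = "cGy")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(g, path, seed = 42L)
  h <- read_volume(path)
  expect_identical(dim(h), dim(g))
  expect_true(all(abs(h$spacing - g$spacing) < 1e-4))
  expect_true(all(abs(h$origin - g$origin) < 1e-3))
  rng <- diff(range(vals))
  expect_lt(max(abs(h$values - g$values)), 1e-6 * rng)
  expect_identical(h$unit, "cGy")

  z <- image_grid(array(0, c(10, 10, 10)), c(1, 1, 1))
  path2 <- withr::local_tempfile(fileext = ".nii")
  write_volume(z, path2)
  expect_equal(read_volume(path2)$values, z$values)
})

test_that("volume I/O rejects unreadable paths and bad extensions", {
  expect_error(read_volume(file.path(tempdir(), "no-such-file.nii.gz")),
               "no-such-file")
  g <- uniform_grid(0)
  expect_error(write_volume(g, file.path(tempdir(), "vol.txt")), "nii")
})

test_that("mask round trip through uint8 NIfTI", {
  g <- uniform_grid(0, dims = c(8, 8, 4), spacing = c(2, 2, 2))
  mask <- array(FALSE, dim(g)); mask[2:4, 3:5, 1:2] <- TRUE
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(mask, g, path)
  back <- read_mask(path)
  expect_identical(back$mask, mask)
})

test_that("assert_aligned is a pure predicate over lattice geometry", {
  a <- uniform_grid(1)
  expect_true(assert_aligned(a, a))
  b <- a; b$origin <- a$origin + c(1, 0, 0)
  expect_false(assert_aligned(a, b))
  c <- image_grid(array(0, c(10, 10, 11)), c(1, 1, 1))
  expect_false(assert_aligned(a, c))
  d <- a; d$origin <- a$origin + c(5e-4, 0, 0) # within tolerance
  expect_true(assert_aligned(a, d))
})

test_that("mask_volume_cc counts voxel volume and is additive", {
  g1 <- uniform_grid(0, dims = c(10, 10, 10), spacing = c(1, 1, 1))
  expect_equal(mask_volume_cc(array(TRUE, dim(g1)), g1), 1.0)
  expect_equal(mask_volume_cc(array(FALSE, dim(g1)), g1), 0.0)
  # 125 voxels at 2 mm isotropic = 125 * 8 mm3 = 1 cm3
  g2 <- uniform_grid(0, dims = c(10, 10, 10), spacing = c(2, 2, 2))
  m <- array(FALSE, dim(g2)); m[1:5, 1:5, 1:5] <- TRUE
  expect_equal(mask_volume_cc(m, g2), 1.0)
  # additivity over disjoint masks
  m2 <- array(FALSE, dim(g2)); m2[6:9, 1:3, 1:2] <- TRUE
  expect_equal(mask_volume_cc(m | m2, g2),
               mask_volume_cc(m, g2) + mask_volume_cc(m2, g2))
  expect_error(mask_volume_cc(array(TRUE, c(2, 2, 2)), g2), "aligned")
})

test_that("voxel-world mapping is consistent with trilinear sampling", {
  vals <- array(0, c(5, 5, 5))
  vals[3, 4, 2] <- 10
  g <- image_grid(vals, spacing = c(2, 2, 2), origin = c(1, 1, 1))
  # voxel (3,4,2) in 1-based R indexing = 0-based (2,3,1) -> world (5,7,3)
  expect_equal(spacerdose:::interp_trilinear(g, rbind(c(5, 7, 3))), 10)
  expect_equal(spacerdose:::interp_trilinear(g, rbind(c(6, 7, 3))), 5)
})

test_that("validate_rois enforces the CTV union and spacer disjointness", {
  g <- uniform_grid(0, dims = c(6, 6, 6))
  pro <- array(FALSE, dim(g)); pro[2:3, 2:3, 2:3] <- TRUE
  sv <- array(FALSE, dim(g)); sv[5, 5, 5] <- TRUE
  spacer <- array(FALSE, dim(g)); spacer[1, 1, 1] <- TRUE
  rois <- list(prostate = pro, seminal_vesicles = sv, ctv = pro | sv,
               spacer = spacer)
  expect_silent(validate_rois(rois, g))
  rois$ctv <- pro # drops the SV voxel
  expect_error(validate_rois(rois, g), "ctv")
  rois$ctv <- pro | sv
  rois$spacer <- pro
  expect_error(validate_rois(rois, g), "overlap")
  rois$spacer <- array(FALSE, dim(g))
  expect_error(validate_rois(rois, g), "empty")
})
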