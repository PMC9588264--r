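test_that("molecular components expand to elemental weight fractions", {
  w <- material_from_components(c(water = 1), density = 1.0)
  # H2O: 2*1.008 / 18.015 and 15.999 / 18.015
  expect_equal(unname(w$elements["H"]), 0.1119, tolerance = 1e-3)
  expect_equal(unname(w$elements["O"]), 0.8881, tolerance = 1e-3)

  sp <- spacer_material()
  expect_equal(unname(sp$elements["I"]), 0.012, tolerance = 1e-9)
  expect_equal(sum(sp$elements), 1, tolerance = 1e-6)
  expect_equal(sp$density, 1.03)
  expect_true(all(c("H", "C", "N", "O", "I") %in% names(sp$elements)))

  expect_error(material_from_components(c(water = 0.9), 1.0), "sum")
  expect_error(material_from_components(c(unobtainium = 1), 1.0), "unknown")
  expect_error(material_spec(c(H = 0.5, O = 0.5), density = -1), "density")
})

test_that("theoretical SPR: water self-ratio, density scaling, spacer value", {
  water <- material_from_components(c(water = 1), 1.0)
  expect_equal(compute_spr(water, 100), 1.0, tolerance = 1e-12)
  expect_equal(compute_spr(water, 250), 1.0, tolerance = 1e-12)

  dense_water <- material_from_components(c(water = 1), 1.10)
  expect_equal(compute_spr(dense_water, 150), 1.10, tolerance = 1e-6)

  # the spacer composition at the verification energy
  expect_equal(compute_spr(spacer_material(), 198.3), 1.03, tolerance = 0.01)

  expect_error(compute_spr(spacer_material(), 0.5), "energy")
  expect_error(compute_spr(spacer_material(), 500), "energy")
})

test_that("SPR is continuous and monotone in density at fixed composition", {
  rhos <- seq(0.9, 1.2, by = 0.02)
  sprs <- vapply(rhos, function(r)
    compute_spr(material_from_components(
      c(water = 0.88, trilysine = 0.007, PEG = 0.101, I = 0.012), r), 198.3),
    numeric(1))
  expect_true(all(diff(sprs) > 0))
  # linear in density: ratios equal density ratios
  expect_equal(sprs[2] / sprs[1], rhos[2] / rhos[1], tolerance = 1e-9)
})

test_that("power-law effective Z: single element, water, spacer", {
  oxy <- material_spec(c(O = 1), 1.0)
  expect_equal(effective_z(oxy, 3.5), 8)
  expect_equal(effective_z(oxy, 2.0), 8)
  expect_equal(effective_z(material_from_components(c(water = 1), 1.0)), 7.5,
               tolerance = 0.01)
  expect_equal(effective_z(spacer_material()), 14.47, tolerance = 0.02 * 14.47)
  expect_error(effective_z(oxy, 0), "m must be")
})

test_that("HU curve validation and piecewise-linear lookup", {
  cv <- default_hu_curve()
  expect_equal(hu_to_spr(0, cv), 1.0)
  expect_equal(hu_to_spr(-1000, cv), 0.001)
  expect_equal(hu_to_spr(-2000, cv), 0.001) # clamped to the end knot
  expect_equal(hu_to_spr(120, cv), 1.11, tolerance = 1e-9)
  arr <- array(c(0, 120, -1000, 100), c(2, 2, 1))
  out <- hu_to_spr(arr, cv)
  expect_identical(dim(out), dim(arr))
  expect_equal(out[2, 1, 1], 1.11)

  expect_error(hu_curve(data.frame(hu = 0, spr = 1)), "2 knots")
  expect_error(hu_curve(data.frame(hu = c(0, 0), spr = c(1, 1.1))),
               "increasing")
  expect_error(hu_curve(data.frame(hu = c(-100, 0), spr = c(1.2, 1))),
               "non-decreasing")
  expect_error(hu_curve(data.frame(hu = c(-100, 100), spr = c(0.9, 1.3))),
               "pass")
})

test_that("scenario override logic only changes spacer voxels", {
  hu <- uniform_grid(40, dims = c(8, 8, 4), unit = "HU")
  hu$values[5:6, 5:6, 2:3] <- 120
  spacer <- array(FALSE, dim(hu)); spacer[5:6, 5:6, 2:3] <- TRUE
  rois <- list(spacer = spacer)

  nm <- build_spr_grid(hu, rois, "NM")
  wm <- build_spr_grid(hu, rois, "WM")
  tm <- build_spr_grid(hu, rois, "TM")

  expect_equal(unique(as.vector(nm$values[spacer])), 1.11, tolerance = 1e-9)
  expect_equal(unique(as.vector(wm$values[spacer])), 1.0)
  expect_equal(unique(as.vector(tm$values[spacer])), 1.03, tolerance = 0.01)
  # identical outside the spacer
  expect_equal(nm$values[!spacer], wm$values[!spacer])
  expect_equal(nm$values[!spacer], tm$values[!spacer])
  # the ordering that drives the material-discrepancy effect
  expect_gt(nm$values[5, 5, 2], tm$values[5, 5, 2])
  expect_gt(tm$values[5, 5, 2], wm$values[5, 5, 2])

  expect_error(build_spr_grid(hu, list(), "NM"), "spacer")
  expect_error(scenario("XX"), "arg")
})

test_that("bundled materials table reproduces the spacer recipe", {
  mats <- load_materials()
  expect_true("iodinated_hydrogel" %in% names(mats))
  expect_equal(compute_spr(mats$iodinated_hydrogel, 198.3),
               compute_spr(spacer_material(), 198.3))
})
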