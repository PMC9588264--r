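test_that("Bragg-Kleeman range law", {
  md <- depth_dose_model()
  # closed form: 0.0022 * 198.3^1.77
  expect_equal(bragg_range(198.3, md), 0.0022 * 198.3^1.77)
  expect_equal(bragg_range(198.3, md), 25.63, tolerance = 0.01)
  # doubling the energy scales range by 2^p
  expect_equal(bragg_range(200, md) / bragg_range(100, md), 2^1.77)
  expect_error(bragg_range(0, md), "> 0")
  expect_equal(range_to_energy(bragg_range(150, md), md), 150)
})

test_that("SOBP plateau is flat and falls off sharply past the distal edge", {
  md <- depth_dose_model()
  for (iv in list(c(150, 200), c(80, 120))) {
    s <- build_sobp(iv[1], iv[2], md)
    expect_true(all(s$weights >= 0))
    dep <- seq(iv[1], iv[2], by = 1)
    curve <- spacerdose:::eval_sobp(s, dep, md)
    expect_lt(max(abs(curve / mean(curve) - 1)), 0.03)
    expect_lt(spacerdose:::eval_sobp(s, iv[2] + 8, md) / mean(curve), 0.10)
    expect_lt(spacerdose:::eval_sobp(s, iv[2] + 10, md) / mean(curve), 0.10)
  }
  # single-layer request: one pristine peak with weight 1 peaking at depth
  s1 <- build_sobp(180, 180, md)
  expect_length(s1$weights, 1)
  expect_equal(s1$weights, 1)
  peak_dose <- spacerdose:::eval_sobp(s1, seq(100, 220, by = 0.5), md)
  expect_equal(seq(100, 220, by = 0.5)[which.max(peak_dose)], 180,
               tolerance = 1)
  expect_error(build_sobp(150, 100, md), "d_prox")
  expect_error(build_sobp(100, 5000, md), "deliverable")
})

test_that("WEPL tracing: uniform medium, slab arithmetic, fine-step oracle", {
  u <- uniform_grid(1, dims = c(40, 20, 20), spacing = c(3, 3, 3),
                    unit = "SPR")
  r <- ray(entry = c(-10, 28.5, 28.5), direction = c(1, 0, 0), step = 1)
  tr <- wepl_trace(u, r)
  i <- which.min(abs(tr$t - 100))
  expect_lt(abs(tr$wepl[i] - tr$t[i]), 0.5)
  expect_true(all(diff(tr$wepl) >= 0))

  # a 4-voxel slab of SPR 2 at 3 mm spacing adds 12 mm of extra
  # water-equivalent depth
  slab <- u
  ax <- grid_axes(u)
  slab$values[ax$x >= 30 & ax$x < 40, , ] <- 2
  ts <- wepl_trace(slab, r)
  expect_lt(abs((max(ts$wepl) - max(tr$wepl)) - 12), 0.5)

  # oblique ray through a layered grid vs a 10x finer quadrature
  set.seed(1)
  lay <- u
  prof <- runif(40, 0.8, 1.6)
  lay$values <- array(prof, dim(u)) # varies along x only
  ro <- ray(entry = c(-5, 5, 5), direction = c(1, 0.35, 0.2), step = 1)
  ro_fine <- ray(entry = ro$entry, direction = ro$direction, step = 0.15)
  w1t <- wepl_trace(lay, ro)
  w2t <- wepl_trace(lay, ro_fine)
  tc <- max(w1t$t)
  w1 <- max(w1t$wepl)
  w2 <- approx(w2t$t, w2t$wepl, xout = tc)$y
  expect_lt(abs(w1 - w2) / w2, 0.005)

  expect_warning(tr0 <- wepl_trace(u, ray(c(0, -500, 0), c(1, 0, 0))),
                 "misses")
  expect_identical(nrow(tr0), 0L)
  expect_error(ray(c(0, 0, 0), c(0, 0, 0)), "nonzero")
  expect_error(ray(c(0, 0, 0), c(1, 0, 0), step = 0), "step")
})

test_that("plan optimization meets the coverage objective on a water box", {
  # water-box phantom with a spherical CTV
  dims <- c(50L, 40L, 30L)
  spr <- uniform_grid(1, dims = dims, spacing = c(4, 4, 4), unit = "SPR")
  ax <- grid_axes(spr)
  ctv <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    ctv[, , k] <- outer((ax$x - 100)^2, (ax$y - 80)^2, "+") +
      (ax$z[k] - 60)^2 <= 25^2
  }
  md <- depth_dose_model()
  plan <- optimize_plan(spr, list(ctv = ctv), 7000, md)
  dose <- compute_dose(plan, spr, md)
  expect_equal(d_at_percent(dose, ctv, 95)$d_x, 7000, tolerance = 0.01 * 7000)
  expect_gte(mean(dose$values[ctv] >= 7000), 0.95)
  expect_true(all(dose$values >= 0))

  # dose is linear in the prescription (global fluence scale)
  plan2 <- plan; plan2$scale <- 2 * plan$scale
  dose2 <- compute_dose(plan2, spr, md)
  expect_equal(dose2$values, 2 * dose$values, tolerance = 1e-12)

  # recomputing on the optimization grid reproduces the dose bit-identically
  expect_identical(compute_dose(plan, spr, md)$values, dose$values)

  expect_error(optimize_plan(spr, list(ctv = array(FALSE, dims)), 7000, md),
               "empty")
})

test_that("a one-voxel CTV still yields a valid two-beam plan", {
  dims <- c(40L, 24L, 24L)
  spr <- uniform_grid(1, dims = dims, spacing = c(4, 4, 4), unit = "SPR")
  ctv <- array(FALSE, dims); ctv[20, 12, 12] <- TRUE
  md <- depth_dose_model()
  plan <- optimize_plan(spr, list(ctv = ctv), 7000, md)
  expect_length(plan$beams, 2)
  dose <- compute_dose(plan, spr, md)
  expect_gte(dose$values[20, 12, 12], 7000 * 0.99)
})

test_that("raising spacer SPR above the true value pulls dose off the CTV", {
  case <- reduced_case()
  hot <- case$spr$TM
  hot$values[case$rois$spacer] <- 1.6
  d_hot <- compute_dose(case$plan, hot, case$model)
  expect_lt(mean(d_hot$values[case$rois$ctv]),
            mean(case$dose$TM$values[case$rois$ctv]))
})

test_that("zero fluence gives zero dose", {
  case <- reduced_case()
  p0 <- case$plan; p0$scale <- 0
  d0 <- compute_dose(p0, case$spr$TM, case$model)
  expect_true(all(d0$values == 0))
})
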