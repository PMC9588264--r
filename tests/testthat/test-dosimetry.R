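make_dose <- function(values_fn, dims = c(10, 10, 10), spacing = c(2, 2, 2)) {
  n <- prod(dims)
  image_grid(array(values_fn(n), dims), spacing, unit = "cGy")
}

test_that("DVH invariants: uniform and bimodal structures", {
  g <- make_dose(function(n) rep(7000, n))
  mask <- array(TRUE, dim(g))
  h <- dvh(g, mask)
  expect_equal(sum(h$bins$diff_frac), 1, tolerance = 1e-9)
  expect_true(all(diff(h$bins$cum_frac) <= 0))
  expect_equal(h$bins$cum_frac[1], 1) # V(0) = 1
  occupied <- which(h$bins$diff_frac > 0)
  expect_length(occupied, 1)
  expect_true(abs(h$bins$dose[occupied] - 7000) <= h$bin_width)

  half <- make_dose(function(n) rep(c(6000, 7000), n / 2))
  hh <- dvh(half, mask)
  # V(6500) = 0.5
  i <- max(which(hh$bins$edge <= 6500))
  expect_equal(hh$bins$cum_frac[i], 0.5)
  expect_error(dvh(g, array(FALSE, dim(g))), "empty")
})

test_that("cumulative DVH matches a direct sort-based oracle", {
  set.seed(8)
  g <- make_dose(function(n) 8000 * runif(n))
  mask <- array(TRUE, dim(g))
  h <- dvh(g, mask, bin_width = 10)
  doses <- g$values[mask]
  for (d0 in c(500, 2500, 5000, 7900)) {
    i <- max(which(h$bins$edge <= d0))
    oracle <- mean(doses >= h$bins$edge[i])
    expect_equal(h$bins$cum_frac[i], oracle, tolerance = 1e-12)
  }
})

test_that("Dx from order statistics: uniform, ramp, median coincidence", {
  g <- make_dose(function(n) rep(7000, n))
  mask <- array(TRUE, dim(g))
  r <- d_at_percent(g, mask, c(2, 95))
  expect_equal(r$d_x, c(7000, 7000))
  expect_equal(r$mean_dose, c(7000, 7000))

  # doses spanning 0..10000 uniformly: D95 ~ 5th percentile = 500
  ramp <- make_dose(function(n) seq(0, 10000, length.out = n))
  expect_equal(d_at_percent(ramp, mask, 95)$d_x, 500, tolerance = 15)
  # D50 is the median
  expect_equal(d_at_percent(ramp, mask, 50)$d_x,
               median(ramp$values), tolerance = 15)
  # monotone non-increasing in x
  dx <- d_at_percent(ramp, mask, c(2, 5, 20, 50, 95, 98))$d_x
  expect_true(all(diff(dx) <= 0))
  expect_error(d_at_percent(ramp, mask, 0), "x must be")
})

test_that("EUD closed forms and monotonicity in the exponent", {
  expect_equal(eud(rep(4200, 50), a = -10), 4200)
  expect_equal(eud(rep(4200, 50), a = 8), 4200)
  set.seed(3)
  doses <- 7000 * runif(200)
  expect_equal(eud(doses, a = 1), mean(doses))
  # two-compartment hand value: (0.5*6000^8 + 0.5*7000^8)^(1/8)
  expect_equal(eud(c(6000, 7000), a = 8),
               (0.5 * 6000^8 + 0.5 * 7000^8)^(1 / 8))
  expect_equal(eud(c(6000, 7000), a = 8), 6633, tolerance = 5)
  # power-mean inequality: EUD non-decreasing in a
  as_ <- c(-10, -2, 1, 2, 8, 20)
  euds <- vapply(as_, function(a) eud(doses, a = a), numeric(1))
  expect_true(all(diff(euds) >= 0))
  expect_true(all(euds >= min(doses) - 0.1 & euds <= max(doses)))
  # large a approaches the maximum dose
  expect_equal(eud(doses, a = 200), max(doses), tolerance = 0.05 * max(doses))
  expect_error(eud(doses, a = 0), "nonzero")
  # zero-dose floor keeps negative exponents finite
  expect_true(is.finite(eud(c(0, 7000), a = -10)))
})

test_that("dose grid and dvh routes agree for EUD", {
  set.seed(9)
  g <- make_dose(function(n) 6500 + 500 * runif(n))
  mask <- array(FALSE, dim(g)); mask[3:8, 3:8, 3:8] <- TRUE
  direct <- eud(g, a = 8, mask = mask)
  binned <- eud(dvh(g, mask, bin_width = 10), a = 8)
  expect_equal(direct, binned, tolerance = 10) # within a bin width
})

test_that("constraint report evaluates every rule type", {
  dims <- c(20, 20, 10)
  rois <- list(
    rectum = array(FALSE, dims), bladder = array(FALSE, dims),
    penile_bulb = array(FALSE, dims), body = array(TRUE, dims)
  )
  rois$rectum[1:5, 1:5, ] <- TRUE
  rois$bladder[6:19, 1:12, ] <- TRUE
  rois$penile_bulb[1:3, 15:18, 1:3] <- TRUE

  low <- image_grid(array(3000, dims), c(2, 2, 2), unit = "cGy")
  rep_low <- constraint_report(low, rois)
  r35 <- rep_low[rep_low$roi == "rectum" & rep_low$rule == "V35Gy", ]
  expect_equal(r35$value, 0)
  expect_identical(r35$verdict, "pass")
  missing <- rep_low[rep_low$roi == "femur_left", ]
  expect_identical(unique(missing$verdict), "skipped")

  hot <- image_grid(array(7600, dims), c(2, 2, 2), unit = "cGy")
  rep_hot <- constraint_report(hot, rois)
  d003 <- rep_hot[rep_hot$rule == "D0.03cc", ]
  expect_equal(d003$value, 76)
  expect_identical(d003$verdict, "fail")

  # bladder with exactly 12 cm3 at/above 70 Gy fails the 10 cm3 rule
  vox_cc <- prod(c(2, 2, 2)) / 1000
  n_hot <- 12 / vox_cc
  d <- image_grid(array(1000, dims), c(2, 2, 2), unit = "cGy")
  idx <- which(rois$bladder)[seq_len(n_hot)]
  d$values[idx] <- 7000
  rep_b <- constraint_report(d, rois)
  v70 <- rep_b[rep_b$roi == "bladder" & rep_b$rule == "V70Gy" &
                 rep_b$units == "cm3", ]
  expect_equal(v70$value, 12)
  expect_identical(v70$verdict, "fail")
})

test_that("scenario dose differences follow the expected organ pattern", {
  case <- reduced_case()
  rois <- case$rois
  # NVB shows the largest NM-TM EUD magnitude among OARs when it sits in
  # the lateral beam corridor
  oar_a <- c(rectum = 8, bladder = 8, nvb = 8)
  d_eud <- vapply(names(oar_a), function(rn) {
    abs(eud(case$dose$TM, oar_a[[rn]], rois[[rn]]) -
          eud(case$dose$NM, oar_a[[rn]], rois[[rn]]))
  }, numeric(1))
  expect_identical(names(which.max(d_eud)), "nvb")
})
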