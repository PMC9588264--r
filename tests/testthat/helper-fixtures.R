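# Shared fixtures. Everything is generated in code; heavyweight objects are
# memoised so several test files can reuse one reduced-resolution case.

uniform_grid <- function(value, dims = c(10, 10, 10), spacing = c(1, 1, 1),
                         unit = "cGy") {
  image_grid(array(value, dims), spacing = spacing, unit = unit)
}

# reduced-resolution phantom parameters used throughout the suite
small_params <- function(seed = 3L) {
  phantom_params(shape = c(60L, 60L, 40L), spacing = c(4, 4, 4), seed = seed)
}

.case_cache <- new.env(parent = emptyenv())

# one fully computed reduced case: phantom, iodinated HU, scenario SPR grids,
# TM-optimized plan and the three scenario doses
reduced_case <- function() {
  if (!is.null(.case_cache$case)) return(.case_cache$case)
  ph <- generate_phantom(small_params())
  hu <- iodinate_spacer(ph$hu, ph$rois$spacer, seed = 3L)
  rois <- ph$rois
  rois$nvb <- rois$nvb_left | rois$nvb_right
  spr <- lapply(list(NM = "NM", WM = "WM", TM = "TM"),
                function(s) build_spr_grid(hu, rois, s))
  model <- depth_dose_model()
  plan <- optimize_plan(spr$TM, rois, 7000, model)
  dose <- lapply(spr, function(g) compute_dose(plan, g, model))
  .case_cache$case <- list(ph = ph, hu = hu, rois = rois, spr = spr,
                           model = model, plan = plan, dose = dose)
  .case_cache$case
}

# independent, exhaustive R implementation of the gamma index used as an
# oracle on small grids: no early termination, plain vectorised search
gamma_oracle <- function(ref, eval_, criteria) {
  step <- criteria$subsample * criteria$dta_mm
  cap <- criteria$search_cap * criteria$dta_mm
  n <- floor(cap / step)
  s <- (-n:n) * step
  off <- as.matrix(expand.grid(x = s, y = s, z = s))
  off <- off[rowSums(off^2) <= cap^2, , drop = FALSE]
  dd <- criteria$dose_pct / 100 * max(ref$values)
  d <- dim(ref)
  ax <- grid_axes(ref)
  out <- array(NA_real_, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    p0 <- c(ax$x[i], ax$y[j], ax$z[k])
    pts <- sweep(off, 2, p0, "+")
    ev <- spacerdose:::interp_trilinear(eval_, pts)
    g2 <- rowSums(off^2) / criteria$dta_mm^2 +
      ((ev - ref$values[i, j, k]) / dd)^2
    out[i, j, k] <- sqrt(min(g2))
  }
  image_grid(out, ref$spacing, ref$origin, unit = "gamma")
}
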