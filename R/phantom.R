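# Synthetic pelvic CT phantoms with contoured ROIs and the iodinated-spacer
# override. The phantom is a geometric stand-in for a male pelvis at the level
# of the prostate: elliptical body with a fat rim, prostate + seminal
# vesicles (CTV), rectum with gas lumen, a crescent hydrogel spacer between
# the prostate posterior surface and the rectum anterior wall, neurovascular
# bundles (NVBs) placed posterolaterally at spacer depth so that lateral
# beams traverse NVB and spacer along the same x-corridor, bladder, femoral
# heads and penile bulb.

#' Parameters of the synthetic pelvic phantom
#'
#' Defaults give a 120 x 120 x 80 voxel grid at 2 x 2 x 2 mm centred on the
#' prostate. All geometry is in mm; HU means/sds per tissue are configurable.
#' The spacer baseline HU mean is 31 (native hydrogel, soft-tissue-like);
#' iodination re-renders it at mean 120 (see [iodinate_spacer()]).
#'
#' @param shape Integer length-3 grid shape.
#' @param spacing Numeric length-3 voxel spacing (mm).
#' @param prostate_semiaxes Prostate ellipsoid semi-axes (mm).
#' @param sv_semiaxes Seminal-vesicle ellipsoid semi-axes (mm).
#' @param sv_offset Centre of the right SV relative to prostate centre (mm);
#'   the left SV mirrors in x.
#' @param spacer_thickness Spacer thickness along y (mm), > 0.
#' @param spacer_lateral Extra lateral (x) half-extent of the spacer shell
#'   beyond the prostate (mm); sets the lateral chord a beam traverses.
#' @param rectum_outer_radius,rectum_wall Rectal tube outer radius and wall
#'   thickness (mm); the tube runs along z.
#' @param rectum_half_length Rectal tube half-length in z (mm).
#' @param nvb_radius NVB cylinder radius (mm).
#' @param nvb_x,nvb_y NVB cylinder centre (|x|, y) (mm); cylinders run along
#'   z and hug the posterolateral prostate capsule at the spacer's lateral
#'   tips, so lateral beams traverse spacer and NVB along the same
#'   x-corridor.
#' @param nvb_half_length NVB half-length in z (mm).
#' @param bladder_centre,bladder_semiaxes Bladder ellipsoid geometry (mm).
#' @param femur_x,femur_y,femur_radius Femoral-head cylinder geometry (mm).
#' @param bulb_centre,bulb_semiaxes Penile-bulb ellipsoid geometry (mm).
#' @param body_semiaxes Body ellipse semi-axes in (x, y) (mm).
#' @param fat_rim Thickness of the subcutaneous fat rim (mm).
#' @param hu_means,hu_sds Named lists of per-tissue HU means / noise sds.
#' @param spacer_hu_mean Baseline (non-iodinated) spacer HU mean.
#' @param iodinated_hu_mean,iodinated_hu_sd Target HU distribution of the
#'   iodinated spacer.
#' @param smooth_sigma 3D smoothing width for iodination, in voxels.
#' @param seed RNG seed for the HU noise.
#' @return Object of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(120L, 120L, 80L),
                           spacing = c(2, 2, 2),
                           prostate_semiaxes = c(23, 21, 21),
                           sv_semiaxes = c(7, 6, 12),
                           sv_offset = c(9, 12, 30),
                           spacer_thickness = 10,
                           spacer_lateral = 6,
                           rectum_outer_radius = 14,
                           rectum_wall = 4,
                           rectum_half_length = 60,
                           nvb_radius = 4.5,
                           nvb_x = 20, nvb_y = 24,
                           nvb_half_length = 18,
                           bladder_centre = c(0, -45, 20),
                           bladder_semiaxes = c(32, 25, 25),
                           femur_x = 72, femur_y = -5, femur_radius = 16,
                           bulb_centre = c(0, 18, -38),
                           bulb_semiaxes = c(9, 7, 7),
                           body_semiaxes = c(110, 95),
                           fat_rim = 12,
                           hu_means = list(body = 20, fat = -100, prostate = 40,
                                           sv = 40, rectum_wall = 40,
                                           rectum_lumen = -700, bladder = 10,
                                           bone = 700, nvb = 40, bulb = 40,
                                           air = -1000),
                           hu_sds = list(tissue = 10, air = 3),
                           spacer_hu_mean = 31,
                           iodinated_hu_mean = 120,
                           iodinated_hu_sd = 15,
                           smooth_sigma = 1,
                           seed = 1L) {
  p <- as.list(environment())
  p$shape <- as.integer(p$shape)
  sizes <- c(p$prostate_semiaxes, p$sv_semiaxes, p$spacer_thickness,
             p$spacer_lateral,
             p$rectum_outer_radius, p$rectum_wall, p$rectum_half_length,
             p$nvb_radius, p$nvb_half_length, p$bladder_semiaxes,
             p$femur_radius, p$bulb_semiaxes, p$body_semiaxes, p$spacing)
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    stop("all geometric sizes and spacings must be > 0", call. = FALSE)
  }
  if (p$rectum_wall >= p$rectum_outer_radius) {
    stop("rectum_wall must be smaller than rectum_outer_radius", call. = FALSE)
  }
  structure(p, class = "phantom_params")
}

ellipsoid_mask <- function(X, Y, Z, centre, semi) {
  ((X - centre[1]) / semi[1])^2 + ((Y - centre[2]) / semi[2])^2 +
    ((Z - centre[3]) / semi[3])^2 <= 1
}

coord_arrays <- function(shape, spacing) {
  # grid centred on the prostate (world origin at volume centre)
  half <- (shape - 1) / 2
  xc <- (seq_len(shape[1]) - 1 - half[1]) * spacing[1]
  yc <- (seq_len(shape[2]) - 1 - half[2]) * spacing[2]
  zc <- (seq_len(shape[3]) - 1 - half[3]) * spacing[3]
  list(
    X = array(xc, shape),
    Y = array(rep(yc, each = shape[1]), shape),
    Z = array(rep(zc, each = shape[1] * shape[2]), shape),
    origin = c(xc[1], yc[1], zc[1])
  )
}

#' Generate a synthetic pelvic HU phantom with ROI masks
#'
#' Builds the anatomy analytically from [phantom_params()], adds per-tissue
#' Gaussian HU noise, and returns the HU grid plus the canonical ROI set
#' (prostate, seminal_vesicles, ctv, rectum, bladder, nvb_left, nvb_right,
#' femur_left, femur_right, penile_bulb, spacer, body). The spacer carries
#' its native soft-tissue-like HU (mean 31 by default); apply
#' [iodinate_spacer()] to re-render it as the iodinated product.
#' Deterministic for a fixed `params$seed`.
#'
#' @param params A [phantom_params()].
#' @return List with `hu` ([image_grid()]), `rois` (named list of logical
#'   masks) and `params`.
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  # rectum anterior wall placed tangent to the spacer outer surface
  rectum_centre_y <- p$prostate_semiaxes[2] + p$spacer_thickness +
    p$rectum_outer_radius
  co <- coord_arrays(p$shape, p$spacing)
  X <- co$X; Y <- co$Y; Z <- co$Z

  body <- (X / p$body_semiaxes[1])^2 + (Y / p$body_semiaxes[2])^2 <= 1
  inner <- (X / (p$body_semiaxes[1] - p$fat_rim))^2 +
    (Y / (p$body_semiaxes[2] - p$fat_rim))^2 <= 1
  fat <- body & !inner

  prostate <- ellipsoid_mask(X, Y, Z, c(0, 0, 0), p$prostate_semiaxes)
  sv_r <- ellipsoid_mask(X, Y, Z, p$sv_offset, p$sv_semiaxes)
  sv_l <- ellipsoid_mask(X, Y, Z, p$sv_offset * c(-1, 1, 1), p$sv_semiaxes)
  sv <- (sv_r | sv_l) & !prostate
  ctv <- prostate | sv

  r2 <- X^2 + (Y - rectum_centre_y)^2
  in_z <- abs(Z) <= p$rectum_half_length
  rectum <- r2 <= p$rectum_outer_radius^2 & in_z
  lumen <- r2 <= (p$rectum_outer_radius - p$rectum_wall)^2 & in_z

  shell_semi <- p$prostate_semiaxes + c(p$spacer_lateral, p$spacer_thickness, 0)
  spacer <- ellipsoid_mask(X, Y, Z, c(0, 0, 0), shell_semi) &
    !prostate & Y > 0 & !ctv & !rectum
  if (!any(spacer)) {
    stop("spacer geometry produced an empty mask", call. = FALSE)
  }

  nvb_r <- (X - p$nvb_x)^2 + (Y - p$nvb_y)^2 <= p$nvb_radius^2 &
    abs(Z) <= p$nvb_half_length
  nvb_l <- (X + p$nvb_x)^2 + (Y - p$nvb_y)^2 <= p$nvb_radius^2 &
    abs(Z) <= p$nvb_half_length
  nvb_r <- nvb_r & !spacer & !ctv
  nvb_l <- nvb_l & !spacer & !ctv

  bladder <- ellipsoid_mask(X, Y, Z, p$bladder_centre, p$bladder_semiaxes) &
    !ctv
  fem_r <- (X - p$femur_x)^2 + (Y - p$femur_y)^2 <= p$femur_radius^2
  fem_l <- (X + p$femur_x)^2 + (Y - p$femur_y)^2 <= p$femur_radius^2
  bulb <- ellipsoid_mask(X, Y, Z, p$bulb_centre, p$bulb_semiaxes) & !ctv

  if (any(spacer & ctv)) stop("spacer overlaps the CTV", call. = FALSE)

  mu <- array(p$hu_means$air, p$shape)
  sd <- array(p$hu_sds$air, p$shape)
  paint <- function(mask, mean_hu) {
    mu[mask] <<- mean_hu
    sd[mask] <<- p$hu_sds$tissue
  }
  paint(body, p$hu_means$body)
  paint(fat, p$hu_means$fat)
  paint(bladder, p$hu_means$bladder)
  paint(fem_r | fem_l, p$hu_means$bone)
  paint(rectum, p$hu_means$rectum_wall)
  paint(lumen, p$hu_means$rectum_lumen)
  paint(prostate, p$hu_means$prostate)
  paint(sv, p$hu_means$sv)
  paint(spacer, p$spacer_hu_mean)
  paint(nvb_r | nvb_l, p$hu_means$nvb)
  paint(bulb, p$hu_means$bulb)

  set.seed(p$seed)
  hu_vals <- mu + rnorm(length(mu), 0, 1) * sd
  hu <- image_grid(array(hu_vals, p$shape), p$spacing, co$origin, unit = "HU")

  rois <- list(
    prostate = prostate, seminal_vesicles = sv, ctv = ctv,
    rectum = rectum & !lumen | lumen, bladder = bladder,
    nvb_left = nvb_l, nvb_right = nvb_r,
    femur_left = fem_l, femur_right = fem_r,
    penile_bulb = bulb, spacer = spacer, body = body
  )
  # structures cropped out by a small field of view are omitted
  rois <- rois[vapply(rois, any, logical(1))]
  validate_rois(rois, hu)
  list(hu = hu, rois = rois, params = p)
}

# separable 3D Gaussian smoothing by shift-and-add; sigma in voxels,
# kernel truncated at radius ceiling(3 sigma)
gauss_smooth_3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  shift_axis <- function(a, off, axis) {
    out <- array(0, d)
    n <- d[axis]
    src <- max(1, 1 - off):min(n, n - off)
    dst <- src + off
    ix <- function(rng) switch(axis,
      list(rng, TRUE, TRUE), list(TRUE, rng, TRUE), list(TRUE, TRUE, rng))
    do.call(`[<-`, c(list(out), ix(dst), list(do.call(`[`, c(list(a), ix(src))))))
  }
  for (axis in 1:3) {
    acc <- array(0, d)
    for (i in seq_along(k)) {
      off <- i - r - 1
      acc <- acc + k[i] * shift_axis(arr, off, axis)
    }
    arr <- acc
  }
  arr
}

dilate1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(a, off, axis) {
    res <- array(FALSE, d)
    n <- d[axis]
    src <- max(1, 1 - off):min(n, n - off)
    dst <- src + off
    ix <- function(rng) switch(axis,
      list(rng, TRUE, TRUE), list(TRUE, rng, TRUE), list(TRUE, TRUE, rng))
    do.call(`[<-`, c(list(res), ix(dst), list(do.call(`[`, c(list(a), ix(src))))))
  }
  for (axis in 1:3) for (off in c(-1L, 1L)) out <- out | shift(mask, off, axis)
  out
}

#' Re-render the spacer as the iodinated product
#'
#' Replaces in-mask HU with draws from `Normal(mean_hu, sd_hu)` and applies
#' 3D Gaussian smoothing restricted to the spacer region (mask-normalised
#' convolution), with boundary blending confined to at most one voxel outside
#' the mask; all other voxels are untouched. The in-mask HU mean converges to
#' `mean_hu` as the mask grows.
#'
#' @param hu [image_grid()] of HU.
#' @param spacer_mask Logical mask aligned with `hu`, non-empty.
#' @param mean_hu Target iodinated HU mean (default 120).
#' @param sd_hu HU noise sd, >= 0 (default 15).
#' @param smooth_sigma Gaussian width in voxels (0 disables smoothing).
#' @param seed RNG seed.
#' @return [image_grid()] of HU with the spacer re-rendered.
#' @export
iodinate_spacer <- function(hu, spacer_mask, mean_hu = 120, sd_hu = 15,
                            smooth_sigma = 1, seed = 1L) {
  stopifnot(inherits(hu, "image_grid"))
  mask <- check_mask(spacer_mask, hu)
  n_in <- sum(mask)
  if (n_in == 0L) stop("spacer mask is empty", call. = FALSE)
  if (!is.finite(sd_hu) || sd_hu < 0) stop("sd_hu must be >= 0", call. = FALSE)
  set.seed(seed)
  noisy <- array(0, dim(hu))
  noisy[mask] <- rnorm(n_in, mean_hu, sd_hu)
  out <- hu$values
  if (smooth_sigma > 0) {
    w <- gauss_smooth_3d(array(as.numeric(mask), dim(mask)), smooth_sigma)
    s <- gauss_smooth_3d(noisy, smooth_sigma)
    sm <- ifelse(w > 1e-12, s / pmax(w, 1e-12), 0)
    rim <- dilate1(mask) & !mask
    out[mask] <- sm[mask]
    # blend rim voxels toward the smoothed spacer by their kernel weight
    out[rim] <- w[rim] * sm[rim] + (1 - w[rim]) * out[rim]
  } else {
    out[mask] <- noisy[mask]
  }
  image_grid(out, hu$spacing, hu$origin, unit = "HU")
}

#' Generate a cohort of jittered phantom cases
#'
#' Each case perturbs the base geometry (sizes by a relative fraction,
#' positions by a shift in mm) with a per-case seed derived from the master
#' seed as `master_seed * 1000 + case_index`, then generates the phantom and
#' applies the iodination override. Reproducible from `master_seed`.
#'
#' @param n_cases Number of cases, >= 1.
#' @param base_params A [phantom_params()] the jitter is applied to.
#' @param master_seed Master RNG seed.
#' @param size_jitter Relative size jitter (default 0.10 = +/-10%).
#' @param position_jitter Positional jitter in mm (default 3).
#' @param iodinate Apply [iodinate_spacer()] to each case (default TRUE).
#' @return List of cases; each case is a list with `case_id`, `seed`, `hu`
#'   (iodinated when requested), `hu_native`, `rois`, `params`. A manifest
#'   tibble of per-case parameters is attached as attribute `"manifest"`.
#' @export
generate_cohort <- function(n_cases, base_params = phantom_params(),
                            master_seed = 1L, size_jitter = 0.10,
                            position_jitter = 3, iodinate = TRUE) {
  stopifnot(n_cases >= 1)
  cases <- vector("list", n_cases)
  manifest <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    seed_i <- master_seed * 1000L + i
    set.seed(seed_i)
    jit <- function(x) x * (1 + stats::runif(length(x), -size_jitter, size_jitter))
    shift <- function(x) x + stats::runif(length(x), -position_jitter,
                                          position_jitter)
    p <- base_params
    p$prostate_semiaxes <- jit(p$prostate_semiaxes)
    p$sv_semiaxes <- jit(p$sv_semiaxes)
    p$spacer_thickness <- jit(p$spacer_thickness)
    p$nvb_radius <- jit(p$nvb_radius)
    p$nvb_x <- shift(p$nvb_x)
    p$nvb_y <- shift(p$nvb_y)
    p$bladder_centre <- shift(p$bladder_centre)
    p$bulb_centre <- shift(p$bulb_centre)
    p$seed <- seed_i
    ph <- generate_phantom(p)
    hu <- ph$hu
    if (iodinate) {
      hu <- iodinate_spacer(ph$hu, ph$rois$spacer,
                            mean_hu = p$iodinated_hu_mean,
                            sd_hu = p$iodinated_hu_sd,
                            smooth_sigma = p$smooth_sigma,
                            seed = seed_i + 500L)
    }
    cases[[i]] <- list(case_id = sprintf("case%02d", i), seed = seed_i,
                       hu = hu, hu_native = ph$hu, rois = ph$rois, params = p)
    manifest[[i]] <- tibble::tibble(
      case_id = cases[[i]]$case_id, seed = seed_i,
      prostate_a = p$prostate_semiaxes[1], prostate_b = p$prostate_semiaxes[2],
      prostate_c = p$prostate_semiaxes[3],
      spacer_thickness = p$spacer_thickness,
      nvb_x = p$nvb_x, nvb_y = p$nvb_y,
      spacer_voxels = sum(ph$rois$spacer)
    )
  }
  attr(cases, "manifest") <- dplyr::bind_rows(manifest)
  cases
}
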