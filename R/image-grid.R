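# Voxel grid container shared by all stages.
#
# Conventions (fixed package-wide):
#   * axis order (x = left->right, y = anterior->posterior, z = inferior->superior)
#   * 0-based voxel indices, voxel-centre world mapping:
#       world(i,j,k) = origin + c(i,j,k) * spacing
#   * all lengths in mm; dose carried in cGy.

GRID_UNITS <- c("HU", "SPR", "cGy", "gamma", "unitless")

#' Create a 3D image grid
#'
#' An `image_grid` is the package's voxel container: a 3D numeric array with
#' isotropic-or-not spacing (mm), a world origin (mm, voxel-centre convention,
#' 0-based indices) and a unit tag (`"HU"`, `"SPR"`, `"cGy"`, `"gamma"` or
#' `"unitless"`).
#'
#' @param values 3D numeric array of finite values.
#' @param spacing Numeric length-3, voxel spacing in mm, all > 0.
#' @param origin Numeric length-3, world coordinate (mm) of voxel (0,0,0).
#' @param unit One of `"HU"`, `"SPR"`, `"cGy"`, `"gamma"`, `"unitless"`.
#' @return An object of class `image_grid`.
#' @export
#' @examples
#' g <- image_grid(array(0, c(4, 4, 2)), spacing = c(2, 2, 2), unit = "HU")
#' dim(g)
image_grid <- function(values, spacing, origin = c(0, 0, 0), unit = "unitless") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive finite values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  }
  unit <- match.arg(unit, GRID_UNITS)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing, origin = origin, unit = unit),
    class = "image_grid"
  )
}

#' @export
dim.image_grid <- function(x) dim(x$values)

#' @export
print.image_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<image_grid> %d x %d x %d voxels [%s]\n  spacing %.3g x %.3g x %.3g mm, origin (%.4g, %.4g, %.4g) mm\n  range [%.4g, %.4g]\n",
    d[1], d[2], d[3], x$unit,
    x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3],
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Voxel-centre coordinate vectors of a grid
#'
#' @param grid An [image_grid()].
#' @return List with numeric vectors `x`, `y`, `z` of world coordinates (mm).
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  d <- dim(grid)
  list(
    x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
    y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2],
    z = grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  )
}

#' Test whether two grids share the same voxel lattice
#'
#' True iff shapes are equal, spacings agree within 1e-6 mm and origins within
#' 1e-3 mm. A pure predicate: never throws.
#'
#' @param a,b [image_grid()] objects.
#' @return Logical scalar.
#' @export
assert_aligned <- function(a, b) {
  if (!inherits(a, "image_grid") || !inherits(b, "image_grid")) return(FALSE)
  identical(dim(a), dim(b)) &&
    all(abs(a$spacing - b$spacing) <= 1e-6) &&
    all(abs(a$origin - b$origin) <= 1e-3)
}

stop_if_misaligned <- function(a, b, what = "grids") {
  if (!assert_aligned(a, b)) {
    stop(sprintf("%s are not aligned (shape/spacing/origin mismatch)", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

check_mask <- function(mask, grid) {
  if (!is.array(mask) || !identical(dim(mask), dim(grid))) {
    stop("mask is not aligned with the grid", call. = FALSE)
  }
  if (!is.logical(mask)) mask <- mask != 0
  mask
}

#' Absolute volume of a mask in cubic centimetres
#'
#' @param mask Logical array aligned with `grid`.
#' @param grid An [image_grid()] supplying the voxel size.
#' @return Volume in cm^3 (`n_voxels * voxel_volume_mm3 / 1000`).
#' @export
#' @examples
#' g <- image_grid(array(0, c(10, 10, 10)), c(1, 1, 1))
#' mask <- array(TRUE, dim(g))
#' mask_volume_cc(mask, g)  # 1 cm^3
mask_volume_cc <- function(mask, grid) {
  stopifnot(inherits(grid, "image_grid"))
  mask <- check_mask(mask, grid)
  sum(mask) * prod(grid$spacing) / 1000
}

#' Validate a set of ROI masks against a reference grid
#'
#' Checks alignment, that each present mask has at least one voxel, that the
#' clinical target volume equals prostate union seminal vesicles when all
#' three are present, and that the spacer is disjoint from the CTV.
#'
#' @param rois Named list of logical arrays.
#' @param grid Reference [image_grid()].
#' @return `rois`, invisibly, after coercing masks to logical.
#' @export
validate_rois <- function(rois, grid) {
  stopifnot(is.list(rois), !is.null(names(rois)))
  rois <- lapply(rois, check_mask, grid = grid)
  empty <- vapply(rois, function(m) sum(m) == 0L, logical(1))
  if (any(empty)) {
    stop("empty ROI mask(s): ", paste(names(rois)[empty], collapse = ", "),
         call. = FALSE)
  }
  if (all(c("ctv", "prostate", "seminal_vesicles") %in% names(rois))) {
    u <- rois$prostate | rois$seminal_vesicles
    if (!identical(u, rois$ctv)) {
      stop("ctv must equal prostate | seminal_vesicles", call. = FALSE)
    }
  }
  if (all(c("ctv", "spacer") %in% names(rois)) &&
      any(rois$ctv & rois$spacer)) {
    stop("spacer and ctv masks overlap", call. = FALSE)
  }
  invisible(rois)
}

#' Construct a ray for water-equivalent path tracing
#'
#' @param entry Numeric length-3, world entry point (mm).
#' @param direction Numeric length-3; normalised internally, must be nonzero.
#' @param step Step length in mm, > 0.
#' @return Object of class `ray`.
#' @export
ray <- function(entry, direction, step = 0.5) {
  entry <- as.numeric(entry)
  direction <- as.numeric(direction)
  stopifnot(length(entry) == 3L, length(direction) == 3L)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm <= 0) stop("direction must be nonzero", call. = FALSE)
  if (!is.finite(step) || step <= 0) stop("step must be > 0", call. = FALSE)
  structure(list(entry = entry, direction = direction / nrm, step = step),
            class = "ray")
}

# Trilinear interpolation of grid values at world points (n x 3 matrix, mm).
# Points outside the voxel-centre hull are clamped to it.
interp_trilinear <- function(grid, pts) {
  d <- dim(grid)
  v <- grid$values
  f <- sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/")
  out <- numeric(nrow(f))
  for (ax in 1:3) f[, ax] <- pmin(pmax(f[, ax], 0), d[ax] - 1)
  i0 <- floor(f)
  i0 <- pmin(i0, matrix(rep(d - 2, each = nrow(f)), ncol = 3)) # keep i0+1 valid
  i0[i0 < 0] <- 0
  w <- f - i0
  idx <- function(dx, dy, dz) {
    (i0[, 1] + dx) + d[1] * ((i0[, 2] + dy) + d[2] * (i0[, 3] + dz)) + 1
  }
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wt <- (if (dx == 1) w[, 1] else 1 - w[, 1]) *
      (if (dy == 1) w[, 2] else 1 - w[, 2]) *
      (if (dz == 1) w[, 3] else 1 - w[, 3])
    out <- out + wt * v[idx(dx, dy, dz)]
  }
  out
}
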