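# Volume I/O: NIfTI (.nii / .nii.gz) with a JSON sidecar for the unit tag,
# since the NIfTI header has no dose-unit field. Masks are written as uint8.

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write an image grid to NIfTI with a JSON sidecar
#'
#' Spacing is stored in the header `pixdim`/qform and the origin in the qform
#' offset. The unit tag (and optional free-text description and seed) go to a
#' JSON sidecar next to the volume, `<stem>.json`.
#'
#' @param grid An [image_grid()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param description Optional free-text note stored in the sidecar.
#' @param seed Optional integer seed recorded for provenance.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, description = NULL, seed = NULL) {
  stopifnot(inherits(grid, "image_grid"))
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop("path must end in .nii or .nii.gz", call. = FALSE)
  }
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  m <- rbind(cbind(diag(grid$spacing), grid$origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  meta <- list(unit = grid$unit, spacing = grid$spacing, origin = grid$origin)
  if (!is.null(description)) meta$description <- description
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image grid from NIfTI
#'
#' Restores spacing and origin from the header and the unit tag from the JSON
#' sidecar when present (falling back to `"unitless"`).
#'
#' @param path Path to a `.nii` / `.nii.gz` volume.
#' @return An [image_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read volume: no such file '%s'", path), call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop(sprintf("invalid voxel spacing in NIfTI header of '%s'", path),
         call. = FALSE)
  }
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  unit <- "unitless"
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$unit) && meta$unit %in% GRID_UNITS) unit <- meta$unit
  }
  vals <- array(as.numeric(img), dim = dim(img)[1:3])
  image_grid(vals, spacing = spacing, origin = origin, unit = unit)
}

#' Write a logical ROI mask as uint8 NIfTI
#'
#' @param mask Logical array aligned with `grid`.
#' @param grid Reference [image_grid()] supplying geometry.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, grid, path) {
  mask <- check_mask(mask, grid)
  g <- image_grid(array(as.numeric(mask), dim(grid)), grid$spacing,
                  grid$origin, unit = "unitless")
  write_volume(g, path)
}

#' Read a uint8 NIfTI mask back to a logical array
#'
#' @param path Path to the mask volume.
#' @return List with `mask` (logical array) and `grid` (geometry carrier).
#' @export
read_mask <- function(path) {
  g <- read_volume(path)
  list(mask = g$values != 0, grid = g)
}
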