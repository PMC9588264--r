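# 3D gamma-index comparison of two dose distributions and structure-specific
# passing ratios.

#' Gamma-index criteria
#'
#' @param dose_pct Dose tolerance as percent of the global reference maximum
#'   (> 0), e.g. 3 for 3%.
#' @param dta_mm Distance-to-agreement in mm (> 0).
#' @param low_dose_threshold Exclusion threshold as a fraction of the maximum
#'   reference dose (default 0.10): voxels below it are excluded from passing
#'   ratios.
#' @param search_cap Search radius cap in multiples of `dta_mm` (default 3).
#' @param subsample Interpolation subsample step as a fraction of `dta_mm`
#'   (default 0.1).
#' @param normalization `"global"` (dose tolerance from the reference
#'   maximum; default) or `"local"` (percent of the local reference voxel).
#' @return Object of class `gamma_criteria`.
#' @export
#' @examples
#' gamma_criteria(3, 3)   # 3%/3 mm
#' gamma_criteria(1, 1)   # 1%/1 mm
gamma_criteria <- function(dose_pct, dta_mm, low_dose_threshold = 0.10,
                           search_cap = 3, subsample = 0.1,
                           normalization = c("global", "local")) {
  if (!is.finite(dose_pct) || dose_pct <= 0) stop("dose_pct must be > 0",
                                                  call. = FALSE)
  if (!is.finite(dta_mm) || dta_mm <= 0) stop("dta_mm must be > 0",
                                              call. = FALSE)
  if (low_dose_threshold < 0 || low_dose_threshold >= 1) {
    stop("low_dose_threshold must be in [0, 1)", call. = FALSE)
  }
  normalization <- match.arg(normalization)
  structure(list(dose_pct = dose_pct, dta_mm = dta_mm,
                 low_dose_threshold = low_dose_threshold,
                 search_cap = search_cap, subsample = subsample,
                 normalization = normalization),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %g%%/%g mm (%s), threshold %g, cap %g x dta, subsample %g x dta\n",
              x$dose_pct, x$dta_mm, x$normalization, x$low_dose_threshold,
              x$search_cap, x$subsample))
  invisible(x)
}

gamma_offsets <- function(criteria, spacing) {
  step <- criteria$subsample * criteria$dta_mm
  cap <- criteria$search_cap * criteria$dta_mm
  n <- floor(cap / step)
  s <- (-n:n) * step
  off <- as.matrix(expand.grid(x = s, y = s, z = s))
  d2 <- rowSums(off^2)
  keep <- d2 <= cap^2 & d2 > 0
  off <- off[keep, , drop = FALSE]
  d2 <- d2[keep]
  ord <- order(d2)
  list(offsets = off[ord, , drop = FALSE], dist2 = d2[ord])
}

#' 3D gamma-index map
#'
#' Per reference voxel `r`, `gamma(r)` is the minimum over evaluation
#' positions `e` within the search cap of
#' `sqrt(|e - r|^2 / dta^2 + (D_eval(e) - D_ref(r))^2 / dD^2)`,
#' with `dD = dose_pct% of max(D_ref)` under global normalization, and the
#' evaluated dose trilinearly interpolated on a subsampled lattice.
#'
#' @param ref Reference dose [image_grid()] (cGy); its maximum must be > 0.
#' @param eval_ Evaluated dose [image_grid()] aligned with `ref`.
#' @param criteria A [gamma_criteria()].
#' @return [image_grid()] tagged `"gamma"`.
#' @export
gamma_map <- function(ref, eval_, criteria = gamma_criteria(3, 3)) {
  stopifnot(inherits(ref, "image_grid"), inherits(eval_, "image_grid"),
            inherits(criteria, "gamma_criteria"))
  stop_if_misaligned(ref, eval_, "dose grids")
  dmax <- max(ref$values)
  if (dmax <= 0) stop("reference maximum dose must be > 0", call. = FALSE)
  off <- gamma_offsets(criteria, ref$spacing)
  local <- criteria$normalization == "local"
  dd_abs <- if (local) criteria$dose_pct / 100 else criteria$dose_pct / 100 * dmax
  g <- cpp_gamma_map(as.numeric(ref$values), as.numeric(eval_$values),
                     dim(ref), ref$spacing, off$offsets, off$dist2,
                     criteria$dta_mm, dd_abs, local)
  image_grid(array(g, dim(ref)), ref$spacing, ref$origin, unit = "gamma")
}

#' Gamma passing ratio, optionally structure-specific
#'
#' Fraction of voxels with `gamma < 1` (strict) among voxels whose reference
#' dose is at least `low_dose_threshold` times the maximum reference dose,
#' optionally restricted to an ROI mask. Returns `NA` when no voxel survives
#' the exclusion (undefined, not an error).
#'
#' @param gamma [image_grid()] from [gamma_map()].
#' @param ref The reference dose grid used for the low-dose exclusion.
#' @param mask Optional logical ROI mask; `NULL` means the whole grid.
#' @param criteria The [gamma_criteria()] (supplies the threshold).
#' @return Fraction in `[0, 1]`, or `NA_real_` if undefined.
#' @export
passing_ratio <- function(gamma, ref, mask = NULL,
                          criteria = gamma_criteria(3, 3)) {
  stopifnot(inherits(gamma, "image_grid"), inherits(ref, "image_grid"))
  stop_if_misaligned(gamma, ref, "gamma/reference grids")
  sel <- ref$values >= criteria$low_dose_threshold * max(ref$values)
  if (!is.null(mask)) sel <- sel & check_mask(mask, ref)
  n <- sum(sel)
  if (n == 0L) return(NA_real_)
  sum(gamma$values[sel] < 1) / n
}

#' Structure-specific passing-ratio table
#'
#' Computes gamma maps for one reference/evaluated pair at several criteria
#' and tabulates per-ROI (plus whole-grid `"body"`-free `"all"`) passing
#' ratios.
#'
#' @param ref,eval_ Dose grids (reference first).
#' @param rois Named list of logical masks (may be empty).
#' @param criteria_list List of [gamma_criteria()].
#' @return Tibble with columns `roi`, `criteria`, `pr`.
#' @export
pr_table <- function(ref, eval_, rois = list(),
                     criteria_list = list(gamma_criteria(1, 1),
                                          gamma_criteria(2, 2),
                                          gamma_criteria(3, 3))) {
  rows <- list()
  for (cr in criteria_list) {
    g <- gamma_map(ref, eval_, cr)
    lab <- sprintf("%g%%/%gmm", cr$dose_pct, cr$dta_mm)
    rows[[length(rows) + 1]] <- tibble::tibble(
      roi = "all", criteria = lab, pr = passing_ratio(g, ref, NULL, cr))
    for (rn in names(rois)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        roi = rn, criteria = lab,
        pr = passing_ratio(g, ref, rois[[rn]], cr))
    }
  }
  dplyr::bind_rows(rows)
}
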