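# DVH construction, dosimetric indices (Dx, mean dose, EUD) and the
# institutional dose-constraint report.

#' Dose-volume histogram of an ROI
#'
#' Differential histogram of in-mask voxel doses on uniform bins plus the
#' cumulative volume fraction. `V(d)` is the fraction of the structure
#' receiving at least dose `d`; `V(0) = 1` and `V` is non-increasing.
#'
#' @param dose [image_grid()] of dose (cGy).
#' @param mask Logical ROI mask aligned with `dose`, non-empty.
#' @param bin_width Bin width in cGy (default 10).
#' @return Object of class `dvh`: tibble-backed bins plus metadata
#'   (`volume_cc`, `n_voxels`).
#' @export
dvh <- function(dose, mask, bin_width = 10) {
  stopifnot(inherits(dose, "image_grid"))
  mask <- check_mask(mask, dose)
  doses <- dose$values[mask]
  if (length(doses) == 0L) stop("empty structure", call. = FALSE)
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop("bin_width must be > 0", call. = FALSE)
  }
  top <- max(doses, 0)
  breaks <- seq(0, (floor(top / bin_width) + 1) * bin_width, by = bin_width)
  h <- graphics::hist(doses, breaks = breaks, plot = FALSE, right = FALSE)
  diff_frac <- h$counts / length(doses)
  # cumulative fraction receiving >= left bin edge
  cum_frac <- rev(cumsum(rev(diff_frac)))
  structure(list(
    bins = tibble::tibble(dose = h$mids, edge = breaks[-length(breaks)],
                          diff_frac = diff_frac, cum_frac = cum_frac),
    bin_width = bin_width,
    volume_cc = sum(mask) * prod(dose$spacing) / 1000,
    n_voxels = length(doses)
  ), class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %d voxels, %.2f cm3, %d bins of %g cGy\n",
              x$n_voxels, x$volume_cc, nrow(x$bins), x$bin_width))
  invisible(x)
}

#' @rdname dvh
#' @param x A `dvh` object.
#' @param ... Unused.
#' @export
tidy.dvh <- function(x, ...) x$bins

#' Dose covering the hottest x% of a structure, and the mean dose
#'
#' `D_x` is the minimum dose received by the hottest `x`% of the structure
#' (standard ICRU reading), computed from raw voxel doses by exact order
#' statistics rather than from histogram bins.
#'
#' @param dose [image_grid()] of dose.
#' @param mask Logical ROI mask, non-empty.
#' @param x Percent in (0, 100].
#' @return Tibble with `x`, `d_x` (cGy) and `mean_dose` (cGy).
#' @export
#' @examples
#' g <- image_grid(array(7000, c(5, 5, 5)), c(2, 2, 2), unit = "cGy")
#' d_at_percent(g, array(TRUE, c(5, 5, 5)), 95)
d_at_percent <- function(dose, mask, x) {
  stopifnot(inherits(dose, "image_grid"))
  mask <- check_mask(mask, dose)
  doses <- dose$values[mask]
  if (length(doses) == 0L) stop("empty structure", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0) || any(x > 100)) {
    stop("x must be in (0, 100]", call. = FALSE)
  }
  s <- sort(doses, decreasing = TRUE)
  k <- pmax(1L, ceiling(x / 100 * length(s)))
  tibble::tibble(x = x, d_x = s[k], mean_dose = mean(doses))
}

#' Equivalent uniform dose
#'
#' Generalised power mean `EUD_a = (sum_i n_i d_i^a)^(1/a)` with `n_i` the
#' fraction of the structure at dose `d_i`. Target structures use `a = -10`,
#' organs at risk `a = 8`. For `a < 0`, zero-dose voxels are floored at
#' 0.1 cGy before exponentiation (the power mean is singular at zero dose);
#' `a = 0` is rejected.
#'
#' @param x An [image_grid()] (with `mask`), a [dvh()] object, or a numeric
#'   vector of voxel doses.
#' @param a Power-mean exponent, nonzero.
#' @param mask ROI mask when `x` is a dose grid.
#' @return EUD in cGy; always between the minimum and maximum dose.
#' @export
#' @examples
#' eud(c(6000, 7000), a = 8)  # ~6633 cGy
eud <- function(x, a, mask = NULL) {
  if (!is.finite(a) || a == 0) stop("a must be nonzero", call. = FALSE)
  if (inherits(x, "image_grid")) {
    if (is.null(mask)) stop("mask required with a dose grid", call. = FALSE)
    mask <- check_mask(mask, x)
    doses <- x$values[mask]
    if (length(doses) == 0L) stop("empty structure", call. = FALSE)
    frac <- rep(1 / length(doses), length(doses))
  } else if (inherits(x, "dvh")) {
    doses <- x$bins$dose
    frac <- x$bins$diff_frac
  } else {
    doses <- as.numeric(x)
    if (length(doses) == 0L) stop("empty structure", call. = FALSE)
    frac <- rep(1 / length(doses), length(doses))
  }
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  if (a < 0) doses <- pmax(doses, 0.1)
  # scale so the powered terms stay <= 1: avoids overflow for large |a|
  m <- if (a > 0) max(doses) else min(doses)
  if (m == 0) return(0)
  m * (sum(frac * (doses / m)^a))^(1 / a)
}

#' Standard dosimetric index table for one ROI
#'
#' D02/D05/D20/D50/D95/D98, mean dose, and (when `eud_a` is given) the EUD.
#'
#' @param dose [image_grid()] of dose.
#' @param mask Logical ROI mask.
#' @param eud_a Optional EUD exponent for this ROI.
#' @param percents Percent levels for `D_x`.
#' @return Tibble with columns `metric`, `value` (cGy).
#' @export
dose_metrics <- function(dose, mask, eud_a = NULL,
                         percents = c(2, 5, 20, 50, 95, 98)) {
  dx <- d_at_percent(dose, mask, percents)
  out <- tibble::tibble(metric = sprintf("D%02d", percents), value = dx$d_x)
  out <- dplyr::bind_rows(out, tibble::tibble(metric = "Dmean",
                                              value = dx$mean_dose[1]))
  if (!is.null(eud_a)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      metric = "EUD", value = eud(dose, a = eud_a, mask = mask)))
  }
  out
}

#' Institutional dose-constraint table
#'
#' The OAR constraint set used for two-lateral-beam prostate planning,
#' shipped as editable YAML in `inst/extdata/constraints.yaml`: bladder
#' V70Gy < 10 cm3, V65 < 15%, V61 < 25%, V55 < 30%, V44 < 50%, V39 < 60%;
#' rectum V70Gy < 10 cm3, V65 < 10%, V61 < 15%, V53 < 30%, V35 < 50%;
#' femoral heads V39 < 5%; penile bulb mean < 39 Gy; body D0.03cm3 < 74.9 Gy.
#'
#' @param path Optional path to a YAML constraint file; defaults to the
#'   bundled table.
#' @return Tibble with columns `roi`, `metric`, `dose_gy`, `volume_cc`,
#'   `limit`, `limit_units`.
#' @export
default_constraints <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "constraints.yaml", package = "spacerdose")
  }
  y <- yaml::read_yaml(path)
  dplyr::bind_rows(lapply(y$constraints, function(r) {
    tibble::tibble(
      roi = r$roi, metric = r$metric,
      dose_gy = if (is.null(r$dose_gy)) NA_real_ else r$dose_gy,
      volume_cc = if (is.null(r$volume_cc)) NA_real_ else r$volume_cc,
      limit = r$limit, limit_units = r$limit_units
    )
  }))
}

eval_constraint <- function(rule, dose, rois) {
  lim <- rule$limit
  lim_units <- rule$limit_units
  if (!rule$roi %in% names(rois)) {
    return(tibble::tibble(roi = rule$roi, rule = rule$metric, value = NA_real_,
                          limit = lim, units = lim_units, verdict = "skipped"))
  }
  mask <- check_mask(rois[[rule$roi]], dose)
  doses <- dose$values[mask]
  vox_cc <- prod(dose$spacing) / 1000
  val <- switch(rule$metric,
    V_rel = 100 * mean(doses >= rule$dose_gy * 100),
    V_abs = sum(doses >= rule$dose_gy * 100) * vox_cc,
    Dmean = mean(doses) / 100,
    Dcc = { # dose to the hottest `volume_cc` of the structure
      nvox <- max(1L, ceiling(rule$volume_cc / vox_cc))
      s <- sort(doses, decreasing = TRUE)
      s[min(nvox, length(s))] / 100
    },
    stop("malformed constraint metric: ", rule$metric, call. = FALSE)
  )
  lbl <- switch(rule$metric,
    V_rel = sprintf("V%.0fGy", rule$dose_gy),
    V_abs = sprintf("V%.0fGy", rule$dose_gy),
    Dmean = "Dmean",
    Dcc = sprintf("D%.2gcc", rule$volume_cc))
  tibble::tibble(roi = rule$roi, rule = lbl, value = val, limit = lim,
                 units = lim_units,
                 verdict = if (val < lim) "pass" else "fail")
}

#' Evaluate dose constraints against a dose grid
#'
#' Supports relative volume rules (% of ROI at or above a dose), absolute
#' volume rules (cm3 at or above a dose), mean-dose rules, and
#' dose-at-absolute-volume rules (minimum dose over the hottest given cm3).
#' ROIs missing from `rois` are reported as skipped rather than failing.
#'
#' @param dose [image_grid()] of dose in cGy.
#' @param rois Named list of logical masks.
#' @param constraints Constraint tibble as from [default_constraints()].
#' @return Tibble with `roi`, `rule`, `value`, `limit`, `units`, `verdict`.
#' @export
constraint_report <- function(dose, rois, constraints = default_constraints()) {
  stopifnot(inherits(dose, "image_grid"))
  dplyr::bind_rows(lapply(seq_len(nrow(constraints)), function(i) {
    eval_constraint(as.list(constraints[i, ]), dose, rois)
  }))
}

#' Plot a cumulative DVH
#'
#' @param object A [dvh()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dvh <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$edge / 100, y = 100 * .data$cum_frac)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)") +
    ggplot2::theme_minimal()
}
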