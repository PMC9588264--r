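# Material physics: elemental compositions, theoretical proton stopping-power
# ratio (SPR) from the Bethe stopping number, power-law effective atomic
# number, HU->SPR calibration curves, and the scenario override logic
# (NM = CT-intensity-based, WM = water override, TM = true material).

PROTON_REST_MEV <- 938.272
TWO_ME_C2_EV <- 1.021998e6 # 2 * m_e c^2 in eV

# Elemental constants: standard atomic weights and ICRU-49-style mean
# excitation energies (eV).
ELEMENT_TABLE <- data.frame(
  symbol = c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Cl", "K", "Ca", "I"),
  Z = c(1, 6, 7, 8, 11, 12, 15, 16, 17, 19, 20, 53),
  A = c(1.008, 12.011, 14.007, 15.999, 22.990, 24.305, 30.974, 32.06,
        35.45, 39.098, 40.078, 126.904),
  I_eV = c(19.2, 78.0, 82.0, 95.0, 149, 156, 173, 180, 174, 190, 191, 491),
  stringsAsFactors = FALSE
)

# Molecular components the spacer recipe is printed in. Trilysine expanded as
# 3 x lysine (C6H14N2O2) minus 2 x H2O; PEG as its repeat unit.
COMPONENT_FORMULAS <- list(
  water = c(H = 2, O = 1),
  trilysine = c(C = 18, H = 38, N = 6, O = 4),
  PEG = c(C = 2, H = 4, O = 1)
)

element_row <- function(sym) {
  i <- match(sym, ELEMENT_TABLE$symbol)
  if (anyNA(i)) {
    stop("unknown element(s): ", paste(sym[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  ELEMENT_TABLE[i, , drop = FALSE]
}

formula_weight_fractions <- function(counts) {
  el <- element_row(names(counts))
  m <- counts * el$A
  m / sum(m)
}

#' Construct a material from elemental weight fractions
#'
#' @param elements Named numeric vector of elemental weight fractions
#'   (symbols, e.g. `c(H = 0.1119, O = 0.8881)`); must sum to 1 within 1e-4.
#' @param density Mass density in g/cm^3, > 0.
#' @param name Optional material name.
#' @return Object of class `material_spec`.
#' @export
material_spec <- function(elements, density, name = "material") {
  stopifnot(is.numeric(elements), !is.null(names(elements)))
  if (any(elements < 0)) stop("weight fractions must be >= 0", call. = FALSE)
  s <- sum(elements)
  if (abs(s - 1) > 1e-4) {
    stop(sprintf("weight fractions sum to %.6f, not 1", s), call. = FALSE)
  }
  elements <- elements / s
  element_row(names(elements)) # validates symbols
  if (!is.finite(density) || density <= 0) {
    stop("density must be > 0", call. = FALSE)
  }
  structure(list(elements = elements, density = density, name = name),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s, rho = %.4g g/cm3\n", x$name, x$density))
  print(round(x$elements, 5))
  invisible(x)
}

#' Build a material from molecular components
#'
#' Expands named components (`water`, `trilysine`, `PEG`) and raw element
#' symbols (e.g. `I`) to elemental weight fractions using molecular formulas
#' (water H2O, trilysine C18H38N6O4, PEG repeat unit C2H4O).
#'
#' @param components Named numeric vector of component weight fractions,
#'   summing to 1 within 1e-4.
#' @param density Mass density in g/cm^3.
#' @param name Optional material name.
#' @return A [material_spec()].
#' @export
#' @examples
#' material_from_components(c(water = 1), density = 1.0, name = "water")
material_from_components <- function(components, density, name = "material") {
  stopifnot(is.numeric(components), !is.null(names(components)))
  s <- sum(components)
  if (abs(s - 1) > 1e-4) {
    stop(sprintf("component fractions sum to %.6f, not 1", s), call. = FALSE)
  }
  acc <- numeric(0)
  for (comp in names(components)) {
    w <- components[[comp]]
    if (comp %in% names(COMPONENT_FORMULAS)) {
      fr <- formula_weight_fractions(COMPONENT_FORMULAS[[comp]])
    } else if (comp %in% ELEMENT_TABLE$symbol) {
      fr <- setNames(1, comp)
    } else {
      stop("unknown component: ", comp, call. = FALSE)
    }
    for (el in names(fr)) {
      acc[el] <- (if (el %in% names(acc)) acc[[el]] else 0) + w * fr[[el]]
    }
  }
  material_spec(acc, density, name = name)
}

#' The iodinated hydrogel spacer material
#'
#' Canonical recipe: 88% water, 0.7% trilysine, 10.1% PEG and 1.2% iodine by
#' weight at mass density 1.03 g/cm^3.
#'
#' @return A [material_spec()].
#' @export
spacer_material <- function() {
  material_from_components(
    c(water = 0.88, trilysine = 0.007, PEG = 0.101, I = 0.012),
    density = 1.03, name = "iodinated_hydrogel"
  )
}

#' Load named materials from a YAML file
#'
#' Reads a `materials:` block of named entries with `components` (weight
#' fractions of molecular components or element symbols) and `density`
#' (g/cm^3). Defaults to the bundled table, which carries the iodinated
#' hydrogel recipe.
#'
#' @param path Optional YAML path; default is the bundled
#'   `extdata/materials.yaml`.
#' @return Named list of [material_spec()] objects.
#' @export
load_materials <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "materials.yaml", package = "spacerdose")
  }
  y <- yaml::read_yaml(path)
  out <- lapply(names(y$materials), function(nm) {
    m <- y$materials[[nm]]
    material_from_components(unlist(m$components), m$density, name = nm)
  })
  setNames(out, names(y$materials))
}

water_material <- function(density = 1.0) {
  material_from_components(c(water = 1), density = density, name = "water")
}

# Per-element electron fractions w_i Z_i / A_i, normalised to sum 1; also
# returns electrons per gram (sum w_i Z_i / A_i, in mol e-/g units).
electron_fractions <- function(material) {
  el <- element_row(names(material$elements))
  za <- material$elements * el$Z / el$A
  list(frac = za / sum(za), epg = sum(za), Z = el$Z, I_eV = el$I_eV)
}

bethe_L <- function(beta2, gamma2, I_eV) {
  log(TWO_ME_C2_EV * beta2 * gamma2 / I_eV) - beta2
}

#' Theoretical proton stopping-power ratio relative to water
#'
#' Ratio of linear stopping powers material/water from the Bethe stopping
#' number: relative electron density times the ratio of stopping numbers
#' `L = ln(2 m_e c^2 beta^2 gamma^2 / I) - beta^2`, with the material mean
#' excitation energy `I` from Bragg-additivity (log-average over electron
#' fractions, elemental `I` values from a bundled ICRU-49-style table). The
#' water reference uses the same additivity rule so that water at density 1
#' maps to exactly 1.
#'
#' @param material A [material_spec()].
#' @param energy_MeV Proton kinetic energy in MeV, in `[1, 300]`.
#' @return Dimensionless SPR.
#' @export
#' @examples
#' compute_spr(spacer_material(), 198.3)
compute_spr <- function(material, energy_MeV) {
  stopifnot(inherits(material, "material_spec"))
  if (!is.finite(energy_MeV) || energy_MeV < 1 || energy_MeV > 300) {
    stop("energy_MeV must be in [1, 300]", call. = FALSE)
  }
  ef <- electron_fractions(material)
  if (ef$epg <= 0) stop("material has zero electron density", call. = FALSE)
  wat <- water_material()
  efw <- electron_fractions(wat)
  gamma <- 1 + energy_MeV / PROTON_REST_MEV
  gamma2 <- gamma^2
  beta2 <- 1 - 1 / gamma2
  I_m <- exp(sum(ef$frac * log(ef$I_eV)))
  I_w <- exp(sum(efw$frac * log(efw$I_eV)))
  rho_e_rel <- material$density * ef$epg / (1.0 * efw$epg)
  rho_e_rel * bethe_L(beta2, gamma2, I_m) / bethe_L(beta2, gamma2, I_w)
}

#' Power-law effective atomic number
#'
#' `Z_eff = (sum_i f_i Z_i^m)^(1/m)` with `f_i` the electron fractions
#' (weight fraction times Z/A, normalised). Default exponent `m = 3.5`
#' (photoelectric-regime convention).
#'
#' @param material A [material_spec()].
#' @param m Exponent, > 0.
#' @return Dimensionless effective Z.
#' @export
#' @examples
#' effective_z(spacer_material())
effective_z <- function(material, m = 3.5) {
  stopifnot(inherits(material, "material_spec"))
  if (!is.finite(m) || m <= 0) stop("m must be > 0", call. = FALSE)
  if (length(material$elements) == 0) stop("empty composition", call. = FALSE)
  ef <- electron_fractions(material)
  (sum(ef$frac * ef$Z^m))^(1 / m)
}

#' HU to stopping-power-ratio calibration curve
#'
#' A piecewise-linear map defined by `(HU, SPR)` knots. HU must be strictly
#' increasing, SPR non-decreasing, and the curve must pass through
#' `(0, 1)` (water) within 1e-6.
#'
#' @param knots Data frame / tibble with numeric columns `hu` and `spr`.
#' @return Object of class `hu_curve`.
#' @export
hu_curve <- function(knots) {
  knots <- as.data.frame(knots)
  stopifnot(all(c("hu", "spr") %in% names(knots)))
  if (nrow(knots) < 2) stop("curve needs at least 2 knots", call. = FALSE)
  knots <- knots[order(knots$hu), c("hu", "spr")]
  if (any(diff(knots$hu) <= 0)) stop("HU knots must be strictly increasing",
                                     call. = FALSE)
  if (any(diff(knots$spr) < 0)) stop("SPR knots must be non-decreasing",
                                     call. = FALSE)
  at0 <- approx(knots$hu, knots$spr, xout = 0, rule = 2)$y
  if (abs(at0 - 1) > 1e-6) {
    stop("curve must pass through (HU = 0, SPR = 1)", call. = FALSE)
  }
  structure(list(knots = tibble::as_tibble(knots)), class = "hu_curve")
}

#' Default HU to SPR calibration
#'
#' A representative soft-tissue/bone piecewise-linear curve with knots
#' (-1000, 0.001), (-100, 0.93), (0, 1.00), (100, 1.10), (1600, 1.85).
#' Any institutional curve can be supplied instead via [hu_curve()].
#'
#' @return An `hu_curve`.
#' @export
default_hu_curve <- function() {
  hu_curve(data.frame(
    hu = c(-1000, -100, 0, 100, 1600),
    spr = c(0.001, 0.93, 1.00, 1.10, 1.85)
  ))
}

#' Map HU values through a calibration curve
#'
#' Piecewise-linear interpolation, clamped to the end knots outside the knot
#' range. Accepts a numeric vector/array or an [image_grid()] (shape and
#' geometry preserved, unit retagged to `"SPR"`).
#'
#' @param hu Numeric vector/array of HU, or an `image_grid` tagged `"HU"`.
#' @param curve An [hu_curve()]; default [default_hu_curve()].
#' @return Same shape as the input (grid in, grid out).
#' @export
hu_to_spr <- function(hu, curve = default_hu_curve()) {
  stopifnot(inherits(curve, "hu_curve"))
  if (inherits(hu, "image_grid")) {
    out <- approx(curve$knots$hu, curve$knots$spr, xout = as.vector(hu$values),
                  rule = 2)$y
    return(image_grid(array(out, dim(hu)), hu$spacing, hu$origin, unit = "SPR"))
  }
  out <- approx(curve$knots$hu, curve$knots$spr, xout = as.vector(hu), rule = 2)$y
  if (is.array(hu)) array(out, dim(hu)) else out
}

#' Spacer material-override scenario
#'
#' * `"NM"` (no material override): spacer SPR comes from the HU curve, so the
#'   iodinated spacer is treated as a high-density structure.
#' * `"WM"` (water override): spacer SPR forced to 1.0.
#' * `"TM"` (true material): spacer SPR from the elemental composition via
#'   [compute_spr()]; the study's ground truth.
#'
#' @param kind One of `"NM"`, `"WM"`, `"TM"`.
#' @param material For `"TM"`, the spacer [material_spec()]
#'   (default [spacer_material()]).
#' @return Object of class `scenario`.
#' @export
scenario <- function(kind = c("NM", "WM", "TM"), material = NULL) {
  kind <- match.arg(kind)
  if (kind == "TM") {
    if (is.null(material)) material <- spacer_material()
    stopifnot(inherits(material, "material_spec"))
  } else {
    material <- NULL
  }
  structure(list(kind = kind, material = material), class = "scenario")
}

#' Build the SPR grid for a material-override scenario
#'
#' Non-spacer voxels always map through the HU calibration curve. Spacer
#' voxels depend on the scenario: NM uses the curve on the (iodinated) HU, WM
#' forces 1.0, TM uses the theoretical SPR of the spacer composition at the
#' given proton energy.
#'
#' @param hu [image_grid()] of HU (the iodinated CT).
#' @param rois Named list of logical masks; must contain `spacer`.
#' @param scen A [scenario()] or one of `"NM"`, `"WM"`, `"TM"`.
#' @param curve [hu_curve()] calibration.
#' @param energy_MeV Proton energy used for the TM theoretical SPR.
#' @return [image_grid()] tagged `"SPR"`, aligned with `hu`.
#' @export
build_spr_grid <- function(hu, rois, scen, curve = default_hu_curve(),
                           energy_MeV = 198.3) {
  stopifnot(inherits(hu, "image_grid"))
  if (is.character(scen)) scen <- scenario(scen)
  stopifnot(inherits(scen, "scenario"))
  if (!"spacer" %in% names(rois)) stop("rois must contain 'spacer'", call. = FALSE)
  mask <- check_mask(rois$spacer, hu)
  spr <- hu_to_spr(hu, curve)
  if (scen$kind == "WM") {
    spr$values[mask] <- 1.0
  } else if (scen$kind == "TM") {
    spr$values[mask] <- compute_spr(scen$material, energy_MeV)
  }
  spr
}
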