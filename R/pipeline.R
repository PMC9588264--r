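# End-to-end cohort analysis: phantom -> iodination -> scenario SPR grids ->
# TM-optimized plan -> NM/WM/TM dose recalculation -> gamma passing ratios ->
# dosimetric indices and paired differences -> cohort permutation tests and
# boxplot summaries.

ROI_EUD_A <- c(prostate = -10, seminal_vesicles = -10, ctv = -10,
               rectum = 8, bladder = 8, nvb = 8)

#' Run the full spacer-material cohort analysis
#'
#' For each synthetic case: generate a phantom, iodinate the spacer, build
#' the NM/WM/TM SPR grids, optimize the two-lateral-beam plan on TM, hold the
#' plan fixed while recalculating dose on NM and WM, compute 3D gamma passing
#' ratios (per criteria level and ROI) for the TM-NM and TM-WM pairs, and
#' collect dosimetric indices (D02...D98, mean dose, EUD) per scenario. At
#' the cohort level, per-(roi, metric, pair) paired sign-flip permutation
#' tests are run on the TM-minus-other differences, and boxplot statistics
#' summarise the passing ratios.
#'
#' Everything is reproducible from `master_seed`; per-case seeds are derived
#' as `master_seed * 1000 + case`.
#'
#' @param n_cases Number of synthetic cases (default 20).
#' @param base_params [phantom_params()] for the cohort; case geometry is
#'   jittered around it.
#' @param master_seed Master RNG seed.
#' @param rx_cgy Prescription in cGy (default 7000 cGy = 70 Gy in 28
#'   fractions).
#' @param curve [hu_curve()] HU-to-SPR calibration.
#' @param material Spacer [material_spec()] for the TM scenario.
#' @param energy_MeV Proton energy anchor for the TM SPR (default 198.3).
#' @param model [depth_dose_model()] for the pencil-beam engine.
#' @param criteria_list List of [gamma_criteria()]; defaults to 1%/1 mm,
#'   2%/2 mm and 3%/3 mm with a common 0.3 mm interpolation step (equal
#'   absolute steps keep the per-voxel gamma, and hence the passing ratios,
#'   monotone across criteria).
#' @param pr_rois Character vector of ROI names to report passing ratios
#'   for.
#' @param metric_rois Named numeric vector of EUD exponents per ROI used for
#'   the index tables (`nvb` means the union of both bundles).
#' @param n_perm Permutations per test (default 1000; exhaustive when
#'   `2^n_cases <= 4096`).
#' @param ray_spacing,margin Plan geometry, mm (see [optimize_plan()]).
#' @param output_dir Optional directory: per-case volumes (NIfTI + JSON
#'   sidecars), CSV tables and a JSON manifest are written there.
#' @param verbose Print per-case progress.
#' @return Object of class `cohort_report` with tibbles `pr` (case, pair,
#'   roi, criteria, PR), `indices` (case, scenario, roi, metric, value),
#'   `diffs` (case, pair, roi, metric, diff in cGy), `stats` (permutation
#'   tests), `box` (PR boxplot stats), plus `manifest` and `config`.
#' @export
run_cohort_analysis <- function(n_cases = 20,
                                base_params = phantom_params(),
                                master_seed = 1L,
                                rx_cgy = 7000,
                                curve = default_hu_curve(),
                                material = spacer_material(),
                                energy_MeV = 198.3,
                                model = depth_dose_model(),
                                criteria_list = list(
                                  gamma_criteria(1, 1, subsample = 0.3),
                                  gamma_criteria(2, 2, subsample = 0.15),
                                  gamma_criteria(3, 3, subsample = 0.1)),
                                pr_rois = c("ctv", "rectum", "bladder", "nvb",
                                            "body"),
                                metric_rois = ROI_EUD_A,
                                n_perm = 1000,
                                ray_spacing = 4, margin = 5,
                                output_dir = NULL,
                                verbose = FALSE) {
  cases <- generate_cohort(n_cases, base_params, master_seed)
  scen <- list(NM = scenario("NM"), WM = scenario("WM"),
               TM = scenario("TM", material))
  pr_rows <- list(); idx_rows <- list(); fail <- character(0)
  if (!is.null(output_dir)) dir.create(output_dir, showWarnings = FALSE,
                                       recursive = TRUE)
  for (case in cases) {
    ok <- tryCatch({
      rois <- case$rois
      rois$nvb <- rois$nvb_left | rois$nvb_right
      spr <- lapply(scen, function(s)
        build_spr_grid(case$hu, rois, s, curve, energy_MeV))
      plan <- optimize_plan(spr$TM, rois, rx_cgy, model,
                            ray_spacing = ray_spacing, margin = margin)
      dose <- lapply(spr, function(g) compute_dose(plan, g, model))
      roi_masks <- rois[intersect(pr_rois, names(rois))]
      for (pair_to in c("NM", "WM")) {
        tab <- pr_table(dose$TM, dose[[pair_to]], roi_masks, criteria_list)
        tab$case <- case$case_id
        tab$pair <- paste0("TM-", pair_to)
        pr_rows[[length(pr_rows) + 1]] <- tab
      }
      for (sname in names(dose)) {
        for (rn in names(metric_rois)) {
          if (!rn %in% names(rois)) next
          m <- dose_metrics(dose[[sname]], rois[[rn]],
                            eud_a = metric_rois[[rn]])
          m$case <- case$case_id; m$scenario <- sname; m$roi <- rn
          idx_rows[[length(idx_rows) + 1]] <- m
        }
      }
      if (!is.null(output_dir)) {
        cd <- file.path(output_dir, case$case_id)
        dir.create(cd, showWarnings = FALSE)
        write_volume(case$hu, file.path(cd, "hu.nii.gz"), seed = case$seed)
        for (sname in names(dose)) {
          write_volume(dose[[sname]],
                       file.path(cd, sprintf("dose_%s.nii.gz", sname)))
        }
        for (rn in names(rois)) {
          write_mask(rois[[rn]], case$hu,
                     file.path(cd, sprintf("mask_%s.nii.gz", rn)))
        }
      }
      if (verbose) message(case$case_id, " done")
      TRUE
    }, error = function(e) {
      warning(sprintf("case %s failed at cohort stage: %s", case$case_id,
                      conditionMessage(e)), call. = FALSE)
      FALSE
    })
    if (!ok) fail <- c(fail, case$case_id)
  }
  pr <- dplyr::bind_rows(pr_rows)
  indices <- dplyr::bind_rows(idx_rows)

  diffs <- indices |>
    tidyr::pivot_wider(names_from = "scenario", values_from = "value") |>
    tidyr::pivot_longer(cols = c("NM", "WM"), names_to = "other",
                        values_to = "other_value") |>
    dplyr::mutate(pair = paste0("TM-", .data$other),
                  diff = .data$TM - .data$other_value) |>
    dplyr::select("case", "pair", "roi", "metric", "diff")

  stats <- diffs |>
    dplyr::group_by(.data$pair, .data$roi, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) return(tibble::tibble())
      tidy(paired_permutation_test(d$diff, n_perm = n_perm,
                                   seed = master_seed))
    }) |>
    dplyr::ungroup()

  box <- pr |>
    dplyr::filter(!is.na(.data$pr)) |>
    dplyr::group_by(.data$pair, .data$roi, .data$criteria) |>
    dplyr::group_modify(function(d, key) tidy(box_summary(d$pr))) |>
    dplyr::ungroup()

  config <- list(n_cases = n_cases, master_seed = master_seed,
                 rx_cgy = rx_cgy, energy_MeV = energy_MeV,
                 shape = base_params$shape, spacing = base_params$spacing,
                 ray_spacing = ray_spacing, margin = margin, n_perm = n_perm,
                 criteria = vapply(criteria_list, function(cr)
                   sprintf("%g%%/%gmm", cr$dose_pct, cr$dta_mm), character(1)),
                 failed_cases = fail)
  report <- structure(list(pr = pr, indices = indices, diffs = diffs,
                           stats = stats, box = box,
                           manifest = attr(cases, "manifest"),
                           config = config),
                      class = "cohort_report")
  if (!is.null(output_dir)) {
    utils::write.csv(pr, file.path(output_dir, "pr_table.csv"),
                     row.names = FALSE)
    utils::write.csv(indices, file.path(output_dir, "indices.csv"),
                     row.names = FALSE)
    utils::write.csv(diffs, file.path(output_dir, "index_diffs.csv"),
                     row.names = FALSE)
    utils::write.csv(stats, file.path(output_dir, "stats.csv"),
                     row.names = FALSE)
    jsonlite::write_json(config, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (length(fail) > 0) {
    warning(sprintf("%d case(s) failed: %s", length(fail),
                    paste(fail, collapse = ", ")), call. = FALSE)
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d case(s), pairs %s\n",
              length(unique(x$pr$case)),
              paste(unique(x$pr$pair), collapse = ", ")))
  s <- x$pr |>
    dplyr::filter(.data$roi == "all") |>
    dplyr::group_by(.data$pair, .data$criteria) |>
    dplyr::summarise(mean_pr = mean(.data$pr), .groups = "drop")
  print(s)
  invisible(x)
}

#' @rdname run_cohort_analysis
#' @param x,object A `cohort_report`.
#' @param ... Unused.
#' @export
tidy.cohort_report <- function(x, ...) x$stats

#' @rdname run_cohort_analysis
#' @export
glance.cohort_report <- function(x, ...) {
  pr_sum <- x$pr |>
    dplyr::filter(.data$roi == "all") |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(mean_pr = mean(.data$pr), .groups = "drop")
  tibble::tibble(
    n_cases = length(unique(x$pr$case)),
    n_failed = length(x$config$failed_cases),
    mean_pr_tm_nm = pr_sum$mean_pr[pr_sum$pair == "TM-NM"],
    mean_pr_tm_wm = pr_sum$mean_pr[pr_sum$pair == "TM-WM"],
    n_tests = nrow(x$stats),
    n_significant = sum(x$stats$p_value < 0.01)
  )
}

#' @rdname run_cohort_analysis
#' @export
autoplot.cohort_report <- function(object, ...) {
  ggplot2::ggplot(object$pr |> dplyr::filter(!is.na(.data$pr)),
                  ggplot2::aes(x = .data$roi, y = .data$pr,
                               fill = .data$pair)) +
    ggplot2::geom_boxplot(outlier.shape = 3) +
    ggplot2::facet_wrap(~.data$criteria) +
    ggplot2::labs(x = NULL, y = "gamma passing ratio",
                  fill = "scenario pair") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
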