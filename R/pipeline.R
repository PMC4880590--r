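#' Pipeline configuration
#'
#' One flat record of every tunable the end-to-end analysis uses, embedded
#' verbatim in the final report for provenance.
#'
#' @param k_parts number of equal-length blade parts (default 10).
#' @param n_sub trapezoid panels per part in the area integrals.
#' @param greenness_threshold excess-green DN threshold for segmentation.
#' @param midrib_frac central fraction of each transect excluded as midrib.
#' @param erosion_px margin erosion radius, pixels.
#' @param calibration `"published"` or the path of a calibration JSON
#'   written by [write_calibration_json()].
#' @param seed integer seed used for every stochastic stage.
#' @param dpi render/scan resolution.
#' @param noise_sd_dn sensor-noise SD for the simulate stage.
#' @param n_leaves population size for the variance stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(k_parts = 10L, n_sub = 100L,
                            greenness_threshold = 30, midrib_frac = 0.2,
                            erosion_px = 2L, calibration = "published",
                            seed = 1L, dpi = 300L, noise_sd_dn = 0,
                            n_leaves = 20L) {
  if (k_parts < 1) {
    stop_leafspad("`k_parts` must be >= 1.", "leafspad_invalid_parameter")
  }
  if (midrib_frac < 0 || midrib_frac >= 1) {
    stop_leafspad("`midrib_frac` must lie in [0, 1).",
                  "leafspad_invalid_parameter")
  }
  structure(list(k_parts = as.integer(k_parts), n_sub = as.integer(n_sub),
                 greenness_threshold = greenness_threshold,
                 midrib_frac = midrib_frac,
                 erosion_px = as.integer(erosion_px),
                 calibration = calibration, seed = as.integer(seed),
                 dpi = as.integer(dpi), noise_sd_dn = noise_sd_dn,
                 n_leaves = as.integer(n_leaves)),
            class = "pipeline_config")
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

stage_fail <- function(stage, msg, class = "leafspad_stage_error") {
  stop_leafspad(sprintf("stage '%s': %s", stage, msg), class)
}

#' Run the full measurement-position analysis
#'
#' Orchestrates the stages in method order: simulate (or load) a leaf scan,
#' normalize it against its reflectance standards, segment the blade, slice
#' it into equal-length parts, average digital numbers per part, convert
#' them to SPAD through the calibration, fit the quadratic chlorophyll
#' profile, digitize the blade shape, compute the area-weighted and
#' conventional representative values with their candidate positions,
#' simulate a blade population for the variance profile, and select the
#' recommended position. Per-stage artifacts (scan PNG, shape and segment
#' CSVs, profile JSON) and a final `report.json` — carrying the full config
#' and package version as provenance — are written to `out_dir`. The run is
#' deterministic for a fixed config and inputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param scan_path optional path to an existing scan PNG (with the JSON
#'   sidecar written by [write_leaf_scan()]); when `NULL` a synthetic scan
#'   is rendered from `n_rate`.
#' @param n_rate nitrogen-rate preset for the simulate stage (see
#'   [n_rate_profile()]).
#' @return the report, invisibly: list with the recommended position, the
#'   representative values and candidate roots, per-part SDs, and
#'   provenance.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         scan_path = NULL, n_rate = "N150") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  k <- config$k_parts

  # calibrate ---------------------------------------------------------------
  model <- if (identical(config$calibration, "published")) {
    published_calibration()
  } else {
    if (!file.exists(config$calibration)) {
      stage_fail("calibrate",
                 sprintf("calibration file not found: %s", config$calibration),
                 "leafspad_missing_input")
    }
    read_calibration_json(config$calibration)
  }
  stage_log("calibrate", sprintf("SPAD = %.4f DN + %.3f (%s band)",
                                 model$slope, model$intercept, model$band))

  # simulate / load ---------------------------------------------------------
  if (is.null(scan_path)) {
    true_profile <- n_rate_profile(n_rate)
    shape0 <- make_leaf_shape(true_profile$length_cm, 1.2, 0.5)
    scan <- render_leaf_scan(shape0, true_profile, model,
                             scan_config(seed = config$seed,
                                         noise_sd_dn = config$noise_sd_dn,
                                         dpi = config$dpi))
    write_leaf_scan(scan, file.path(out_dir, "scan.png"))
    stage_log("simulate", sprintf("rendered %s blade at %d DPI", n_rate,
                                  config$dpi))
  } else {
    if (!file.exists(scan_path)) {
      stage_fail("load", sprintf("scan not found: %s", scan_path),
                 "leafspad_missing_input")
    }
    scan <- read_leaf_scan(scan_path)
    stage_log("load", scan_path)
  }

  # process -----------------------------------------------------------------
  norm <- normalize_scan(scan)
  mask <- segment_leaf(norm, config$greenness_threshold)
  parts <- slice_segments(mask, k)
  segs <- segment_dn(norm, parts, midrib_frac = config$midrib_frac,
                     erosion_px = config$erosion_px)
  segs <- calibrate_segments(segs, model)
  write_segments_csv(segs, file.path(out_dir, "segments.csv"))
  shape <- extract_width_profile(mask, scan$dpi)
  write_shape_csv(shape, file.path(out_dir, "shape.csv"))
  stage_log("process", sprintf("%d parts, blade %.2f cm x %.2f cm max width",
                               k, attr(shape, "length_cm"),
                               max(shape$width_cm)))

  # profile -----------------------------------------------------------------
  Lt <- attr(shape, "length_cm")
  pts <- tibble::tibble(position_cm = (segs$part - 0.5) / k * Lt,
                        spad = segs$spad)
  pfit <- fit_profile(pts, length_cm = Lt)
  write_profile_json(pfit$profile, file.path(out_dir, "profile.json"))
  stage_log("profile", sprintf("r2 = %.4f, vertex at %.2f cm", pfit$r2,
                               pfit$vertex_position_cm))

  # position ----------------------------------------------------------------
  report_pos <- positions_report(shape, pfit$profile, segs$spad, k = k,
                                 n_sub = config$n_sub)
  stage_log("position", sprintf("C = %.3f, mean = %.3f",
                                report_pos$c_value,
                                report_pos$conventional_mean))

  # variance ----------------------------------------------------------------
  pop <- simulate_spad_population(pfit$profile, n_leaves = config$n_leaves,
                                  k = k, shape = shape,
                                  seed = config$seed)
  sds <- part_sd(pop)
  candidates <- report_pos$proportional_weighted
  choice <- if (length(candidates)) select_position(candidates, sds) else NULL
  stage_log("variance", if (is.null(choice)) "no candidate positions" else
    sprintf("recommended position: %.3f of blade length", choice$position_frac))

  report <- list(
    recommended_position_frac = if (is.null(choice)) NA else
      choice$position_frac,
    c_value = report_pos$c_value,
    conventional_mean = report_pos$conventional_mean,
    roots_weighted_cm = as.numeric(report_pos$roots_weighted),
    roots_conventional_cm = as.numeric(report_pos$roots_conventional),
    proportional_weighted = report_pos$proportional_weighted,
    proportional_conventional = report_pos$proportional_conventional,
    part_sd = sds$sd,
    blade_length_cm = Lt,
    blade_area_cm2 = sum(report_pos$part_areas),
    profile = unclass(pfit$profile)[c("a2", "a1", "a0", "length_cm")],
    profile_r2 = pfit$r2,
    provenance = list(config = unclass(config),
                      package = "leafspad",
                      version = as.character(utils::packageVersion("leafspad")))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  stage_log("report", file.path(out_dir, "report.json"))
  invisible(report)
}
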