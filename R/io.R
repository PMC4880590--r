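#' Read and write the package's tabular and JSON artifacts
#'
#' Plain-text interchange: leaf shapes and segment tables as CSV,
#' calibrations, profiles and reports as JSON.
#'
#' @param shape a [leaf_shape]; `path` a file path.
#' @name leafspad-io
NULL

#' @rdname leafspad-io
#' @param path file path.
#' @export
write_shape_csv <- function(shape, path) {
  stopifnot(inherits(shape, "leaf_shape"))
  readr::write_csv(tibble::as_tibble(shape), path)
  invisible(path)
}

#' @rdname leafspad-io
#' @export
read_shape_csv <- function(path) {
  if (!file.exists(path)) {
    stop_leafspad(sprintf("shape file not found: %s", path),
                  "leafspad_missing_input")
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  leaf_shape(df)
}

#' @rdname leafspad-io
#' @param segments a segment table from [segment_dn()].
#' @export
write_segments_csv <- function(segments, path) {
  readr::write_csv(segments, path)
  invisible(path)
}

#' @rdname leafspad-io
#' @export
read_spad_parts_csv <- function(path) {
  if (!file.exists(path)) {
    stop_leafspad(sprintf("SPAD parts file not found: %s", path),
                  "leafspad_missing_input")
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("part", "spad") %in% names(df))) {
    stop_leafspad("SPAD parts CSV needs columns part, spad.",
                  "leafspad_invalid_input")
  }
  dplyr::arrange(df, .data$part)
}

#' @rdname leafspad-io
#' @param model a `dn_spad_calibration`.
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "dn_spad_calibration"))
  jsonlite::write_json(
    list(band = model$band, slope = model$slope, intercept = model$intercept,
         r2 = model$r2, n = model$n, p_value = model$p_value),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname leafspad-io
#' @export
read_calibration_json <- function(path) {
  if (!file.exists(path)) {
    stop_leafspad(sprintf("calibration file not found: %s", path),
                  "leafspad_missing_input")
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_calibration(band = j$band, slope = j$slope, intercept = j$intercept,
                  r2 = j$r2, n = j$n, p_value = j$p_value %||% NA_real_)
}

#' @rdname leafspad-io
#' @param profile a [chl_profile].
#' @export
write_profile_json <- function(profile, path) {
  stopifnot(inherits(profile, "chl_profile"))
  jsonlite::write_json(
    list(a2 = profile$a2, a1 = profile$a1, a0 = profile$a0,
         length_cm = profile$length_cm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname leafspad-io
#' @export
read_profile_json <- function(path) {
  if (!file.exists(path)) {
    stop_leafspad(sprintf("profile file not found: %s", path),
                  "leafspad_missing_input")
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  chl_profile(j$a2, j$a1, j$a0, j$length_cm)
}

#' @rdname leafspad-io
#' @export
read_dn_spad_pairs_csv <- function(path) {
  if (!file.exists(path)) {
    stop_leafspad(sprintf("calibration pairs file not found: %s", path),
                  "leafspad_missing_input")
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("dn", "spad") %in% names(df))) {
    stop_leafspad("calibration pairs CSV needs columns dn, spad.",
                  "leafspad_invalid_input")
  }
  df
}
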