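#' Leaf-scan raster objects
#'
#' A `leaf_scan` holds an 8-bit RGB raster (stored as a numeric
#' `H x W x 3` array of digital numbers in \[0, 255\]), its scan resolution
#' in DPI, and the pixel rectangles of the two reflectance-standard patches
#' (near-black and near-white cardboard placed at the edge of the scan bed)
#' used to normalize DN across images.
#'
#' @param raster numeric `H x W x 3` array, values in \[0, 255\].
#' @param dpi scan resolution, dots per inch.
#' @param standards list with elements `black` and `white`, each a pixel
#'   rectangle `c(row0, row1, col0, col1)` (inclusive, 1-based).
#' @return An object of class `leaf_scan`.
#' @export
leaf_scan <- function(raster, dpi, standards) {
  if (!is.array(raster) || length(dim(raster)) != 3L || dim(raster)[3] != 3L) {
    stop_leafspad("`raster` must be an H x W x 3 array.",
                  "leafspad_invalid_parameter")
  }
  if (min(raster) < 0 || max(raster) > 255) {
    stop_leafspad("raster DN must lie in [0, 255].",
                  "leafspad_invalid_parameter")
  }
  check_number(dpi, "dpi", positive = TRUE)
  if (!is.list(standards) || !all(c("black", "white") %in% names(standards))) {
    stop_leafspad("`standards` needs elements `black` and `white`.",
                  "leafspad_invalid_parameter")
  }
  h <- dim(raster)[1]; w <- dim(raster)[2]
  rect_check(standards$black, h, w, "standards$black")
  rect_check(standards$white, h, w, "standards$white")
  for (ch in 1:3) {
    if (rect_mean(raster[, , ch], standards$white) <=
        rect_mean(raster[, , ch], standards$black)) {
      stop_leafspad(
        "white standard must be brighter than the black standard in every channel.",
        "leafspad_degenerate_standards")
    }
  }
  structure(list(raster = raster, dpi = dpi, standards = standards),
            class = "leaf_scan")
}

#' @export
print.leaf_scan <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf("<leaf_scan> %d x %d px, %d DPI (%.3g x %.3g cm)%s\n",
              d[1], d[2], x$dpi, d[1] * 2.54 / x$dpi, d[2] * 2.54 / x$dpi,
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  invisible(x)
}

#' Configuration for synthetic scan rendering
#'
#' Collects the generator's tunables: RNG seed, sensor-noise level, scan
#' resolution and raw patch levels. Defaults reproduce the reference study
#' conditions: 300 DPI, 8-bit channels, noise-free unless requested.
#'
#' @param seed integer RNG seed; recorded with every render.
#' @param noise_sd_dn additive Gaussian sensor noise SD on DN (>= 0),
#'   applied per pixel before 8-bit clipping.
#' @param dpi scan resolution.
#' @param black_level,white_level raw DN of the black and white standard
#'   patches. With the defaults 0/255 the scanner is perfectly calibrated
#'   and normalization is the identity; other values emulate scanner
#'   gain/offset, which [normalize_scan()] removes.
#' @param margin_cm margin around all rendered elements, cm.
#' @param patch_w_cm,patch_h_cm reflectance-standard patch size, cm.
#' @param canvas_cm optional `c(width_cm, height_cm)` canvas size; when
#'   given, a leaf too long or wide to fit raises a geometry error.
#'   Default `NULL` sizes the canvas to fit.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(seed = 1L, noise_sd_dn = 0, dpi = 300L,
                        black_level = 0, white_level = 255,
                        margin_cm = 0.5, patch_w_cm = 2.5, patch_h_cm = 1.5,
                        canvas_cm = NULL) {
  check_number(noise_sd_dn, "noise_sd_dn", non_negative = TRUE)
  check_number(dpi, "dpi", positive = TRUE)
  if (white_level <= black_level) {
    stop_leafspad("`white_level` must exceed `black_level`.",
                  "leafspad_invalid_parameter")
  }
  structure(list(seed = as.integer(seed), noise_sd_dn = noise_sd_dn,
                 dpi = as.integer(dpi), black_level = black_level,
                 white_level = white_level, margin_cm = margin_cm,
                 patch_w_cm = patch_w_cm, patch_h_cm = patch_h_cm,
                 canvas_cm = canvas_cm),
            class = "scan_config")
}

#' Render a synthetic flatbed leaf scan
#'
#' Forward model of the scanner: inside the blade silhouette defined by
#' `shape`, the red digital number at axial position `L` is the inverse of
#' the calibration line, `(SPAD(L) - intercept) / slope`; the green channel
#' is an affine function of red (`0.55 * red + 110`, reproducing the
#' empirical ordering green > red > blue) and blue is a constant 20. The
#' background is white and two reflectance-standard patches (near-black,
#' near-white) sit along the top edge. Raw channel values are mapped through
#' the configured black/white levels (emulating scanner gain/offset), given
#' additive Gaussian sensor noise, rounded, and clipped to \[0, 255\]. The
#' silhouette is symmetric about a straight horizontal midline with the leaf
#' base at the image left.
#'
#' @param shape a [leaf_shape].
#' @param profile a [chl_profile] with the same blade length.
#' @param calibration a `dn_spad_calibration` (nonzero slope); defaults to
#'   [published_calibration()].
#' @param config a [scan_config()].
#' @return A [leaf_scan] whose `"ground_truth"` attribute records the true
#'   silhouette mask, shape, profile, calibration and config (for round-trip
#'   validation of the processing pipeline).
#' @export
render_leaf_scan <- function(shape, profile,
                             calibration = published_calibration(),
                             config = scan_config()) {
  stopifnot(inherits(shape, "leaf_shape"), inherits(profile, "chl_profile"),
            inherits(calibration, "dn_spad_calibration"))
  if (calibration$slope == 0) {
    stop_leafspad("calibration slope must be nonzero to invert.",
                  "leafspad_invalid_parameter")
  }
  px <- config$dpi / 2.54             # pixels per cm
  Lt <- attr(shape, "length_cm")
  maxw <- max(shape$width_cm)
  m <- config$margin_cm
  need_w_cm <- max(m + Lt + m, m + 2 * config$patch_w_cm + 2 * m)
  need_h_cm <- m + config$patch_h_cm + m + maxw + m
  if (!is.null(config$canvas_cm)) {
    if (need_w_cm > config$canvas_cm[1] || need_h_cm > config$canvas_cm[2]) {
      stop_leafspad(
        sprintf("leaf + standards need %.1f x %.1f cm but the canvas is %.1f x %.1f cm.",
                need_w_cm, need_h_cm, config$canvas_cm[1], config$canvas_cm[2]),
        "leafspad_geometry_error")
    }
    need_w_cm <- config$canvas_cm[1]
    need_h_cm <- config$canvas_cm[2]
  }
  W <- as.integer(ceiling(need_w_cm * px))
  H <- as.integer(ceiling(need_h_cm * px))

  raster <- array(255, dim = c(H, W, 3))
  cmpx <- function(x) as.integer(round(x * px))

  # standard patches along the top edge
  pr0 <- cmpx(m) + 1L
  pr1 <- pr0 + cmpx(config$patch_h_cm) - 1L
  b0 <- cmpx(m) + 1L
  b1 <- b0 + cmpx(config$patch_w_cm) - 1L
  w0 <- b1 + cmpx(m) + 1L
  w1 <- w0 + cmpx(config$patch_w_cm) - 1L
  black_rect <- c(pr0, pr1, b0, b1)
  white_rect <- c(pr0, pr1, w0, w1)
  raster[pr0:pr1, b0:b1, ] <- config$black_level
  raster[pr0:pr1, w0:w1, ] <- config$white_level

  # leaf band below the patches, base at the left
  mid_row <- pr1 + cmpx(m) + cmpx(maxw / 2)
  leaf_c0 <- cmpx(m) + 1L
  len_px <- cmpx(Lt)
  mask <- matrix(FALSE, H, W)
  gain <- (config$white_level - config$black_level) / 255

  cols <- seq_len(len_px)
  L <- (cols - 0.5) / px
  spad <- evaluate_profile(profile, L, warn = FALSE)
  red_target <- (spad - calibration$intercept) / calibration$slope
  green_target <- 0.55 * red_target + 110
  hw_px <- width_at(shape, L) / 2 * px
  rows_all <- seq_len(H)
  for (j in cols) {
    if (hw_px[j] <= 0) next
    rr <- rows_all[abs(rows_all - mid_row) <= hw_px[j]]
    cc <- leaf_c0 + j - 1L
    mask[rr, cc] <- TRUE
    raster[rr, cc, 1] <- config$black_level + red_target[j] * gain
    raster[rr, cc, 2] <- config$black_level + green_target[j] * gain
    raster[rr, cc, 3] <- config$black_level + 20 * gain
  }

  if (config$noise_sd_dn > 0) {
    raster <- withr::with_seed(config$seed, {
      raster + array(rnorm(length(raster), 0, config$noise_sd_dn),
                     dim = dim(raster))
    })
  }
  raster <- round(pmin(pmax(raster, 0), 255))

  out <- leaf_scan(raster, dpi = config$dpi,
                   standards = list(black = black_rect, white = white_rect))
  attr(out, "ground_truth") <- list(mask = mask, shape = shape,
                                    profile = profile,
                                    calibration = calibration,
                                    config = config)
  out
}

#' Read and write leaf scans as PNG with a JSON sidecar
#'
#' The raster is written as an 8-bit RGB PNG; DPI and the standard-patch
#' rectangles go to `<path>.json` so the scan can be re-read losslessly.
#'
#' @param scan a [leaf_scan].
#' @param path PNG file path.
#' @return `write_leaf_scan()` returns `path` invisibly; `read_leaf_scan()`
#'   returns a [leaf_scan].
#' @export
write_leaf_scan <- function(scan, path) {
  stopifnot(inherits(scan, "leaf_scan"))
  png::writePNG(scan$raster / 255, target = path)
  meta <- list(dpi = scan$dpi,
               standards = list(black = as.integer(scan$standards$black),
                                white = as.integer(scan$standards$white)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_leaf_scan
#' @export
read_leaf_scan <- function(path) {
  if (!file.exists(path) || !file.exists(paste0(path, ".json"))) {
    stop_leafspad(sprintf("scan file or sidecar missing: %s", path),
                  "leafspad_missing_input")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img <- img[, , 1:3, drop = FALSE] * 255
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  leaf_scan(round(img), dpi = meta$dpi,
            standards = list(black = meta$standards$black,
                             white = meta$standards$white))
}
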