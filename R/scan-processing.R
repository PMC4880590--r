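#' Normalize a scan against its reflectance standards
#'
#' Scanner exposure drifts between scans; the black and white cardboard
#' patches pin the response. Per channel, a linear map sends the
#' black-standard mean to 0 and the white-standard mean to 255, after which
#' values are rounded and clipped to the 8-bit range. Applying the map twice
#' changes nothing beyond rounding (idempotence).
#'
#' @param scan a [leaf_scan].
#' @return A normalized [leaf_scan] (attribute `normalized = TRUE`); the
#'   `"ground_truth"` attribute of synthetic renders is carried through.
#' @export
normalize_scan <- function(scan) {
  stopifnot(inherits(scan, "leaf_scan"))
  raster <- scan$raster
  for (ch in 1:3) {
    b <- rect_mean(raster[, , ch], scan$standards$black)
    w <- rect_mean(raster[, , ch], scan$standards$white)
    if (w <= b) {
      stop_leafspad(
        sprintf("channel %d: white-standard mean (%.1f) <= black-standard mean (%.1f).",
                ch, w, b),
        "leafspad_degenerate_standards")
    }
    raster[, , ch] <- round(pmin(255, pmax(0, 255 * (raster[, , ch] - b) / (w - b))))
  }
  out <- leaf_scan(raster, dpi = scan$dpi, standards = scan$standards)
  attr(out, "normalized") <- TRUE
  attr(out, "ground_truth") <- attr(scan, "ground_truth")
  out
}

#' Segment the leaf from a normalized scan
#'
#' Green tissue on the white scanner background is isolated with the
#' excess-green index `2G - R - B`: pixels above `greenness_threshold` are
#' candidate tissue (white background and the grey-scale standards score
#' near 0). The standard-patch rectangles are excluded outright, and the
#' largest 8-connected component is returned as the leaf.
#'
#' @param scan a normalized [leaf_scan].
#' @param greenness_threshold excess-green DN threshold (default 30).
#' @param min_pixels smallest acceptable component size; below it the
#'   segmentation is declared empty.
#' @return logical matrix mask of the leaf.
#' @export
segment_leaf <- function(scan, greenness_threshold = 30, min_pixels = 50L) {
  stopifnot(inherits(scan, "leaf_scan"))
  r <- scan$raster
  egi <- 2 * r[, , 2] - r[, , 1] - r[, , 3]
  cand <- egi > greenness_threshold
  for (rect in scan$standards) {
    cand[rect[1]:rect[2], rect[3]:rect[4]] <- FALSE
  }
  if (!any(cand)) {
    stop_leafspad("no pixels pass the greenness criterion.",
                  "leafspad_empty_segmentation")
  }
  lab <- EBImage::bwlabel(cand)
  sizes <- tabulate(lab[lab > 0])
  if (max(sizes) < min_pixels) {
    stop_leafspad(
      sprintf("largest green component has %d px (< min_pixels = %d).",
              max(sizes), min_pixels),
      "leafspad_empty_segmentation")
  }
  lab == which.max(sizes)
}

# Principal-axis coordinates of a mask. Returns per-pixel axial coordinate
# `t` (0 at the base end) and signed perpendicular offset `u`, both in
# pixels, plus the pixel indices. The base end is the end whose adjacent 10%
# of axial stations is wider on average (rice blades are widest nearer the
# base than the tip); `base_end = "min_t"` / `"max_t"` overrides the rule.
leaf_axis <- function(mask, base_end = c("auto", "min_t", "max_t")) {
  base_end <- match.arg(base_end)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop_leafspad("mask is empty.", "leafspad_empty_segmentation")
  }
  xy <- cbind(idx[, 2], idx[, 1])            # (col, row) = (x, y)
  ctr <- colMeans(xy)
  xc <- sweep(xy, 2, ctr)
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  ax <- ev$vectors[, 1]
  pv <- ev$vectors[, 2]
  # canonical orientation: axial coordinate increases with x (then y), so
  # min_t/max_t refer to a deterministic end of the blade
  if (ax[1] < 0 || (ax[1] == 0 && ax[2] < 0)) ax <- -ax
  t <- drop(xc %*% ax)
  u <- drop(xc %*% pv)
  t <- t - min(t)
  flip <- FALSE
  if (base_end == "max_t") {
    flip <- TRUE
  } else if (base_end == "auto") {
    Tm <- max(t)
    nb <- max(1, ceiling(0.1 * (Tm + 1)))
    w_lo <- mean_station_width(t, u, 0, nb - 1)
    w_hi <- mean_station_width(t, u, Tm - nb + 1, Tm)
    flip <- w_hi > w_lo
  }
  if (flip) t <- max(t) - t
  list(t = t, u = u, idx = idx, length_px = max(t) + 1)
}

mean_station_width <- function(t, u, lo, hi) {
  sel <- t >= lo & t <= hi
  if (!any(sel)) return(0)
  st <- round(t[sel])
  widths <- tapply(u[sel], st, function(v) diff(range(v)) + 1)
  mean(widths)
}

#' Digitize the blade width profile from a mask
#'
#' Re-implements manual shape digitization: the mask's longest principal
#' direction defines the blade axis; at `n_stations` evenly spaced stations
#' along it, the width is the transect extent of the mask perpendicular to
#' the axis, converted to cm via `2.54 / dpi` per pixel. The returned shape
#' starts at the base (position 0) and ends with width 0 at the recovered
#' blade length.
#'
#' @param mask logical leaf mask (from [segment_leaf()]).
#' @param dpi scan resolution of the mask's source image.
#' @param n_stations number of width stations along the axis.
#' @param base_end `"auto"` identifies the base as the wider end;
#'   `"min_t"`/`"max_t"` force an orientation.
#' @return A [leaf_shape].
#' @export
extract_width_profile <- function(mask, dpi, n_stations = 51L,
                                  base_end = "auto") {
  check_number(dpi, "dpi", positive = TRUE)
  axis <- leaf_axis(mask, base_end = base_end)
  s <- axis$t + 0.5                      # axial coordinate from the base edge
  Tlen <- axis$length_px
  edges <- seq(0, Tlen, length.out = n_stations + 1)
  bin <- pmin(n_stations, pmax(1L, findInterval(s, edges, rightmost.closed = TRUE)))
  widths_px <- vapply(seq_len(n_stations), function(b) {
    v <- axis$u[bin == b]
    if (length(v) == 0) 0 else diff(range(v)) + 1
  }, numeric(1))
  if (sum(widths_px > 0) < 3L) {
    stop_leafspad("mask has fewer than 3 stations of nonzero width.",
                  "leafspad_degenerate_shape")
  }
  cm <- 2.54 / dpi
  mids <- (edges[-1] + edges[-(n_stations + 1)]) / 2
  length_cm <- Tlen * cm
  samples <- tibble::tibble(
    position_cm = c(0, mids * cm, length_cm),
    width_cm = c(widths_px[1], widths_px, 0) * cm)
  leaf_shape(samples, length_cm = length_cm)
}

#' Slice a leaf mask into equal-length axial parts
#'
#' Partitions the mask by `k` intervals of equal AXIAL LENGTH (not equal
#' area) along the blade axis, base to tip — the digital analogue of cutting
#' the scanned blade into k equal slices. Part 1 contains the base end;
#' parts are disjoint and their union is the mask.
#'
#' @inheritParams extract_width_profile
#' @param k number of parts (>= 1), at most the axial pixel length.
#' @return An object of class `leaf_parts`: list with the integer label
#'   matrix `labels` (0 = background, 1..k base to tip), `k`, and the axis
#'   record used.
#' @export
slice_segments <- function(mask, k = 10L, base_end = "auto") {
  if (!is.numeric(k) || k < 1) {
    stop_leafspad("`k` must be >= 1.", "leafspad_invalid_parameter")
  }
  k <- as.integer(k)
  axis <- leaf_axis(mask, base_end = base_end)
  if (k > axis$length_px) {
    stop_leafspad(sprintf("k = %d exceeds the axial pixel length (%d).",
                          k, as.integer(axis$length_px)),
                  "leafspad_invalid_parameter")
  }
  s <- axis$t + 0.5
  part <- pmin(k, pmax(1L, ceiling(s / (axis$length_px / k))))
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[axis$idx] <- part
  structure(list(labels = labels, k = k, axis = axis),
            class = "leaf_parts")
}

#' Per-part mean digital numbers
#'
#' Computes per-channel mean DN for each blade part, after excluding pixels
#' a careful operator would avoid: a central midrib strip
#' (`midrib_frac` of each transect's width around the transect centre) and
#' the blade margin (binary erosion by `erosion_px` pixels). Part areas come
#' from the FULL part pixel count (exclusions affect the DN means only).
#' `spad` is left `NA` until a calibration is applied with
#' [calibrate_segments()].
#'
#' @param scan the (normalized) [leaf_scan] the parts were sliced from.
#' @param parts a `leaf_parts` from [slice_segments()].
#' @param midrib_frac fraction of each transect's width, centred on the
#'   transect, excluded as midrib (default 0.2).
#' @param erosion_px margin erosion radius in pixels (default 2).
#' @return A tibble with columns `part`, `area_cm2`, `dn_r`, `dn_g`,
#'   `dn_b`, `spad`, `pixel_count` (pixels surviving exclusion), with
#'   attributes `k` and `dpi`.
#' @export
segment_dn <- function(scan, parts, midrib_frac = 0.2, erosion_px = 2L) {
  stopifnot(inherits(scan, "leaf_scan"), inherits(parts, "leaf_parts"))
  if (midrib_frac < 0 || midrib_frac >= 1) {
    stop_leafspad("`midrib_frac` must lie in [0, 1).",
                  "leafspad_invalid_parameter")
  }
  mask <- parts$labels > 0L
  keep <- mask
  if (erosion_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(erosion_px) + 1L, "disc")
    keep <- EBImage::erode(mask, brush) > 0
  }
  axis <- parts$axis
  if (midrib_frac > 0) {
    st <- round(axis$t)
    centre <- tapply(axis$u, st, function(v) (max(v) + min(v)) / 2)
    wid <- tapply(axis$u, st, function(v) diff(range(v)) + 1)
    key <- as.character(st)
    off <- abs(axis$u - centre[key])
    is_midrib <- off <= midrib_frac / 2 * wid[key]
    mid_idx <- axis$idx[is_midrib, , drop = FALSE]
    keep[mid_idx] <- FALSE
  }
  r <- scan$raster[, , 1]; g <- scan$raster[, , 2]; b <- scan$raster[, , 3]
  cm2 <- (2.54 / scan$dpi)^2
  rows <- purrr::map(seq_len(parts$k), function(i) {
    part_px <- parts$labels == i
    surv <- part_px & keep
    n_surv <- sum(surv)
    if (n_surv == 0L) {
      stop_leafspad(sprintf("part %d has no pixels after exclusion.", i),
                    "leafspad_empty_part")
    }
    tibble::tibble(part = i,
                   area_cm2 = sum(part_px) * cm2,
                   dn_r = mean(r[surv]), dn_g = mean(g[surv]),
                   dn_b = mean(b[surv]),
                   spad = NA_real_, pixel_count = n_surv)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "k") <- parts$k
  attr(out, "dpi") <- scan$dpi
  out
}

#' Apply a DN-to-SPAD calibration to a segment table
#'
#' Fills the `spad` column from the mean DN of the calibration's band.
#'
#' @param segments a segment table from [segment_dn()].
#' @param model a `dn_spad_calibration`.
#' @return The segment table with `spad` filled in.
#' @export
calibrate_segments <- function(segments, model = published_calibration()) {
  stopifnot(is.data.frame(segments), inherits(model, "dn_spad_calibration"))
  col <- c(red = "dn_r", green = "dn_g", blue = "dn_b")[[model$band]]
  segments$spad <- dn_to_spad(model, segments[[col]])
  segments
}
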