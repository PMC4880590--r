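#' Per-part blade areas by numerical integration
#'
#' Splits the blade into `k` equal-length intervals from base to tip and
#' integrates the width profile over each with a composite trapezoid rule
#' (`n_sub` panels per part, widths interpolated linearly between the
#' shape's samples). Because the integrand is evaluated on a common
#' refinement, the part areas sum exactly (to floating point) to the
#' whole-blade integral, and the rule is exact for piecewise-linear widths.
#'
#' @param shape a [leaf_shape].
#' @param k number of equal-length parts (>= 1).
#' @param n_sub trapezoid panels per part (>= 1; default 100).
#' @return numeric vector of `k` areas in cm^2, with attribute `total`.
#' @examples
#' sh <- make_leaf_shape(24, 1.2, 0.5)
#' sum(segment_areas(sh, 10))
#' @export
segment_areas <- function(shape, k = 10L, n_sub = 100L) {
  stopifnot(inherits(shape, "leaf_shape"))
  if (!is.numeric(k) || k < 1 || !is.numeric(n_sub) || n_sub < 1) {
    stop_leafspad("`k` and `n_sub` must be >= 1.",
                  "leafspad_invalid_parameter")
  }
  k <- as.integer(k); n_sub <- as.integer(n_sub)
  Lt <- attr(shape, "length_cm")
  if (Lt <= 0) {
    stop_leafspad("shape has non-positive length.", "leafspad_invalid_input")
  }
  edges <- seq(0, Lt, length.out = k + 1)
  areas <- vapply(seq_len(k), function(i) {
    xs <- seq(edges[i], edges[i + 1], length.out = n_sub + 1)
    ws <- width_at(shape, xs)
    h <- (edges[i + 1] - edges[i]) / n_sub
    h * sum((ws[-1] + ws[-(n_sub + 1)]) / 2)
  }, numeric(1))
  attr(areas, "total") <- sum(areas)
  areas
}

#' Area-weighted representative SPAD value (the calculus method)
#'
#' The whole-blade representative value weights each part's mean SPAD by
#' that part's actual leaf area:
#' \deqn{C = \sum_i A_i \, SPAD_i \big/ \sum_i A_i.}
#' With equal areas this reduces to the arithmetic mean; in general it is a
#' convex combination, so `min(SPAD_i) <= C <= max(SPAD_i)`, and it is
#' invariant to rescaling all areas by a positive constant.
#'
#' @param areas numeric vector of positive part areas (cm^2).
#' @param spad_parts numeric vector of per-part mean SPAD values, same
#'   length.
#' @return the representative SPAD value `C`.
#' @export
weighted_c <- function(areas, spad_parts) {
  if (length(areas) != length(spad_parts) || length(areas) == 0L) {
    stop_leafspad("`areas` and `spad_parts` must have equal positive length.",
                  "leafspad_invalid_input")
  }
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    stop_leafspad("all areas must be finite and > 0.",
                  "leafspad_invalid_input")
  }
  sum(areas * spad_parts) / sum(areas)
}

#' Conventional representative SPAD value
#'
#' The conventional method represents the blade by the plain arithmetic
#' mean of the per-part SPAD values, ignoring how much leaf area each part
#' holds.
#'
#' @param spad_parts numeric vector of per-part SPAD values.
#' @return arithmetic mean.
#' @export
conventional_mean <- function(spad_parts) {
  if (length(spad_parts) == 0L || any(!is.finite(spad_parts))) {
    stop_leafspad("`spad_parts` must be non-empty and finite.",
                  "leafspad_invalid_input")
  }
  mean(spad_parts)
}

#' Invert the chlorophyll profile at a target SPAD value
#'
#' Solves `a2 L^2 + a1 L + (a0 - target) = 0` for the blade positions where
#' the fitted profile attains the representative value. A concave profile
#' yields two roots (one proximal, one distal), a vertex-level target a
#' double root, and a target above the maximum none — reported explicitly
#' rather than clamped, since clamping would fabricate positions. Roots
#' outside `[0, length_cm]` are returned but flagged.
#'
#' @param profile a [chl_profile] (or a linear profile with `a2 = 0`,
#'   `a1 != 0`).
#' @param target_spad the SPAD value to solve for.
#' @return numeric vector of 0-2 roots (cm, ascending) with attributes
#'   `status` (`"two_roots"`, `"double_root"`, `"one_root"` for the linear
#'   case, or `"no_real_roots"`) and `in_domain` (logical per root).
#' @examples
#' invert_profile(published_profile(), 38.42)
#' @export
invert_profile <- function(profile, target_spad) {
  stopifnot(inherits(profile, "chl_profile"))
  check_number(target_spad, "target_spad")
  a <- profile$a2; b <- profile$a1; c0 <- profile$a0 - target_spad
  finish <- function(roots, status) {
    roots <- sort(roots)
    attr(roots, "status") <- status
    attr(roots, "in_domain") <- roots >= 0 & roots <= profile$length_cm
    roots
  }
  if (a == 0) {
    if (b == 0) {
      stop_leafspad("profile is constant: cannot invert.",
                    "leafspad_invalid_profile")
    }
    return(finish(-c0 / b, "one_root"))
  }
  disc <- b^2 - 4 * a * c0
  if (disc < -1e-12) {
    return(finish(numeric(0), "no_real_roots"))
  }
  if (abs(disc) <= 1e-12) {
    return(finish(-b / (2 * a), "double_root"))
  }
  # numerically stable quadratic roots
  q <- -(b + sign(b) * sqrt(disc)) / 2
  finish(c(q / a, c0 / q), "two_roots")
}

#' Assemble the full representative-position report
#'
#' Runs the calculus method end to end for one blade: part areas from the
#' shape, the area-weighted `C` and the conventional arithmetic mean from
#' the per-part SPAD values, and the blade positions where the fitted
#' chlorophyll profile equals each — the candidate measurement positions —
#' both in cm and as fractions of blade length.
#'
#' @param shape a [leaf_shape].
#' @param profile a [chl_profile] describing SPAD along the same blade.
#' @param spad_parts per-part mean SPAD values, length `k`, base to tip.
#' @param k number of parts (defaults to `length(spad_parts)`).
#' @param n_sub trapezoid panels per part for the area integrals.
#' @return An object of class `position_report`: list with `c_value`,
#'   `conventional_mean`, `roots_weighted`, `roots_conventional` (cm),
#'   `proportional_weighted`, `proportional_conventional`, `part_areas`.
#' @export
positions_report <- function(shape, profile, spad_parts,
                             k = length(spad_parts), n_sub = 100L) {
  stopifnot(inherits(shape, "leaf_shape"), inherits(profile, "chl_profile"))
  if (k != length(spad_parts)) {
    stop_leafspad("`k` must equal length(spad_parts).",
                  "leafspad_invalid_input")
  }
  areas <- segment_areas(shape, k = k, n_sub = n_sub)
  c_value <- weighted_c(areas, spad_parts)
  conv <- conventional_mean(spad_parts)
  rw <- invert_profile(profile, c_value)
  rc <- invert_profile(profile, conv)
  Lt <- profile$length_cm
  structure(list(
    c_value = c_value,
    conventional_mean = conv,
    roots_weighted = rw,
    roots_conventional = rc,
    proportional_weighted = as.numeric(rw) / Lt,
    proportional_conventional = as.numeric(rc) / Lt,
    part_areas = as.numeric(areas),
    k = k
  ), class = "position_report")
}

#' @export
print.position_report <- function(x, ...) {
  cat("<position_report>\n")
  cat(sprintf("  area-weighted C      : %.4f SPAD -> positions %s cm\n",
              x$c_value, paste(sprintf("%.2f", x$roots_weighted),
                               collapse = ", ")))
  cat(sprintf("  conventional mean    : %.4f SPAD -> positions %s cm\n",
              x$conventional_mean,
              paste(sprintf("%.2f", x$roots_conventional), collapse = ", ")))
  cat(sprintf("  blade area           : %.3f cm^2 in %d parts\n",
              sum(x$part_areas), x$k))
  invisible(x)
}

#' @rdname positions_report
#' @param x a `position_report`.
#' @param ... unused.
#' @export
tidy.position_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(method = "weighted", value = x$c_value,
                   root_cm = as.numeric(x$roots_weighted),
                   root_frac = x$proportional_weighted),
    tibble::tibble(method = "conventional", value = x$conventional_mean,
                   root_cm = as.numeric(x$roots_conventional),
                   root_frac = x$proportional_conventional))
}

#' @rdname positions_report
#' @export
glance.position_report <- function(x, ...) {
  tibble::tibble(c_value = x$c_value,
                 conventional_mean = x$conventional_mean,
                 total_area_cm2 = sum(x$part_areas), k = x$k)
}
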