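#' Leaf-shape objects: a digitized blade width profile
#'
#' A `leaf_shape` is a tibble of `(position_cm, width_cm)` samples describing
#' the half-blade-symmetric width of a leaf as a function of distance from the
#' leaf base (collar). Positions are strictly increasing, start at 0 and end
#' at the blade length; the width at the tip is 0 (the blade tapers to a
#' point). This is the geometric input to the area-weighted representative
#' SPAD value.
#'
#' @param samples data frame with columns `position_cm` and `width_cm`.
#' @param length_cm blade length in cm; defaults to the last sampled position.
#' @param single_peak if `TRUE`, additionally require the width profile to
#'   have a single interior maximum and to taper to zero width at the tip
#'   (true of generated blades; digitized shapes may carry measurement
#'   wiggles, and analytic stand-ins such as rectangles may end at positive
#'   width, so those are validated without the two conditions).
#' @return A tibble of class `leaf_shape` with attribute `length_cm`.
#' @export
leaf_shape <- function(samples, length_cm = NULL, single_peak = FALSE) {
  if (!is.data.frame(samples) ||
      !all(c("position_cm", "width_cm") %in% names(samples))) {
    stop_leafspad("`samples` needs columns position_cm and width_cm.",
                  "leafspad_invalid_parameter")
  }
  pos <- samples$position_cm
  w <- samples$width_cm
  length_cm <- length_cm %||% pos[length(pos)]
  check_number(length_cm, "length_cm", positive = TRUE)
  if (length(pos) < 3L) {
    stop_leafspad("a leaf shape needs at least 3 samples.",
                  "leafspad_invalid_parameter")
  }
  if (any(diff(pos) <= 0)) {
    stop_leafspad("positions must be strictly increasing.",
                  "leafspad_invalid_shape")
  }
  if (abs(pos[1]) > 1e-9 || abs(pos[length(pos)] - length_cm) > 1e-9) {
    stop_leafspad("positions must start at 0 and end at length_cm.",
                  "leafspad_invalid_shape")
  }
  if (any(w < 0) || !all(is.finite(w))) {
    stop_leafspad("widths must be finite and >= 0.", "leafspad_invalid_shape")
  }
  if (single_peak && w[length(w)] > 1e-9) {
    stop_leafspad("width at the tip (last sample) must be 0.",
                  "leafspad_invalid_shape")
  }
  if (single_peak) {
    peak <- which.max(w)
    if (peak == 1L ||
        any(diff(w[seq_len(peak)]) < -1e-12) ||
        any(diff(w[peak:length(w)]) > 1e-12)) {
      stop_leafspad("width profile must have a single interior maximum.",
                    "leafspad_invalid_shape")
    }
  }
  out <- tibble::tibble(position_cm = pos, width_cm = w)
  attr(out, "length_cm") <- length_cm
  class(out) <- c("leaf_shape", class(out))
  out
}

#' Generate a parametric rice-like leaf blade shape
#'
#' Rice blade width rises from a small positive width at the collar to a
#' maximum near mid-blade and tapers to zero at the tip. The generator uses a
#' shifted beta-like family
#' \deqn{w(x) \propto (x + x_0)^\alpha (L_t - x)^\beta,}
#' with \eqn{x_0 = } `base_offset_frac` \eqn{\cdot L_t} and \eqn{\alpha}
#' solved from \eqn{\beta} so the maximum sits exactly at
#' `peak_frac * length_cm`. The small base offset gives a positive collar
#' width, and the family has a closed-form integral (incomplete beta), so the
#' blade area is checkable against numerical integration.
#'
#' @param length_cm blade length \eqn{L_t} in cm.
#' @param max_width_cm maximum blade width in cm.
#' @param peak_frac fractional position of the width maximum, in (0, 1).
#' @param n_samples number of evenly spaced width samples (>= 3).
#' @param base_offset_frac base offset \eqn{x_0/L_t}; controls the collar
#'   width (default 0.05).
#' @param tip_exponent \eqn{\beta}; values > 1 round the approach to the tip.
#' @return A [leaf_shape] with attributes `alpha`, `beta`, `x0_cm` recording
#'   the generating parameters.
#' @examples
#' sh <- make_leaf_shape(24, 1.2, 0.5, 101)
#' max(sh$width_cm)
#' @export
make_leaf_shape <- function(length_cm, max_width_cm, peak_frac,
                            n_samples = 101L, base_offset_frac = 0.05,
                            tip_exponent = 1.2) {
  check_number(length_cm, "length_cm", positive = TRUE)
  check_number(max_width_cm, "max_width_cm", positive = TRUE)
  check_fraction(peak_frac, "peak_frac")
  if (!is.numeric(n_samples) || n_samples < 3) {
    stop_leafspad("`n_samples` must be >= 3.", "leafspad_invalid_parameter")
  }
  x0 <- base_offset_frac * length_cm
  p <- peak_frac * length_cm
  beta <- tip_exponent
  # stationarity of (x + x0)^a (Lt - x)^b at p: a/(p + x0) = b/(Lt - p)
  alpha <- beta * (p + x0) / (length_cm - p)
  g <- function(x) (x + x0)^alpha * (length_cm - x)^beta
  xs <- seq(0, length_cm, length.out = n_samples)
  w <- max_width_cm * g(xs) / g(p)
  w[n_samples] <- 0
  out <- leaf_shape(tibble::tibble(position_cm = xs, width_cm = w),
                    length_cm = length_cm, single_peak = TRUE)
  attr(out, "alpha") <- alpha
  attr(out, "beta") <- beta
  attr(out, "x0_cm") <- x0
  out
}

#' Interpolated blade width at arbitrary positions
#'
#' Linear interpolation between the shape's samples; 0 outside `[0, length]`.
#'
#' @param shape a [leaf_shape].
#' @param position_cm numeric vector of positions from the leaf base, cm.
#' @return numeric vector of widths in cm.
#' @export
width_at <- function(shape, position_cm) {
  stopifnot(inherits(shape, "leaf_shape"))
  out <- approx(shape$position_cm, shape$width_cm, xout = position_cm,
                yleft = 0, yright = 0, ties = "ordered")$y
  out
}

#' @export
print.leaf_shape <- function(x, ...) {
  cat(sprintf("<leaf_shape> length %.3g cm, max width %.3g cm, %d samples\n",
              attr(x, "length_cm"), max(x$width_cm), nrow(x)))
  NextMethod()
}

#' @rdname leaf_shape
#' @param object,x a `leaf_shape`.
#' @param ... unused.
#' @export
autoplot.leaf_shape <- function(object, ...) {
  half <- dplyr::mutate(tibble::as_tibble(object), half = object$width_cm / 2)
  ggplot2::ggplot(half, ggplot2::aes(x = .data$position_cm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = -.data$half, ymax = .data$half),
                         fill = "darkseagreen3", colour = "darkgreen") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "distance from leaf base (cm)", y = "width (cm)",
                  title = "Blade silhouette") +
    ggplot2::theme_minimal()
}
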