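#' Fit the quadratic chlorophyll profile to positional SPAD data
#'
#' Ordinary least squares of SPAD on position and position squared, solved
#' through the QR (orthogonal) decomposition of the Vandermonde design —
#' three distinct positions are interpolated exactly, and noiseless samples
#' of any quadratic are recovered to numerical precision. Positions may be
#' absolute (cm from the leaf base) or proportional (fraction of blade
#' length); when the blade length is known both coefficient sets are stored,
#' related by rescaling the regressor.
#'
#' @param data data frame of per-position SPAD observations.
#' @param position,spad column names (strings); defaults `"position_cm"`
#'   and `"spad"`.
#' @param length_cm blade length. If `proportional = FALSE` it defaults to
#'   the largest observed position; it is required when
#'   `proportional = TRUE`.
#' @param proportional if `TRUE`, the position column holds fractions of
#'   blade length in \[0, 1\] rather than cm.
#' @return An object of class `profile_fit`: the fitted [chl_profile] (cm
#'   domain) in `$profile`, the proportional-regressor coefficients in
#'   `$coef_proportional`, plus `r2`, `n`, `vertex_position_cm`,
#'   `vertex_spad`.
#' @examples
#' pts <- data.frame(position_cm = c(0, 10, 20),
#'                   spad = c(33.763, 40.532, 38.261))
#' fit_profile(pts)$profile
#' @export
fit_profile <- function(data, position = "position_cm", spad = "spad",
                        length_cm = NULL, proportional = FALSE) {
  if (!is.data.frame(data) || !all(c(position, spad) %in% names(data))) {
    stop_leafspad("`data` must contain the position and spad columns.",
                  "leafspad_invalid_parameter")
  }
  x <- data[[position]]
  y <- data[[spad]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 3L) {
    stop_leafspad("need at least 3 distinct positions for a quadratic fit.",
                  "leafspad_singular_design")
  }
  if (proportional) {
    if (is.null(length_cm)) {
      stop_leafspad("`length_cm` is required with proportional positions.",
                    "leafspad_invalid_parameter")
    }
    x_cm <- x * length_cm
  } else {
    length_cm <- length_cm %||% max(x)
    x_cm <- x
  }
  fit <- lm(y ~ x_cm + I(x_cm^2))
  cf <- coef(fit)
  a0 <- unname(cf[1]); a1 <- unname(cf[2]); a2 <- unname(cf[3])
  sm <- summary(fit)
  profile <- chl_profile(a2 = a2, a1 = a1, a0 = a0, length_cm = length_cm)
  vertex_pos <- if (a2 != 0) -a1 / (2 * a2) else NA_real_
  structure(list(
    profile = profile,
    # same parabola with the regressor expressed as a fraction of length
    coef_proportional = c(a2 = a2 * length_cm^2, a1 = a1 * length_cm, a0 = a0),
    r2 = sm$r.squared,
    n = length(y),
    vertex_position_cm = vertex_pos,
    vertex_spad = if (is.na(vertex_pos)) NA_real_ else
      evaluate_profile(profile, vertex_pos, warn = FALSE),
    fit = fit
  ), class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  cat("<profile_fit>\n")
  print(x$profile)
  cat(sprintf("  r2 = %.4f, n = %d\n", x$r2, x$n))
  invisible(x)
}

#' @rdname fit_profile
#' @param x a `profile_fit`.
#' @param ... unused.
#' @export
tidy.profile_fit <- function(x, ...) {
  tibble::tibble(term = c("a2", "a1", "a0"),
                 estimate = unname(coef(x$profile)))
}

#' @rdname fit_profile
#' @export
glance.profile_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = x$n,
                 vertex_position_cm = x$vertex_position_cm,
                 vertex_spad = x$vertex_spad)
}

#' @rdname fit_profile
#' @param object a `profile_fit`.
#' @export
autoplot.profile_fit <- function(object, ...) {
  mf <- object$fit$model
  pts <- tibble::tibble(position_cm = mf[[2]], spad = mf[[1]])
  xs <- seq(0, object$profile$length_cm, length.out = 200)
  curve <- tibble::tibble(position_cm = xs,
                          spad = evaluate_profile(object$profile, xs,
                                                  warn = FALSE))
  ggplot2::ggplot(pts, ggplot2::aes(.data$position_cm, .data$spad)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_line(data = curve, colour = "darkgreen") +
    ggplot2::annotate("point", x = object$vertex_position_cm,
                      y = object$vertex_spad, shape = 4, size = 3,
                      colour = "red") +
    ggplot2::labs(x = "distance from leaf base (cm)", y = "SPAD",
                  title = "Chlorophyll profile fit") +
    ggplot2::theme_minimal()
}

#' Normalize SPAD values to the blade maximum
#'
#' Divides each value by the maximum, so the largest value maps to 1. Used
#' to compare chlorophyll distribution shapes across leaves and N rates
#' independently of their absolute level.
#'
#' @param spad_values numeric vector with a positive maximum.
#' @return numeric vector of relative values in (0, 1] (for positive input).
#' @export
normalize_to_max <- function(spad_values) {
  if (length(spad_values) == 0L || !all(is.finite(spad_values))) {
    stop_leafspad("input must be non-empty and finite.",
                  "leafspad_invalid_input")
  }
  m <- max(spad_values)
  if (m <= 0) {
    stop_leafspad("maximum must be positive to normalize.",
                  "leafspad_invalid_input")
  }
  spad_values / m
}

#' Range of relative SPAD values, in percent
#'
#' `(max - min) * 100` of a normalized vector: the spread of relative
#' chlorophyll along the blade, the quantity used to gauge how sensitive a
#' blade region is to nitrogen supply.
#'
#' @param relative_values numeric vector, typically from
#'   [normalize_to_max()].
#' @return spread in percentage points.
#' @export
relative_range <- function(relative_values) {
  if (length(relative_values) == 0L || !all(is.finite(relative_values))) {
    stop_leafspad("input must be non-empty and finite.",
                  "leafspad_invalid_input")
  }
  (max(relative_values) - min(relative_values)) * 100
}
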