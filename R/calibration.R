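#' Linear digital-number to SPAD calibration
#'
#' Scanner digital numbers (DN, 0-255 per channel) decrease as leaf
#' chlorophyll increases (darker tissue reflects less). A straight line fit
#' by ordinary least squares links the per-region mean DN of one scanner
#' band to co-located SPAD-meter readings:
#' \deqn{SPAD = slope \cdot DN + intercept.}
#'
#' @name calibration
NULL

new_calibration <- function(band, slope, intercept, r2, n, p_value,
                            fit = NULL) {
  structure(list(band = band, slope = slope, intercept = intercept,
                 r2 = r2, n = n, p_value = p_value, fit = fit),
            class = "dn_spad_calibration")
}

#' Fit a DN-to-SPAD calibration line
#'
#' Ordinary least squares of SPAD on DN for one scanner band; the QR
#' decomposition of the design matrix gives the exact least-squares
#' minimizer. Residuals sum to zero and a noiseless linear input is
#' recovered exactly (to numerical precision).
#'
#' @param data data frame with the calibration pairs.
#' @param dn,spad column names (as strings) holding the digital numbers and
#'   SPAD readings; defaults `"dn"` and `"spad"`.
#' @param band which scanner band the DN came from: `"red"` (the
#'   recommended carrier), `"green"` or `"blue"`.
#' @return A `dn_spad_calibration` with `slope`, `intercept`, `r2`
#'   (\eqn{1 - SS_{res}/SS_{tot}}), `n` and the regression F-test `p_value`.
#' @examples
#' d <- data.frame(dn = c(0, 1), spad = c(1, 3))
#' fit_dn_spad(d)$slope
#' @export
fit_dn_spad <- function(data, dn = "dn", spad = "spad", band = "red") {
  band <- match.arg(band, c("red", "green", "blue"))
  if (!is.data.frame(data) || !all(c(dn, spad) %in% names(data))) {
    stop_leafspad("`data` must contain the `dn` and `spad` columns.",
                  "leafspad_invalid_parameter")
  }
  x <- data[[dn]]
  y <- data[[spad]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) {
    stop_leafspad("need at least 2 calibration pairs.",
                  "leafspad_invalid_parameter")
  }
  if (var(x) == 0) {
    stop_leafspad("all DN values are equal: the design is singular.",
                  "leafspad_singular_design")
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  new_calibration(band = band,
                  slope = unname(coef(fit)[2]),
                  intercept = unname(coef(fit)[1]),
                  r2 = sm$r.squared, n = length(x), p_value = p, fit = fit)
}

#' The published red-band calibration for rice
#'
#' The reference red-band calibration, fitted on 39 rice leaves sampled at
#' tillering: `SPAD = -0.2509 R + 52.735`, explaining 85.1% of the SPAD
#' variance. Use it when no local calibration pairs are available; refit
#' with [fit_dn_spad()] when they are (scanner hardware differs). The exact
#' regression p-value was not reported (only p < 0.01), so `p_value` is
#' `NA`.
#'
#' @return A `dn_spad_calibration` with `slope = -0.2509`,
#'   `intercept = 52.735`, `r2 = 0.851`, `n = 39`.
#' @export
published_calibration <- function() {
  new_calibration(band = "red", slope = -0.2509, intercept = 52.735,
                  r2 = 0.851, n = 39L, p_value = NA_real_)
}

#' Convert digital numbers to SPAD values
#'
#' Applies `slope * dn + intercept`, vectorized over `dn`. Out-of-range DN
#' (outside the 8-bit interval \[0, 255\]) are permitted but flagged with a
#' warning, since they indicate a normalization or segmentation problem.
#'
#' @param model a `dn_spad_calibration`.
#' @param dn numeric vector of digital numbers.
#' @return numeric vector of SPAD values.
#' @examples
#' dn_to_spad(published_calibration(), c(62.3, 149.5))
#' @export
dn_to_spad <- function(model, dn) {
  stopifnot(inherits(model, "dn_spad_calibration"))
  if (!all(is.finite(c(model$slope, model$intercept)))) {
    stop_leafspad("calibration coefficients must be finite.",
                  "leafspad_invalid_parameter")
  }
  if (length(dn) && any(dn < 0 | dn > 255, na.rm = TRUE)) {
    warn("DN values outside [0, 255] passed to dn_to_spad()")
  }
  model$slope * dn + model$intercept
}

#' @export
print.dn_spad_calibration <- function(x, ...) {
  cat(sprintf("<dn_spad_calibration> SPAD = %.6g * DN(%s) + %.6g\n",
              x$slope, x$band, x$intercept))
  cat(sprintf("  r2 = %.3f, n = %d, p = %s\n", x$r2, x$n,
              ifelse(is.na(x$p_value), "NA (reported p < 0.01)",
                     format(x$p_value, digits = 3))))
  invisible(x)
}

#' @rdname fit_dn_spad
#' @param x a `dn_spad_calibration`.
#' @param ... unused.
#' @export
tidy.dn_spad_calibration <- function(x, ...) {
  tibble::tibble(term = c("intercept", "dn"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname fit_dn_spad
#' @export
glance.dn_spad_calibration <- function(x, ...) {
  tibble::tibble(band = x$band, r.squared = x$r2, nobs = x$n,
                 p.value = x$p_value)
}
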