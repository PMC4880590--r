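#' @importFrom rlang abort warn %||%
#' @importFrom stats approx coef lm pf predict rnorm sd var setNames
#' @importFrom utils head tail
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# invalid-parameter / invalid-input helpers with classed conditions so tests
# can assert on the condition class rather than message text
stop_leafspad <- function(msg, class) {
  abort(msg, class = c(class, "leafspad_error"))
}

check_number <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_leafspad(sprintf("`%s` must be a single finite number.", name),
                  "leafspad_invalid_parameter")
  }
  if (positive && x <= 0) {
    stop_leafspad(sprintf("`%s` must be > 0 (got %g).", name, x),
                  "leafspad_invalid_parameter")
  }
  if (non_negative && x < 0) {
    stop_leafspad(sprintf("`%s` must be >= 0 (got %g).", name, x),
                  "leafspad_invalid_parameter")
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  check_number(x, name)
  if (x <= 0 || x >= 1) {
    stop_leafspad(sprintf("`%s` must lie strictly between 0 and 1 (got %g).",
                          name, x), "leafspad_invalid_parameter")
  }
  invisible(x)
}

# pixel rectangle: integer vector c(row0, row1, col0, col1), inclusive bounds
rect_check <- function(rect, h, w, name = "rect") {
  if (length(rect) != 4L || any(!is.finite(rect))) {
    stop_leafspad(sprintf("`%s` must be c(row0, row1, col0, col1).", name),
                  "leafspad_invalid_parameter")
  }
  if (rect[1] < 1 || rect[2] > h || rect[3] < 1 || rect[4] > w ||
      rect[1] > rect[2] || rect[3] > rect[4]) {
    stop_leafspad(sprintf("`%s` lies outside the raster bounds.", name),
                  "leafspad_invalid_parameter")
  }
  invisible(rect)
}

rect_mean <- function(channel, rect) {
  mean(channel[rect[1]:rect[2], rect[3]:rect[4]])
}

in_rect <- function(rows, cols, rect) {
  rows >= rect[1] & rows <= rect[2] & cols >= rect[3] & cols <= rect[4]
}
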