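# shared fixtures for the test suite; everything built in code

# the published quadratic chlorophyll profile and red-band calibration
eq_profile <- function() chl_profile(-0.0452, 1.1289, 33.763, length_cm = 25)
cal_slope <- -0.2509
cal_intercept <- 52.735

# the published per-part SPAD values, base (part 1) to tip (part 10)
spadi_printed <- c(35.8, 36.5, 39.2, 40.3, 40.6, 39.8, 41.2, 39.4, 37.1, 34.3)

# a small noise-free synthetic scan for processing tests (low dpi keeps the
# raster small; patch levels offset from 0/255 so normalization is exercised)
small_scan <- function(dpi = 100, noise_sd_dn = 0, seed = 1L,
                       black_level = 12, white_level = 243,
                       shape = make_leaf_shape(25, 1.2, 0.5),
                       profile = published_profile()) {
  render_leaf_scan(shape, profile,
                   config = scan_config(seed = seed, noise_sd_dn = noise_sd_dn,
                                        dpi = dpi, black_level = black_level,
                                        white_level = white_level))
}

# closed-form blade area of the generated width family, computed here
# independently of the package's integration code:
#   w(x) = w_max * g(x) / g(p),  g(x) = (x + x0)^alpha (Lt - x)^beta
# Integral via the regularized incomplete beta function after the
# substitution t = (x + x0) / (Lt + x0).
closed_form_area <- function(shape) {
  Lt <- attr(shape, "length_cm")
  a <- attr(shape, "alpha"); b <- attr(shape, "beta")
  x0 <- attr(shape, "x0_cm")
  w_max <- max(shape$width_cm)
  p <- shape$position_cm[which.max(shape$width_cm)]
  g <- function(x) (x + x0)^a * (Lt - x)^b
  t0 <- x0 / (Lt + x0)
  full <- (Lt + x0)^(a + b + 1) * beta(a + 1, b + 1) *
    (1 - pbeta(t0, a + 1, b + 1))
  w_max / g(p) * full
}

# analytic masks for axis/width tests
rectangle_mask <- function(h = 120, w = 400, border = 10) {
  m <- matrix(FALSE, h, w)
  m[border:(h - border), border:(w - border)] <- TRUE
  m
}

# width grows linearly along the axis; narrow end at the left
triangle_mask <- function(len = 400, max_half = 40, pad = 15) {
  h <- 2 * (max_half + pad)
  m <- matrix(FALSE, h, len + 2 * pad)
  mid <- h / 2
  for (j in seq_len(len)) {
    half <- max_half * j / len
    rows <- which(abs(seq_len(h) - mid) <= half)
    m[rows, pad + j] <- TRUE
  }
  m
}
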