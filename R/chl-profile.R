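#' Quadratic chlorophyll profile along the blade
#'
#' Chlorophyll (expressed as SPAD units) along a mature cereal blade rises
#' from the base to a maximum at roughly mid-blade and falls toward the tip.
#' The package models this as a concave quadratic in the distance `L` (cm)
#' from the leaf base:
#' \deqn{SPAD(L) = a_2 L^2 + a_1 L + a_0.}
#'
#' @param a2,a1,a0 quadratic coefficients (leading, linear, intercept).
#' @param length_cm blade length, the upper end of the profile's domain.
#' @return An object of class `chl_profile`.
#' @seealso [make_profile()] to build one from base/peak values,
#'   [published_profile()] for the reference rice profile.
#' @export
chl_profile <- function(a2, a1, a0, length_cm) {
  for (nm in c("a2", "a1", "a0")) check_number(get(nm), nm)
  check_number(length_cm, "length_cm", positive = TRUE)
  structure(list(a2 = a2, a1 = a1, a0 = a0, length_cm = length_cm),
            class = "chl_profile")
}

#' @export
print.chl_profile <- function(x, ...) {
  cat(sprintf("<chl_profile> SPAD(L) = %.6g L^2 + %.6g L + %.6g on [0, %.3g] cm\n",
              x$a2, x$a1, x$a0, x$length_cm))
  if (x$a2 < 0) {
    v <- -x$a1 / (2 * x$a2)
    cat(sprintf("  vertex: %.4g cm (%.3g%% of blade), SPAD %.4g\n",
                v, 100 * v / x$length_cm, evaluate_profile(x, v, warn = FALSE)))
  }
  invisible(x)
}

#' @export
coef.chl_profile <- function(object, ...) {
  c(a2 = object$a2, a1 = object$a1, a0 = object$a0)
}

#' Build a concave quadratic profile from base and peak SPAD values
#'
#' Constructs the unique quadratic with vertex `(peak_frac * length_cm,
#' peak_spad)` and value `base_spad` at the leaf base (`L = 0`). Because
#' `peak_spad > base_spad`, the leading coefficient is always negative
#' (concave, single interior maximum).
#'
#' @param length_cm blade length in cm.
#' @param base_spad SPAD value at the leaf base.
#' @param peak_spad maximum SPAD value on the blade; must exceed `base_spad`.
#' @param peak_frac fractional position of the maximum, in (0, 1).
#' @return A [chl_profile].
#' @examples
#' make_profile(20, 30, 40, 0.5)
#' @export
make_profile <- function(length_cm, base_spad, peak_spad, peak_frac) {
  check_number(length_cm, "length_cm", positive = TRUE)
  check_number(base_spad, "base_spad")
  check_number(peak_spad, "peak_spad")
  check_fraction(peak_frac, "peak_frac")
  if (peak_spad <= base_spad) {
    stop_leafspad("`peak_spad` must exceed `base_spad` for a concave profile.",
                  "leafspad_invalid_parameter")
  }
  v <- peak_frac * length_cm
  k <- (peak_spad - base_spad) / v^2
  chl_profile(a2 = -k, a1 = 2 * k * v, a0 = base_spad, length_cm = length_cm)
}

#' Evaluate a chlorophyll profile
#'
#' @param profile a [chl_profile].
#' @param L_cm numeric vector of distances from the leaf base, cm.
#' @param warn warn when positions fall outside `[0, length_cm]`
#'   (extrapolation).
#' @return numeric vector of SPAD values.
#' @export
evaluate_profile <- function(profile, L_cm, warn = TRUE) {
  stopifnot(inherits(profile, "chl_profile"))
  if (!all(is.finite(L_cm))) {
    stop_leafspad("positions must be finite.", "leafspad_invalid_parameter")
  }
  if (warn && length(L_cm) &&
      any(L_cm < 0 | L_cm > profile$length_cm)) {
    warn("evaluating chlorophyll profile outside [0, length_cm] (extrapolation)")
  }
  profile$a2 * L_cm^2 + profile$a1 * L_cm + profile$a0
}

#' The reference rice chlorophyll-distribution profile
#'
#' The quadratic SPAD-vs-distance model reported for a rice blade under light
#' nitrogen deficiency (150 kg N/ha) at panicle initiation:
#' `SPAD = -0.0452 L^2 + 1.1289 L + 33.763`, `L` in cm from the leaf base.
#' The blade length is taken as 25 cm, consistent with the reported root
#' positions expressed both in cm and as fractions of blade length.
#'
#' @return A [chl_profile].
#' @export
published_profile <- function() {
  chl_profile(a2 = -0.0452, a1 = 1.1289, a0 = 33.763, length_cm = 25)
}

#' Simulated SPAD-meter readings along a profile
#'
#' Evaluates the profile at the requested positions and adds i.i.d. Gaussian
#' measurement noise. With `noise_sd_spad = 0` the readings equal the profile
#' exactly; for a fixed seed the output is reproducible. Randomness is scoped
#' to the call (no global RNG state is consumed).
#'
#' @param profile a [chl_profile].
#' @param positions_cm positions from the leaf base, cm, within the domain.
#' @param noise_sd_spad Gaussian noise SD in SPAD units (>= 0).
#' @param seed integer seed.
#' @return tibble with columns `position_cm`, `spad`.
#' @export
sample_spad_readings <- function(profile, positions_cm, noise_sd_spad = 0,
                                 seed = 1L) {
  stopifnot(inherits(profile, "chl_profile"))
  check_number(noise_sd_spad, "noise_sd_spad", non_negative = TRUE)
  if (length(positions_cm) == 0L) {
    return(tibble::tibble(position_cm = numeric(), spad = numeric()))
  }
  if (any(positions_cm < 0 | positions_cm > profile$length_cm)) {
    stop_leafspad("positions must lie within [0, length_cm].",
                  "leafspad_domain_error")
  }
  base <- evaluate_profile(profile, positions_cm)
  noise <- if (noise_sd_spad > 0) {
    withr::with_seed(seed, rnorm(length(positions_cm), 0, noise_sd_spad))
  } else {
    0
  }
  tibble::tibble(position_cm = positions_cm, spad = base + noise)
}

#' Mean profile SPAD over equal-length blade parts
#'
#' For each of `k` equal-length parts from base to tip, the mean of
#' `SPAD(L)` over the part — either the plain axial mean, or (when a shape is
#' supplied) the blade-area-weighted mean, which is what the mean digital
#' number over a part's pixels estimates in a scan.
#'
#' @param profile a [chl_profile].
#' @param k number of equal-length parts.
#' @param shape optional [leaf_shape] for width-weighting.
#' @param n_grid integration grid points per part.
#' @return tibble with columns `part`, `mid_frac` (part midpoint as a
#'   fraction of blade length), `spad`.
#' @export
profile_part_means <- function(profile, k = 10L, shape = NULL, n_grid = 201L) {
  stopifnot(inherits(profile, "chl_profile"))
  Lt <- profile$length_cm
  edges <- seq(0, Lt, length.out = k + 1)
  spad <- vapply(seq_len(k), function(i) {
    xs <- seq(edges[i], edges[i + 1], length.out = n_grid)
    ys <- evaluate_profile(profile, xs, warn = FALSE)
    if (is.null(shape)) {
      mean(ys)
    } else {
      wts <- width_at(shape, xs)
      trap <- function(v) sum((v[-1] + v[-n_grid]) / 2)
      trap(ys * wts) / trap(wts)
    }
  }, numeric(1))
  tibble::tibble(part = seq_len(k), mid_frac = (seq_len(k) - 0.5) / k,
                 spad = spad)
}
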