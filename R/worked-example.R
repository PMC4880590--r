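#' The reference worked example: per-part SPAD values
#'
#' The published per-part mean SPAD values of a rice blade under light N
#' deficiency (150 kg N/ha) at panicle initiation, parts 1 (base) to 10
#' (tip). Their arithmetic mean, 38.42, is the conventional representative
#' value; solving the reference chlorophyll profile
#' ([published_profile()]) at that value gives the conventional
#' representative positions 5.21 and 19.76 cm from the leaf base.
#'
#' @return tibble with columns `part`, `spad`.
#' @examples
#' conventional_mean(worked_example_segments()$spad)
#' @export
worked_example_segments <- function() {
  tibble::tibble(
    part = 1:10,
    spad = c(35.8, 36.5, 39.2, 40.3, 40.6, 39.8, 41.2, 39.4, 37.1, 34.3))
}

#' Run the worked example end to end
#'
#' Combines the published per-part SPAD values, the reference chlorophyll
#' profile, and a constant-width (rectangular) blade — under which the
#' area-weighted `C` reduces exactly to the arithmetic mean — into a
#' [positions_report()]. The reported conventional positions reproduce the
#' published 5.21 / 19.76 cm pair.
#'
#' @param k number of parts (10, matching the published table).
#' @param width_cm blade width of the rectangular stand-in shape.
#' @return a `position_report`.
#' @export
run_worked_example <- function(k = 10L, width_cm = 1.2) {
  profile <- published_profile()
  Lt <- profile$length_cm
  shape <- leaf_shape(
    tibble::tibble(position_cm = c(0, Lt / 2, Lt),
                   width_cm = rep(width_cm, 3)),
    length_cm = Lt)
  positions_report(shape, profile, worked_example_segments()$spad, k = k)
}
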