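#' U-shaped per-part noise profile
#'
#' Measurement variability along a rice blade is highest near the base
#' (narrow tissue with a thick midrib under the meter window) and the tip,
#' and lowest around 60-80% of the blade. This helper builds a per-part
#' noise SD with that shape: a quadratic in the part-midpoint fraction with
#' its minimum at `min_frac`.
#'
#' @param k number of parts.
#' @param sd_min SD at the minimum (SPAD units).
#' @param sd_max SD at the basal end of the blade.
#' @param min_frac fractional position of the SD minimum (default 0.7,
#'   i.e. between parts 7 and 8 of 10).
#' @return numeric vector of `k` SDs, base to tip.
#' @export
sd_profile_u <- function(k = 10L, sd_min = 0.4, sd_max = 2.0,
                         min_frac = 0.7) {
  mids <- (seq_len(k) - 0.5) / k
  sd_min + (sd_max - sd_min) * ((mids - min_frac) / (mids[1] - min_frac))^2
}

#' Simulate a population of per-part SPAD tables
#'
#' Draws `n_leaves` blades sharing one underlying chlorophyll profile: each
#' leaf's per-part SPAD equals the profile's per-part mean (width-weighted
#' when a shape is given), plus a leaf-level Gaussian offset (biological
#' level differences between blades) plus independent per-part noise with
#' the supplied — typically U-shaped — SD profile. Reproducible for a fixed
#' seed; no global RNG state is consumed.
#'
#' @param profile a [chl_profile].
#' @param n_leaves number of blades to draw.
#' @param k parts per blade.
#' @param shape optional [leaf_shape] for width-weighted part means.
#' @param part_sd per-part noise SD, length `k` (default [sd_profile_u()]).
#' @param leaf_offset_sd SD of the common per-leaf offset (default 0.5).
#' @param seed integer seed.
#' @return long tibble with columns `leaf`, `part`, `spad` (usable directly
#'   by [part_sd()]).
#' @export
simulate_spad_population <- function(profile, n_leaves = 20L, k = 10L,
                                     shape = NULL,
                                     part_sd = sd_profile_u(k),
                                     leaf_offset_sd = 0.5, seed = 1L) {
  stopifnot(inherits(profile, "chl_profile"))
  if (length(part_sd) != k || any(part_sd < 0)) {
    stop_leafspad("`part_sd` must be k non-negative SDs.",
                  "leafspad_invalid_parameter")
  }
  means <- profile_part_means(profile, k = k, shape = shape)$spad
  withr::with_seed(seed, {
    purrr::map(seq_len(n_leaves), function(l) {
      off <- rnorm(1, 0, leaf_offset_sd)
      tibble::tibble(leaf = l, part = seq_len(k),
                     spad = means + off + rnorm(k, 0, part_sd))
    }) |> dplyr::bind_rows()
  })
}

#' Reference chlorophyll profiles for three nitrogen rates
#'
#' Synthetic stand-ins for blades grown under severe N deficiency (`"N0"`,
#' 0 kg N/ha), light deficiency (`"N150"`, 150 kg N/ha) and normal supply
#' (`"N225"`, 225 kg N/ha) at panicle initiation. `"N150"` is the published
#' reference profile; the other two shift its level the way N supply shifts
#' leaf chlorophyll while keeping the concave along-blade form.
#'
#' @param preset one of `"N0"`, `"N150"`, `"N225"`.
#' @return a [chl_profile].
#' @export
n_rate_profile <- function(preset = c("N150", "N0", "N225")) {
  preset <- match.arg(preset)
  switch(preset,
         N150 = published_profile(),
         N0 = make_profile(25, base_spad = 29.5, peak_spad = 36.5,
                           peak_frac = 0.5),
         N225 = make_profile(25, base_spad = 35.5, peak_spad = 42.5,
                             peak_frac = 0.5))
}

#' Monte-Carlo check of the position-selection rule
#'
#' Repeatedly simulates the full diagnostic under the model the analysis
#' assumes — a concave quadratic chlorophyll profile, a single-peaked blade
#' shape, and U-shaped per-part measurement noise with its minimum between
#' 60 and 80% of the blade — and records which candidate position the
#' variance rule picks. Each run: draw a random concave profile; simulate a
#' blade population; estimate per-part SDs; fit the profile to the observed
#' part means; compute the area-weighted `C`; invert the fitted profile at
#' `C`; select among the roots by part SD. Under these conditions the
#' distal (~2/3-of-blade) root should be selected in the overwhelming
#' majority of runs.
#'
#' @param n_runs number of simulated populations.
#' @param seed integer seed (each run derives its own sub-seed).
#' @param n_leaves blades per population.
#' @param k parts per blade.
#' @return list with `rate` (fraction of runs selecting the distal root),
#'   `n_runs`, and a per-run tibble `runs`.
#' @export
mc_position_selection <- function(n_runs = 200L, seed = 1L, n_leaves = 20L,
                                  k = 10L) {
  shape <- make_leaf_shape(25, 1.2, 0.5)
  draws <- withr::with_seed(seed, {
    tibble::tibble(
      base = stats::runif(n_runs, 30, 36),
      gain = stats::runif(n_runs, 5, 8),
      peak_frac = stats::runif(n_runs, 0.45, 0.6),
      sub_seed = sample.int(.Machine$integer.max, n_runs))
  })
  runs <- purrr::pmap(draws, function(base, gain, peak_frac, sub_seed) {
    profile <- make_profile(25, base, base + gain, peak_frac)
    pop <- simulate_spad_population(profile, n_leaves = n_leaves, k = k,
                                   shape = shape, seed = sub_seed)
    sds <- part_sd(pop)
    obs_means <- pop |>
      dplyr::group_by(.data$part) |>
      dplyr::summarise(spad = mean(.data$spad), .groups = "drop")
    pts <- tibble::tibble(
      position_cm = (obs_means$part - 0.5) / k * 25,
      spad = obs_means$spad)
    fitted <- fit_profile(pts, length_cm = 25)$profile
    areas <- segment_areas(shape, k = k)
    cval <- weighted_c(areas, obs_means$spad)
    roots <- invert_profile(fitted, cval)
    if (length(roots) < 2L) {
      return(tibble::tibble(selected_frac = NA_real_, distal = FALSE))
    }
    fracs <- as.numeric(roots) / 25
    choice <- select_position(fracs, sds)
    tibble::tibble(selected_frac = choice$position_frac,
                   distal = isTRUE(all.equal(choice$position_frac,
                                             max(fracs))))
  }) |> dplyr::bind_rows()
  list(rate = mean(runs$distal), n_runs = n_runs, runs = runs)
}
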