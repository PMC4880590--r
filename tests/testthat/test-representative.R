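rect_shape <- function(length_cm = 24, width_cm = 0.9) {
  leaf_shape(tibble::tibble(position_cm = c(0, length_cm / 2, length_cm),
                            width_cm = rep(width_cm, 3)),
             length_cm = length_cm)
}

linear_shape <- function(length_cm = 24, slope = 0.125) {
  leaf_shape(tibble::tibble(position_cm = c(0, length_cm / 2, length_cm),
                            width_cm = slope * c(0, length_cm / 2, length_cm)),
             length_cm = length_cm)
}

test_that("part areas are exact on constant and linear width profiles", {
  sh <- rect_shape(24, 0.9)
  areas <- segment_areas(sh, 10)
  expect_equal(as.numeric(areas), rep(0.9 * 24 / 10, 10), tolerance = 1e-6)

  lin <- linear_shape(24, 0.125)
  areas <- segment_areas(lin, 10)
  # closed form for the distal part: 0.125 * (24^2 - 21.6^2) / 2
  expect_equal(areas[[10]], 0.125 * (24^2 - 21.6^2) / 2, tolerance = 1e-6)
  expect_equal(sum(areas), 0.125 * 24^2 / 2, tolerance = 1e-6)

  one <- segment_areas(lin, 1)
  expect_equal(as.numeric(one), sum(segment_areas(lin, 10)), tolerance = 1e-9)
})

test_that("part areas sum to the whole-blade integral and refine stably", {
  sh <- make_leaf_shape(25, 1.3, 0.45)
  a1 <- segment_areas(sh, 10, n_sub = 100)
  expect_equal(sum(a1), attr(a1, "total"), tolerance = 1e-12)
  a2 <- segment_areas(sh, 10, n_sub = 200)
  expect_equal(sum(a1), sum(a2), tolerance = 1e-6)
  expect_equal(as.numeric(a1), as.numeric(a2), tolerance = 1e-5)
})

test_that("weighted C reduces to the mean with equal areas and is convex", {
  expect_equal(weighted_c(rep(3, 10), spadi_printed), 38.42)
  expect_equal(weighted_c(1:10, spadi_printed), 2109.9 / 55)
  expect_equal(weighted_c(c(2, 7, 1), rep(5.5, 3)), 5.5)
  withr::with_seed(77, {
    for (i in 1:50) {
      n <- sample(2:15, 1)
      areas <- runif(n, 0.1, 5)
      spad <- runif(n, 20, 45)
      cv <- weighted_c(areas, spad)
      expect_equal(weighted_c(rep(runif(1, 0.5, 2), n), spad), mean(spad),
                   tolerance = 1e-12)
      expect_gte(cv, min(spad))
      expect_lte(cv, max(spad))
      # scale invariance of the weights
      expect_equal(weighted_c(areas * runif(1, 0.01, 100), spad), cv,
                   tolerance = 1e-12)
    }
  })
  expect_error(weighted_c(1:3, 1:4), class = "leafspad_invalid_input")
  expect_error(weighted_c(c(1, -1), c(2, 3)), class = "leafspad_invalid_input")
})

test_that("the conventional mean is the plain arithmetic mean", {
  expect_equal(conventional_mean(spadi_printed), 38.42)
  expect_equal(conventional_mean(7.3), 7.3)
  withr::with_seed(88, {
    v <- runif(10, 20, 45)
    expect_equal(conventional_mean(sample(v)), conventional_mean(v))
  })
  expect_error(conventional_mean(numeric(0)), class = "leafspad_invalid_input")
})

test_that("profile inversion reproduces the published positions", {
  pf <- eq_profile()
  roots <- invert_profile(pf, 38.42)
  expect_equal(round(as.numeric(roots), 2), c(5.21, 19.76))
  expect_equal(attr(roots, "status"), "two_roots")
  expect_true(all(attr(roots, "in_domain")))

  vtx_spad <- pf$a0 - pf$a1^2 / (4 * pf$a2)
  dbl <- invert_profile(pf, vtx_spad)
  expect_equal(attr(dbl, "status"), "double_root")
  expect_equal(as.numeric(dbl), 12.488, tolerance = 1e-3)

  none <- invert_profile(pf, 45)
  expect_length(none, 0)
  expect_equal(attr(none, "status"), "no_real_roots")

  lin <- chl_profile(0, 0.5, 30, length_cm = 25)
  expect_equal(as.numeric(invert_profile(lin, 35)), 10)
  expect_error(invert_profile(chl_profile(0, 0, 30, 25), 30),
               class = "leafspad_invalid_profile")
})

test_that("every returned root evaluates back to its target", {
  withr::with_seed(99, {
    for (i in 1:50) {
      base <- runif(1, 20, 38)
      pf <- make_profile(runif(1, 15, 30), base, base + runif(1, 2, 12),
                         runif(1, 0.3, 0.7))
      target <- runif(1, base - 2, base + runif(1, 1, 10))
      roots <- invert_profile(pf, target)
      for (r in as.numeric(roots)) {
        expect_equal(evaluate_profile(pf, r, warn = FALSE), target,
                     tolerance = 1e-6)
      }
    }
  })
})

test_that("the position report ties the pieces together coherently", {
  rep_eq <- positions_report(rect_shape(25, 1.2), eq_profile(), spadi_printed)
  # constant width: C equals the mean, weighted and conventional roots agree
  expect_equal(rep_eq$c_value, rep_eq$conventional_mean, tolerance = 1e-4)
  expect_equal(round(as.numeric(rep_eq$roots_conventional), 2),
               c(5.21, 19.76))
  expect_equal(as.numeric(rep_eq$roots_weighted),
               as.numeric(rep_eq$roots_conventional), tolerance = 1e-2)
  expect_equal(rep_eq$proportional_conventional,
               as.numeric(rep_eq$roots_conventional) / 25)
  expect_true(all(rep_eq$proportional_conventional >= 0 &
                    rep_eq$proportional_conventional <= 1))
  # bounds
  expect_gte(rep_eq$c_value, min(spadi_printed))
  expect_lte(rep_eq$c_value, max(spadi_printed))

  td <- tidy(rep_eq)
  expect_equal(nrow(td), 4)
  expect_equal(unique(td$method), c("weighted", "conventional"))
})

test_that("area weighting pulls C toward the SPAD of the wide region", {
  # nearly all blade area near the profile vertex -> C above the plain mean
  Lt <- 25
  sh <- leaf_shape(tibble::tibble(
    position_cm = c(0, 10, 12.5, 15, Lt),
    width_cm = c(0.02, 0.03, 3.0, 0.03, 0)), length_cm = Lt)
  pf <- eq_profile()
  spad_parts <- profile_part_means(pf, 10)$spad
  rep1 <- positions_report(sh, pf, spad_parts)
  # independent direct computation of the weighted mean
  areas <- segment_areas(sh, 10)
  expect_equal(rep1$c_value, sum(areas * spad_parts) / sum(areas),
               tolerance = 1e-12)
  expect_gt(rep1$c_value, rep1$conventional_mean)
})
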