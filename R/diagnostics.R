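#' Per-part standard deviation of SPAD across leaves
#'
#' Sample standard deviation (n - 1 denominator) of the per-part SPAD value
#' across a population of blades, per part index: the measurement-stability
#' profile along the blade. Accepts either a list of per-leaf segment
#' tables (each with `part` and `spad` columns) or one long data frame with
#' a `leaf` identifier.
#'
#' @param tables list of segment tables, or a long data frame with columns
#'   `leaf`, `part`, `spad`.
#' @return tibble with columns `part`, `mid_frac` (part midpoint as a
#'   fraction of blade length), `sd`, `n_leaves`.
#' @export
part_sd <- function(tables) {
  if (is.data.frame(tables)) {
    if (!all(c("leaf", "part", "spad") %in% names(tables))) {
      stop_leafspad("long input needs columns leaf, part, spad.",
                    "leafspad_invalid_input")
    }
    long <- tibble::as_tibble(tables[c("leaf", "part", "spad")])
  } else if (is.list(tables)) {
    if (length(tables) < 2L) {
      stop_leafspad("need at least 2 leaves to compute an SD.",
                    "leafspad_invalid_input")
    }
    ks <- vapply(tables, nrow, integer(1))
    if (length(unique(ks)) != 1L) {
      stop_leafspad("all segment tables must have the same part count.",
                    "leafspad_invalid_input")
    }
    long <- purrr::imap(tables, function(tb, i) {
      tibble::tibble(leaf = i, part = tb$part, spad = tb$spad)
    }) |> dplyr::bind_rows()
  } else {
    stop_leafspad("`tables` must be a list of tables or a long data frame.",
                  "leafspad_invalid_input")
  }
  counts <- dplyr::count(long, .data$leaf)
  if (nrow(counts) < 2L) {
    stop_leafspad("need at least 2 leaves to compute an SD.",
                  "leafspad_invalid_input")
  }
  if (length(unique(counts$n)) != 1L) {
    stop_leafspad("all leaves must have the same part count.",
                  "leafspad_invalid_input")
  }
  k <- counts$n[1]
  long |>
    dplyr::group_by(.data$part) |>
    dplyr::summarise(sd = sd(.data$spad), n_leaves = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(mid_frac = (.data$part - 0.5) / k,
                  .after = "part")
}

#' Plot the SD-along-the-blade profile
#'
#' @param sd_tbl output of [part_sd()].
#' @return a ggplot.
#' @export
plot_part_sd <- function(sd_tbl) {
  ggplot2::ggplot(sd_tbl,
                  ggplot2::aes(100 * .data$mid_frac, .data$sd)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance from leaf base (% of blade)",
                  y = "SD of SPAD across leaves",
                  title = "Measurement variability along the blade") +
    ggplot2::theme_minimal()
}

#' Standard deviation of single- and multi-position meter readings
#'
#' SPAD-meter readings are taken at positions a (1/3), b (1/2) and c (2/3)
#' of the distance from the leaf base on replicate leaves. For each of the
#' seven position combinations (a, b, c, ab, ac, bc, abc) every replicate
#' contributes the MEAN of its member-position readings, and the SD is
#' taken across replicates — quantifying how stable each measurement
#' protocol is. Grouped by `leaf_rank` when present.
#'
#' @param readings data frame with columns `replicate`, `position` (values
#'   `"a"`, `"b"`, `"c"`), `spad`, and optionally `leaf_rank`. Every
#'   replicate must have all three positions.
#' @return tibble with columns (`leaf_rank`,) `combination`, `sd`,
#'   `n_replicates`.
#' @export
dipositional_sd <- function(readings) {
  need <- c("replicate", "position", "spad")
  if (!is.data.frame(readings) || !all(need %in% names(readings))) {
    stop_leafspad("`readings` needs columns replicate, position, spad.",
                  "leafspad_invalid_input")
  }
  if (!all(readings$position %in% c("a", "b", "c"))) {
    stop_leafspad("positions must be 'a', 'b' or 'c'.",
                  "leafspad_invalid_input")
  }
  grouped <- "leaf_rank" %in% names(readings)
  combos <- list(a = "a", b = "b", c = "c", ab = c("a", "b"),
                 ac = c("a", "c"), bc = c("b", "c"), abc = c("a", "b", "c"))
  one_group <- function(df) {
    tab <- table(df$replicate, df$position)
    if (any(tab != 1L)) {
      stop_leafspad(
        "every replicate needs exactly one reading at each of a, b, c.",
        "leafspad_invalid_input")
    }
    if (nrow(tab) < 2L) {
      stop_leafspad("need at least 2 replicates.", "leafspad_invalid_input")
    }
    purrr::imap(combos, function(members, nm) {
      per_rep <- df |>
        dplyr::filter(.data$position %in% members) |>
        dplyr::group_by(.data$replicate) |>
        dplyr::summarise(score = mean(.data$spad), .groups = "drop")
      tibble::tibble(combination = nm, sd = sd(per_rep$score),
                     n_replicates = nrow(per_rep))
    }) |> dplyr::bind_rows()
  }
  if (grouped) {
    readings |>
      dplyr::group_by(.data$leaf_rank) |>
      dplyr::group_modify(~ one_group(.x)) |>
      dplyr::ungroup()
  } else {
    one_group(readings)
  }
}

#' Select the recommended measurement position
#'
#' Among the candidate positions where the profile attains the
#' representative value, picks the one whose containing blade part (part
#' `ceil(p * k)` for a fractional position `p`) has the lowest SD across
#' leaves — a representative position is only useful if readings there are
#' stable. Ties break toward the candidate closest to 2/3 of the blade,
#' the empirically low-variance region. Deterministic given its inputs.
#'
#' @param candidates_frac candidate positions as fractions of blade length
#'   (e.g. `positions_report()$proportional_weighted`).
#' @param sd_by_part output of [part_sd()] (tibble with `part` and `sd`),
#'   or a plain numeric vector of per-part SDs, base to tip.
#' @return An object of class `position_choice`: list with
#'   `position_frac`, `part`, `sd`, and a `candidates` rationale tibble.
#' @export
select_position <- function(candidates_frac, sd_by_part) {
  cand <- as.numeric(candidates_frac)
  if (length(cand) == 0L || any(!is.finite(cand))) {
    stop_leafspad("no finite candidate positions supplied.",
                  "leafspad_no_candidate")
  }
  if (is.data.frame(sd_by_part)) {
    sds <- sd_by_part$sd[order(sd_by_part$part)]
  } else {
    sds <- as.numeric(sd_by_part)
  }
  k <- length(sds)
  containing <- pmin(k, pmax(1L, ceiling(cand * k)))
  tab <- tibble::tibble(candidate_frac = cand, part = containing,
                        part_sd = sds[containing],
                        dist_to_two_thirds = abs(cand - 2 / 3))
  ord <- order(tab$part_sd, tab$dist_to_two_thirds)
  best <- tab[ord[1], ]
  structure(list(position_frac = best$candidate_frac, part = best$part,
                 sd = best$part_sd, candidates = tab),
            class = "position_choice")
}

#' @export
print.position_choice <- function(x, ...) {
  cat(sprintf(
    "<position_choice> recommend %.3f of blade length (part %d, SD %.3f)\n",
    x$position_frac, x$part, x$sd))
  print(x$candidates)
  invisible(x)
}

#' Total chlorophyll a+b concentration from extract absorbances
#'
#' Concentration of chlorophyll a + b in an ethanol extract, from
#' spectrophotometer absorbances at 665 and 649 nm:
#' \deqn{Chl_{a+b} = (5.1 A_{665} + 20.04 A_{649}) \cdot V / m}
#' with `V` the extract volume in litres and `m` the fresh sample mass in
#' grams; result in mg chlorophyll per g fresh leaf. Vectorized; the
#' data-frame method appends a `chla_b_mg_g` column.
#'
#' @param a665,a649 absorbances (unitless, >= 0), or a data frame with
#'   columns `a665`, `a649`, `volume_l`, `mass_g` as the first argument.
#' @param volume_l extract volume in litres (> 0).
#' @param mass_g fresh sample mass in grams (> 0).
#' @return numeric vector (or the input tibble with `chla_b_mg_g` added).
#' @examples
#' chla_b(0.5, 0.25, volume_l = 0.01, mass_g = 0.02)
#' @export
chla_b <- function(a665, a649 = NULL, volume_l = NULL, mass_g = NULL) {
  if (is.data.frame(a665)) {
    df <- a665
    need <- c("a665", "a649", "volume_l", "mass_g")
    if (!all(need %in% names(df))) {
      stop_leafspad("data frame needs columns a665, a649, volume_l, mass_g.",
                    "leafspad_invalid_input")
    }
    df$chla_b_mg_g <- chla_b(df$a665, df$a649, df$volume_l, df$mass_g)
    return(tibble::as_tibble(df))
  }
  if (any(!is.finite(a665)) || any(!is.finite(a649)) ||
      any(a665 < 0) || any(a649 < 0)) {
    stop_leafspad("absorbances must be finite and >= 0.",
                  "leafspad_invalid_input")
  }
  if (any(volume_l <= 0) || any(mass_g <= 0)) {
    stop_leafspad("`volume_l` and `mass_g` must be > 0.",
                  "leafspad_invalid_input")
  }
  (5.1 * a665 + 20.04 * a649) * volume_l / mass_g
}

leaf_regression <- function(data, x, y, form) {
  if (!is.data.frame(data) || !all(c(x, y) %in% names(data))) {
    stop_leafspad("`data` must contain the x and y columns.",
                  "leafspad_invalid_parameter")
  }
  xs <- data[[x]]; ys <- data[[y]]
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  p <- if (form == "linear") 2L else 3L
  if (length(unique(xs)) < p) {
    stop_leafspad(sprintf("need at least %d distinct x values for a %s fit.",
                          p, form), "leafspad_singular_design")
  }
  fit <- if (form == "linear") lm(ys ~ xs) else lm(ys ~ xs + I(xs^2))
  sm <- summary(fit)
  fstat <- sm$fstatistic
  pval <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  cf <- coef(fit)
  names(cf) <- if (form == "linear") c("intercept", "x") else
    c("intercept", "x", "x2")
  structure(list(form = form, coefficients = cf, r2 = sm$r.squared,
                 n = length(ys), p_value = pval, conf_level = 0.95,
                 fit = fit, xname = x, yname = y),
            class = "leaf_regression")
}

#' Linear and quadratic regressions with confidence bands
#'
#' OLS machinery for relating SPAD indicators to nitrogen-status measures
#' (extracted chlorophyll, leaf N concentration): coefficients, r2, the
#' regression F-test p-value, and pointwise 95% confidence bands for the
#' mean response via [predict_band()]. The quadratic nests the linear fit:
#' perfectly linear data return a leading coefficient of 0.
#'
#' @param data data frame holding the variables.
#' @param x,y column names (strings); defaults `"x"` and `"y"`.
#' @return An object of class `leaf_regression`.
#' @export
regress_linear <- function(data, x = "x", y = "y") {
  leaf_regression(data, x, y, "linear")
}

#' @rdname regress_linear
#' @export
regress_quadratic <- function(data, x = "x", y = "y") {
  leaf_regression(data, x, y, "quadratic")
}

#' @rdname regress_linear
#' @param object a `leaf_regression`.
#' @param new_x numeric vector of x values at which to evaluate the fit.
#' @return `predict_band()`: tibble with `x`, `fit`, `lwr`, `upr` (pointwise
#'   confidence limits for the mean response at `conf_level`).
#' @export
predict_band <- function(object, new_x) {
  stopifnot(inherits(object, "leaf_regression"))
  pr <- predict(object$fit, newdata = data.frame(xs = new_x),
                interval = "confidence", level = object$conf_level)
  tibble::tibble(x = new_x, fit = unname(pr[, "fit"]),
                 lwr = unname(pr[, "lwr"]), upr = unname(pr[, "upr"]))
}

#' @export
print.leaf_regression <- function(x, ...) {
  cat(sprintf("<leaf_regression> %s fit of %s on %s\n", x$form, x$yname,
              x$xname))
  print(round(x$coefficients, 6))
  cat(sprintf("  r2 = %.4f, n = %d, p = %.3g\n", x$r2, x$n, x$p_value))
  invisible(x)
}

#' @rdname regress_linear
#' @param ... unused.
#' @export
tidy.leaf_regression <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname regress_linear
#' @export
glance.leaf_regression <- function(x, ...) {
  tibble::tibble(form = x$form, r.squared = x$r2, nobs = x$n,
                 p.value = x$p_value)
}

#' @rdname regress_linear
#' @export
autoplot.leaf_regression <- function(object, ...) {
  mf <- object$fit$model
  pts <- tibble::tibble(x = mf$xs, y = mf[[1]])
  grid <- seq(min(pts$x), max(pts$x), length.out = 200)
  band <- predict_band(object, grid)
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$x, ymin = .data$lwr,
                                      ymax = .data$upr),
                         inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(.data$x, .data$fit), colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$xname, y = object$yname,
                  title = sprintf("%s regression with 95%% confidence band",
                                  object$form)) +
    ggplot2::theme_minimal()
}
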