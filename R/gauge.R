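#' Maximum bark thickness from ridge readings
#'
#' Field protocol for fissured bark: bark thickness is measured at ridges
#' (wood surface to outer bark surface), typically at three points per stem
#' quadrant, and `BT_max` is the mean. When quadrant labels are supplied the
#' readings are averaged within each quadrant first and the quadrant means are
#' then averaged, so unbalanced quadrants do not bias the result.
#'
#' @param readings Numeric vector of ridge thickness readings, cm,
#'   non-negative.
#' @param quadrant Optional vector of quadrant labels (e.g. 1-4), same length
#'   as `readings`.
#' @return `BT_max`, cm (single value).
#' @seealso [bt_max_smooth()] for the smooth-bark protocol.
#' @export
bt_max_ridge <- function(readings, quadrant = NULL) {
  check_readings(readings)
  if (is.null(quadrant) || all(is.na(quadrant))) {
    return(mean(readings))
  }
  if (length(quadrant) != length(readings)) {
    rlang::abort("`quadrant` must have the same length as `readings`.")
  }
  mean(tapply(readings, quadrant, mean))
}

#' Maximum bark thickness for smooth bark
#'
#' Smooth bark has no ridges to measure on, so `BT_max` is taken as the mean of
#' the three largest of (at least three) gauge readings. Ties among maximal
#' values are immaterial: any three maximal readings give the same mean.
#'
#' @param readings Numeric vector of gauge readings, cm, at least 3 values.
#' @return `BT_max`, cm.
#' @export
bt_max_smooth <- function(readings) {
  check_readings(readings)
  if (length(readings) < 3) {
    rlang::abort(
      "At least 3 readings are needed for the top-3 rule; use `bt_max_ridge()` for ridge readings."
    )
  }
  mean(sort(readings, decreasing = TRUE)[1:3])
}

check_readings <- function(readings) {
  if (!is.numeric(readings) || length(readings) < 1) {
    rlang::abort("`readings` must be a non-empty numeric vector (cm).")
  }
  if (any(!is.finite(readings)) || any(readings < 0)) {
    rlang::abort("All readings must be finite and non-negative (cm).")
  }
  invisible(TRUE)
}

#' Fissure-corrected bark thickness summary
#'
#' The mean of gauge readings taken at random or systematic points around the
#' circumference -- including within fissures -- estimates the
#' fissure-corrected bark thickness `BT_f`. Readings taken solely at ridges
#' measure `BT_max` instead and would bias `BT_f` upwards, so ridge-only
#' reading sets are rejected.
#'
#' @param readings Numeric vector of gauge readings, cm.
#' @param scheme Sampling scheme of the readings; `"ridge_only"` is rejected.
#' @return One-row tibble with `n`, `bt_f_cm` (mean), `sd_cm` (sample standard
#'   deviation, `n - 1` denominator; `NA` for a single reading) and `cv_pct`
#'   (coefficient of variation, percent of the mean).
#' @examples
#' bt_f_summary(c(1, 3)) # mean 2, sd sqrt(2)
#' @export
bt_f_summary <- function(readings, scheme = c("random", "systematic")) {
  if (length(scheme) > 1) scheme <- scheme[1]
  scheme <- match.arg(scheme, c("random", "systematic", "ridge_only"))
  if (scheme == "ridge_only") {
    rlang::abort(
      "Ridge-only readings measure BT_max, not BT_f; sample within fissures too."
    )
  }
  check_readings(readings)
  n <- length(readings)
  m <- mean(readings)
  s <- if (n > 1) stats::sd(readings) else NA_real_
  tibble::tibble(
    n = n,
    bt_f_cm = m,
    sd_cm = s,
    cv_pct = if (!is.na(s) && m > 0) 100 * s / m else if (identical(s, 0)) 0 else NA_real_
  )
}

#' Bark fissure index from gauge measurements (BGM)
#'
#' The bark fissure index is the ratio of fissure-corrected to maximum bark
#' thickness, `BFI = BT_f / BT_max`: 1 for smooth bark, lower values as a
#' larger share of the nominal bark annulus is air-filled fissure space.
#' Because noisy readings can push `BT_f` slightly above `BT_max`, values
#' above 1 are clamped to 1 with a warning by default (physically `BFI <= 1`).
#'
#' @param bt_f Fissure-corrected bark thickness, cm (mean of gauge readings).
#' @param bt_max Maximum bark thickness, cm, positive.
#' @param clamp Clamp values above 1 to 1 (with a warning)? Default `TRUE`.
#' @return BFI as a fraction. Vectorised.
#' @examples
#' bfi_bgm(bt_f = 2.1, bt_max = 3.1) # ~0.68: a third of the annulus is air
#' @export
bfi_bgm <- function(bt_f, bt_max, clamp = TRUE) {
  if (any(!is.finite(bt_max)) || any(bt_max <= 0)) {
    rlang::abort("`bt_max` must be positive (cm).")
  }
  if (any(!is.finite(bt_f)) || any(bt_f < 0)) {
    rlang::abort("`bt_f` must be non-negative (cm).")
  }
  value <- bt_f / bt_max
  over <- value > 1
  if (clamp && any(over)) {
    rlang::warn(sprintf(
      "%d BFI value(s) exceeded 1 (bt_f > bt_max) and were clamped to 1.",
      sum(over)
    ))
    value[over] <- 1
  }
  value
}

#' Sampling error of mean bark thickness for n gauge readings
#'
#' Relative half-width of the two-sided confidence interval of the mean of `n`
#' gauge readings, `CV * t / sqrt(n)`, where `t` is the upper
#' `(1 + confidence) / 2` quantile of the t distribution with `n - 1` degrees
#' of freedom. Strictly decreasing in `n` (both the quantile and `1/sqrt(n)`
#' shrink) and linear in `CV`.
#'
#' @param cv Coefficient of variation of single readings, percent.
#' @param n Number of readings per tree, integer `>= 2` (the t quantile is
#'   undefined for 0 degrees of freedom).
#' @param confidence Confidence level, fraction in `(0, 1)`; default 0.95.
#' @return Expected relative error, percent. Vectorised over `cv` and `n`.
#' @examples
#' error_for_n(cv = 35.75, n = 5) # ~44%
#' @export
error_for_n <- function(cv, n, confidence = 0.95) {
  if (any(!is.finite(cv)) || any(cv < 0)) {
    rlang::abort("`cv` must be non-negative (percent).")
  }
  if (any(!is.finite(n)) || any(n < 2) || any(n != round(n))) {
    rlang::abort("`n` must be an integer >= 2.")
  }
  if (length(confidence) != 1 || !is.finite(confidence) ||
    confidence <= 0 || confidence >= 1) {
    rlang::abort("`confidence` must be a single value in (0, 1).")
  }
  cv * stats::qt(1 - (1 - confidence) / 2, df = n - 1) / sqrt(n)
}

#' Smallest number of readings achieving a target error
#'
#' Inverse of [error_for_n()]: the smallest `n` in `[2, n_max]` whose predicted
#' relative error does not exceed `target_error`.
#'
#' @inheritParams error_for_n
#' @param target_error Acceptable relative error, percent, positive.
#' @param n_max Search ceiling; `NA` (with a warning) if the target is not
#'   achievable within it.
#' @return Integer sample size, or `NA` if unachievable within `n_max`.
#' @examples
#' required_n(cv = 35.75, target_error = 20) # 15 readings
#' required_n(cv = 15.77, target_error = 20) # 5 readings
#' @export
required_n <- function(cv, target_error, confidence = 0.95, n_max = 1000) {
  if (length(target_error) != 1 || !is.finite(target_error) || target_error <= 0) {
    rlang::abort("`target_error` must be a single positive percent value.")
  }
  if (length(cv) != 1 || !is.finite(cv) || cv < 0) {
    rlang::abort("`cv` must be a single non-negative percent value.")
  }
  if (cv == 0) {
    return(2L)
  }
  n <- 2:n_max
  ok <- error_for_n(cv, n, confidence) <= target_error
  if (!any(ok)) {
    rlang::warn(sprintf(
      "Target error %.3g%% not achievable with n <= %d for CV = %.3g%%.",
      target_error, n_max, cv
    ))
    return(NA_integer_)
  }
  n[which(ok)[1]]
}

#' Sampling-error table for increasing numbers of readings
#'
#' Tabulates the predicted relative and absolute error of the mean bark
#' thickness for a set of candidate sample sizes. The absolute column is
#' defined self-consistently as `error_pct * mean_bt / 100`.
#'
#' @inheritParams error_for_n
#' @param mean_bt Mean (fissure-corrected) bark thickness, cm, used to convert
#'   percent error into cm.
#' @param n_values Sample sizes to tabulate; default `c(5, 10, 15, 20, 30)`.
#' @return A tibble of class `bark_error_table` with columns `n`, `error_pct`,
#'   `error_cm`; `cv`, `mean_bt` and `confidence` are carried as attributes and
#'   used by [autoplot.bark_error_table()].
#' @examples
#' error_table(cv = 35.75, mean_bt = 2.08)
#' @export
error_table <- function(cv, mean_bt, n_values = c(5, 10, 15, 20, 30),
                        confidence = 0.95) {
  if (length(mean_bt) != 1 || !is.finite(mean_bt) || mean_bt < 0) {
    rlang::abort("`mean_bt` must be a single non-negative value (cm).")
  }
  out <- tibble::tibble(
    n = as.integer(n_values),
    error_pct = error_for_n(cv, n_values, confidence),
    error_cm = error_for_n(cv, n_values, confidence) * mean_bt / 100
  )
  attr(out, "cv") <- cv
  attr(out, "mean_bt") <- mean_bt
  attr(out, "confidence") <- confidence
  class(out) <- c("bark_error_table", class(out))
  out
}

#' Compare two paired BFI estimators
#'
#' Paired two-tailed t-test on per-section differences between two BFI methods
#' (e.g. bark-gauge vs contour estimates on the same quadrants). Degenerate
#' inputs are handled explicitly: identical pairs give a mean difference of 0
#' and p = 1; a constant non-zero offset has zero variance, so the t statistic
#' is undefined and `p_value` is `NA`.
#'
#' @param data A data frame holding paired estimates, or a numeric vector of
#'   the first method's values (then `a` must be the second method's vector).
#' @param a,b Unquoted column names of the two paired estimate columns when
#'   `data` is a data frame; ignored extras otherwise.
#' @param methods Length-2 character labels for the two methods.
#' @return An object of class `bfi_method_comparison`; see
#'   [tidy.bfi_method_comparison()].
#' @examples
#' d <- tibble::tibble(bgm = c(.66, .91, .88, .71), cm = c(.68, .90, .90, .70))
#' compare_bfi_methods(d, bgm, cm, methods = c("BGM", "CM"))
#' @export
compare_bfi_methods <- function(data, a, b, methods = c("A", "B")) {
  if (is.data.frame(data)) {
    va <- rlang::eval_tidy(rlang::enquo(a), data)
    vb <- rlang::eval_tidy(rlang::enquo(b), data)
  } else {
    va <- data
    vb <- a
  }
  if (!is.numeric(va) || !is.numeric(vb) || length(va) != length(vb)) {
    rlang::abort("Paired estimates must be numeric vectors of equal length.")
  }
  if (length(va) < 2) {
    rlang::abort("At least 2 matched pairs are required.")
  }
  d <- va - vb
  # same degeneracy guard as t.test: spread indistinguishable from rounding noise
  if (stats::sd(d) <= 10 * .Machine$double.eps * max(abs(mean(d)), abs(d))) {
    res <- list(
      mean_difference = mean(d),
      statistic = NA_real_,
      df = length(d) - 1L,
      p_value = if (all(d == 0)) 1 else NA_real_,
      conf_low = NA_real_, conf_high = NA_real_,
      n_pairs = length(d), methods = methods,
      note = "zero variance of paired differences"
    )
  } else {
    tt <- stats::t.test(va, vb, paired = TRUE)
    res <- list(
      mean_difference = unname(tt$estimate),
      statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value,
      conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
      n_pairs = length(d), methods = methods,
      note = NULL
    )
  }
  structure(res, class = "bfi_method_comparison")
}

#' @export
print.bfi_method_comparison <- function(x, ...) {
  cat(sprintf(
    "Paired comparison of BFI methods %s - %s (n = %d pairs)\n",
    x$methods[1], x$methods[2], x$n_pairs
  ))
  cat(sprintf("  mean difference: %.4f\n", x$mean_difference))
  if (is.na(x$p_value)) {
    cat(sprintf("  p-value: NA (%s)\n", x$note))
  } else {
    cat(sprintf("  two-tailed paired t: p = %.3g (df = %d)\n", x$p_value, x$df))
  }
  invisible(x)
}

#' Per-tree bark summary from raw gauge readings
#'
#' The main field workflow: turns a long table of gauge readings (one row per
#' reading) into one row per tree with `BT_max`, `BT_f`, the reading CV, the
#' bark fissure index, and -- when a diameter column is present -- relative
#' bark thickness and area.
#'
#' `BT_max` is taken from rows with `reading_kind == "ridge"` via
#' [bt_max_ridge()] when any are present, otherwise from the gauge readings via
#' the top-3 rule ([bt_max_smooth()]). An optional constant gauge bias (gauges
#' tend to overestimate thickness by roughly 0.05 cm) is subtracted from every
#' reading before summarising.
#'
#' @param data Data frame with columns `tree_id`, `reading_cm` and optionally
#'   `species`, `dob_cm` (constant within tree), `quadrant`, `reading_kind`
#'   (`"gauge"` or `"ridge"`; missing column means all gauge).
#' @param bt_max_rule Rule used when no ridge readings exist:
#'   `"smooth_top3"` (default) or `"ridge"` (then ridge rows are required).
#' @param bias_cm Constant gauge bias to subtract from all readings, cm.
#' @param clamp Passed to [bfi_bgm()].
#' @return Tibble with one row per tree: `tree_id`, `species`, `n`,
#'   `bt_max_cm`, `bt_f_cm`, `sd_cm`, `cv_pct`, `bfi` and, if `dob_cm` was
#'   present, `dob_cm`, `rbt`, `rba`.
#' @export
bark_gauge_summary <- function(data, bt_max_rule = c("smooth_top3", "ridge"),
                               bias_cm = 0, clamp = TRUE) {
  bt_max_rule <- match.arg(bt_max_rule)
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c("tree_id", "reading_cm"), names(data))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "Missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  data <- dplyr::as_tibble(data)
  if (!"reading_kind" %in% names(data)) data$reading_kind <- "gauge"
  if (!"species" %in% names(data)) data$species <- NA_character_
  if (!"quadrant" %in% names(data)) data$quadrant <- NA
  has_dob <- "dob_cm" %in% names(data)
  data$reading_cm <- pmax(data$reading_cm - bias_cm, 0)

  data |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::group_modify(function(d, key) {
      gauge <- d$reading_cm[d$reading_kind == "gauge"]
      ridge <- d[d$reading_kind == "ridge", , drop = FALSE]
      if (!length(gauge)) {
        rlang::abort(sprintf("Tree '%s' has no gauge readings.", key$tree_id))
      }
      bt_max <- if (nrow(ridge) > 0) {
        bt_max_ridge(ridge$reading_cm, ridge$quadrant)
      } else if (bt_max_rule == "smooth_top3") {
        bt_max_smooth(gauge)
      } else {
        rlang::abort(sprintf(
          "Tree '%s': bt_max_rule = \"ridge\" but no ridge readings present.",
          key$tree_id
        ))
      }
      s <- bt_f_summary(gauge)
      out <- tibble::tibble(
        species = d$species[1],
        n = s$n,
        bt_max_cm = bt_max,
        bt_f_cm = s$bt_f_cm,
        sd_cm = s$sd_cm,
        cv_pct = s$cv_pct,
        bfi = bfi_bgm(s$bt_f_cm, bt_max, clamp = clamp)
      )
      if (has_dob) {
        dob <- d$dob_cm[1]
        out$dob_cm <- dob
        out$rbt <- relative_bark_thickness(dob, bt_max)
        out$rba <- relative_bark_area(dob, bt_max)
      }
      out
    }) |>
    dplyr::ungroup()
}

#' Per-quadrant BFI estimates
#'
#' Computes the bark fissure index separately for each quadrant of a section
#' (the protocol used when comparing against contour-method quadrants) as well
#' as the pooled estimate over all readings.
#'
#' @param data Data frame with columns `reading_cm` and `quadrant` for one
#'   section; optional `reading_kind` as in [bark_gauge_summary()].
#' @param bt_max Maximum bark thickness, cm (e.g. from ridge readings).
#' @param clamp Passed to [bfi_bgm()].
#' @return Tibble with one row per quadrant plus a pooled row
#'   (`quadrant = NA`): columns `quadrant`, `n`, `bt_f_cm`, `bfi`.
#' @export
bfi_by_quadrant <- function(data, bt_max, clamp = TRUE) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c("reading_cm", "quadrant"), names(data))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "Missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  data <- dplyr::as_tibble(data)
  if ("reading_kind" %in% names(data)) {
    data <- dplyr::filter(data, .data$reading_kind == "gauge")
  }
  per_q <- data |>
    dplyr::group_by(.data$quadrant) |>
    dplyr::summarise(
      n = dplyr::n(),
      bt_f_cm = mean(.data$reading_cm),
      .groups = "drop"
    ) |>
    dplyr::mutate(bfi = bfi_bgm(.data$bt_f_cm, bt_max, clamp = clamp))
  pooled <- tibble::tibble(
    quadrant = NA,
    n = nrow(data),
    bt_f_cm = mean(data$reading_cm),
    bfi = bfi_bgm(mean(data$reading_cm), bt_max, clamp = clamp)
  )
  dplyr::bind_rows(per_q, pooled)
}
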