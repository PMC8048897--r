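#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a BFI estimate
#'
#' @param x A `bfi_estimate` (from [bfi_dm()] or [bfi_cm()]).
#' @param ... Unused.
#' @return One-row tibble with `value`, `method`, `n`, `section_id` and the
#'   method's area components where available.
#' @export
tidy.bfi_estimate <- function(x, ...) {
  out <- tibble::tibble(
    value = x$value, method = x$method, n = x$n, section_id = x$section_id
  )
  for (field in c(
    "solid_area_cm2", "annulus_area_cm2", "envelope_area_cm2",
    "outer_area_cm2", "wood_area_cm2"
  )) {
    if (!is.null(x[[field]])) out[[field]] <- x[[field]]
  }
  out
}

#' Tidy a paired BFI method comparison
#'
#' @param x A `bfi_method_comparison` (from [compare_bfi_methods()]).
#' @param ... Unused.
#' @return One-row tibble in the usual test-tidier layout: `estimate` (mean
#'   paired difference), `statistic`, `p.value`, `parameter` (df), `conf.low`,
#'   `conf.high`, `n_pairs`, `method`.
#' @export
tidy.bfi_method_comparison <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_difference,
    statistic = x$statistic,
    p.value = x$p_value,
    parameter = x$df,
    conf.low = x$conf_low,
    conf.high = x$conf_high,
    n_pairs = x$n_pairs,
    method = paste(x$methods, collapse = " - ")
  )
}

#' @rdname tidy.bfi_method_comparison
#' @export
glance.bfi_method_comparison <- function(x, ...) tidy(x, ...)

#' Tidy / summarise a Monte Carlo validation table
#'
#' `tidy()` returns the per-sample-size table as a plain tibble; `glance()`
#' returns the one-row section summary (the ground truths and settings the
#' replicates were run against).
#'
#' @param x A `bgm_validation` (from [validate_bgm()]).
#' @param ... Unused.
#' @export
tidy.bgm_validation <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "bgm_validation")
  for (a in c(
    "true_bfi_thickness", "true_bfi_area", "thickness_cv", "replicates", "scheme"
  )) {
    attr(out, a) <- NULL
  }
  tibble::as_tibble(out)
}

#' @rdname tidy.bgm_validation
#' @export
glance.bgm_validation <- function(x, ...) {
  tibble::tibble(
    true_bfi_thickness = attr(x, "true_bfi_thickness"),
    true_bfi_area = attr(x, "true_bfi_area"),
    thickness_cv = attr(x, "thickness_cv"),
    replicates = attr(x, "replicates"),
    scheme = attr(x, "scheme")
  )
}
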