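#' Relative bark thickness (RBT)
#'
#' Maximum bark thickness expressed relative to the under-bark (wood) diameter,
#' `2 * bt_max / (dob - 2 * bt_max)`. Scaling bark thickness by the wood
#' diameter rather than the over-bark diameter avoids the autocorrelation that
#' arises because bark thickness is itself part of the over-bark diameter.
#'
#' @param dob Diameter over bark, cm. Positive.
#' @param bt_max Maximum bark thickness, cm (ridge-to-wood distance; the
#'   thickness a diameter tape implicitly assumes everywhere). Must satisfy
#'   `0 <= bt_max < dob / 2`, otherwise the under-bark diameter would be
#'   non-positive.
#' @return Dimensionless fraction (multiply by 100 for percent). Vectorised
#'   over `dob` and `bt_max`.
#' @seealso [relative_bark_area()], [bark_allometry()]
#' @examples
#' relative_bark_thickness(dob = 28.3, bt_max = 3.1) # 0.281
#' @export
relative_bark_thickness <- function(dob, bt_max) {
  check_stem_geometry(dob, bt_max)
  2 * bt_max / (dob - 2 * bt_max)
}

#' Relative bark area (RBA)
#'
#' Cross-sectional bark annulus area as a fraction of the over-bark stem
#' cross-section, assuming circular sections:
#' `(4 * bt_max * dob - 4 * bt_max^2) / dob^2`, algebraically identical to
#' `1 - (dub / dob)^2` with `dub = dob - 2 * bt_max`. Under the assumption
#' that bark thickness and texture are proportional along the stem, RBA applied
#' to stem volume gives the bark volume fraction (before any fissure
#' correction; see [bfi_bgm()]).
#'
#' @inheritParams relative_bark_thickness
#' @return Dimensionless fraction in `[0, 1)`. Vectorised.
#' @examples
#' relative_bark_area(dob = 28.3, bt_max = 3.1) # 0.390
#' @export
relative_bark_area <- function(dob, bt_max) {
  check_stem_geometry(dob, bt_max)
  (4 * bt_max * dob - 4 * bt_max^2) / dob^2
}

# Shared invariant checks for stem geometry; names the offending field.
check_stem_geometry <- function(dob, bt_max) {
  if (!is.numeric(dob) || !is.numeric(bt_max)) {
    rlang::abort("`dob` and `bt_max` must be numeric (cm).")
  }
  if (any(!is.finite(dob)) || any(!is.finite(bt_max))) {
    rlang::abort("`dob` and `bt_max` must be finite.")
  }
  if (any(dob <= 0)) {
    rlang::abort("`dob` must be positive (diameter over bark, cm).")
  }
  if (any(bt_max < 0)) {
    rlang::abort("`bt_max` must be non-negative (bark thickness, cm).")
  }
  if (any(bt_max >= dob / 2)) {
    rlang::abort(
      "`bt_max` must be smaller than `dob / 2`: the under-bark diameter would be non-positive."
    )
  }
  invisible(TRUE)
}

#' Add bark allometry columns to a per-tree table
#'
#' Data-frame-first wrapper around [relative_bark_thickness()] and
#' [relative_bark_area()]: adds `rbt` and `rba` columns (fractions) computed
#' row-wise from diameter over bark and maximum bark thickness.
#'
#' @param data A data frame with one row per tree/section.
#' @param dob,bt_max Unquoted column names holding diameter over bark (cm) and
#'   maximum bark thickness (cm). Default `dob_cm`, `bt_max_cm`.
#' @return `data` as a tibble with `rbt` and `rba` columns appended.
#' @examples
#' tibble::tibble(dob_cm = c(28.3, 25.4), bt_max_cm = c(3.1, 1.1)) |>
#'   bark_allometry()
#' @export
bark_allometry <- function(data, dob = dob_cm, bt_max = bt_max_cm) {
  stopifnot(is.data.frame(data))
  dplyr::as_tibble(data) |>
    dplyr::mutate(
      rbt = relative_bark_thickness({{ dob }}, {{ bt_max }}),
      rba = relative_bark_area({{ dob }}, {{ bt_max }})
    )
}

#' Bark carbon from over-bark inventory measurements
#'
#' Converts routine over-bark inventory quantities into bark carbon (kgC) by
#' scaling with the relative bark area (RBA), the bark fissure index (BFI) and,
#' depending on the chosen `mode`, bark density and carbon fraction:
#'
#' * `mode = "basal_area"`: `BA * H * FF * RBA * bark_density * carbon_fraction * BFI`
#' * `mode = "volume"`: `V * RBA * bark_density * carbon_fraction * BFI`
#' * `mode = "biomass"`: `BM * RBA * carbon_fraction * BFI`
#' * `mode = "tree_carbon"`: `TreeC * RBA * BFI`
#'
#' The biomass and tree-carbon modes assume the input already carries a density
#' (and, for tree carbon, a carbon fraction); because those are normally wood
#' values and bark density is usually lower than wood density, they tend to
#' overestimate bark carbon unless the inputs were derived with bark-specific
#' values (see [density_deficit()]).
#'
#' @param rba Relative bark area, fraction in `[0, 1)` (see
#'   [relative_bark_area()]).
#' @param bfi Bark fissure index, fraction in `(0, 1]`; 1 means smooth,
#'   unfissured bark.
#' @param mode Which conversion to apply; determines the required inputs.
#' @param volume Stem volume over bark, m^3 (`mode = "volume"`).
#' @param basal_area Basal area, m^2; `height` tree height, m; `form_factor`
#'   dimensionless taper ratio converting `basal_area * height` to stem volume
#'   (`mode = "basal_area"`).
#' @param height,form_factor See `basal_area`.
#' @param biomass Stem biomass, kg (`mode = "biomass"`).
#' @param tree_carbon Tree carbon, kgC (`mode = "tree_carbon"`).
#' @param bark_density Bark basic density, kg/m^3 (volume and basal-area
#'   modes).
#' @param carbon_fraction Carbon fraction of bark, kgC/kg in `(0, 1)` (all
#'   modes except `tree_carbon`).
#' @return Bark carbon, kgC. Vectorised over all numeric inputs.
#' @examples
#' bark_carbon(
#'   rba = 0.39, bfi = 0.677, mode = "volume",
#'   volume = 1, bark_density = 439, carbon_fraction = 0.5
#' ) # ~58 kgC in the bark of 1 m^3 of over-bark stem volume
#' @export
bark_carbon <- function(rba, bfi,
                        mode = c("volume", "basal_area", "biomass", "tree_carbon"),
                        volume = NULL, basal_area = NULL, height = NULL,
                        form_factor = NULL, biomass = NULL, tree_carbon = NULL,
                        bark_density = NULL, carbon_fraction = NULL) {
  mode <- match.arg(mode)
  if (any(!is.finite(rba)) || any(rba < 0) || any(rba >= 1)) {
    rlang::abort("`rba` must be a fraction in [0, 1).")
  }
  if (any(!is.finite(bfi)) || any(bfi <= 0) || any(bfi > 1)) {
    rlang::abort("`bfi` must be a fraction in (0, 1].")
  }
  need <- function(value, name) {
    if (is.null(value)) {
      rlang::abort(sprintf("`%s` is required for mode = \"%s\".", name, mode))
    }
    if (any(!is.finite(value)) || any(value <= 0)) {
      rlang::abort(sprintf("`%s` must be positive and finite.", name))
    }
    value
  }
  check_cf <- function(cf) {
    if (any(cf <= 0) || any(cf >= 1)) {
      rlang::abort("`carbon_fraction` must lie in (0, 1).")
    }
    cf
  }
  switch(mode,
    basal_area = need(basal_area, "basal_area") * need(height, "height") *
      need(form_factor, "form_factor") * rba *
      need(bark_density, "bark_density") *
      check_cf(need(carbon_fraction, "carbon_fraction")) * bfi,
    volume = need(volume, "volume") * rba * need(bark_density, "bark_density") *
      check_cf(need(carbon_fraction, "carbon_fraction")) * bfi,
    biomass = need(biomass, "biomass") * rba *
      check_cf(need(carbon_fraction, "carbon_fraction")) * bfi,
    tree_carbon = need(tree_carbon, "tree_carbon") * rba * bfi
  )
}

#' Relative density deficit of bark versus wood
#'
#' How much less dense bark is than wood, in percent of the wood density:
#' `100 * (wood_density - bark_density) / wood_density`. Negative values mean
#' the bark is denser than the wood. Large deficits (40-50% in many hardwoods)
#' are the reason substituting wood density for bark density overestimates bark
#' carbon.
#'
#' @param bark_density,wood_density Basic densities, kg/m^3, positive.
#' @return Percent deficit. Vectorised.
#' @examples
#' density_deficit(bark_density = 439, wood_density = 870) # ~50%
#' @export
density_deficit <- function(bark_density, wood_density) {
  if (any(!is.finite(bark_density)) || any(!is.finite(wood_density)) ||
    any(bark_density <= 0) || any(wood_density <= 0)) {
    rlang::abort("Densities must be positive and finite (kg/m^3).")
  }
  100 * (wood_density - bark_density) / wood_density
}

#' Round half away from zero
#'
#' Presentation-layer rounding used for percent columns in reports: halves are
#' rounded away from zero (2.5 -> 3, -2.5 -> -3), unlike [base::round()]'s
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
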