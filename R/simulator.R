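#' Specify a synthetic fissured cross-section
#'
#' Parameterises a circular stem cross-section of wood radius `wood_radius`
#' carrying a bark layer of uniform maximum thickness `bt_max` into which
#' `n_fissures` non-overlapping notches are cut at seeded random angles.
#' Notches are `"rectangular"` (constant depth across their angular width) or
#' `"triangular"` (depth ramping linearly from zero at the edges to the full
#' depth at the centre). Depths and half-widths are drawn uniformly from the
#' given ranges.
#'
#' @param wood_radius Wood (under-bark) radius, cm, positive.
#' @param bt_max Maximum bark thickness, cm, positive.
#' @param n_fissures Number of fissures, integer `>= 0`.
#' @param depth_range Length-2 `(min, max)` fissure depth, cm, with
#'   `max <= bt_max`.
#' @param halfwidth_range Length-2 `(min, max)` angular half-width, degrees.
#' @param shape Notch profile, `"rectangular"` or `"triangular"`.
#' @param seed Integer seed making the section reproducible.
#' @param name Optional label used as section id.
#' @return An object of class `section_spec`.
#' @seealso [make_section()], [default_morphologies()]
#' @export
section_spec <- function(wood_radius, bt_max, n_fissures = 0,
                         depth_range = c(0, 0), halfwidth_range = c(0, 0),
                         shape = c("triangular", "rectangular"),
                         seed = 20210114, name = NULL) {
  shape <- match.arg(shape)
  stopifnot(
    is.numeric(wood_radius), length(wood_radius) == 1, wood_radius > 0,
    is.numeric(bt_max), length(bt_max) == 1, bt_max > 0,
    length(n_fissures) == 1, n_fissures >= 0, n_fissures == round(n_fissures),
    length(depth_range) == 2, length(halfwidth_range) == 2,
    length(seed) == 1, is.finite(seed)
  )
  if (n_fissures > 0) {
    if (any(depth_range < 0) || depth_range[2] > bt_max || diff(depth_range) < 0) {
      rlang::abort("`depth_range` must be increasing, non-negative, with max <= bt_max.")
    }
    if (any(halfwidth_range <= 0) || diff(halfwidth_range) < 0) {
      rlang::abort("`halfwidth_range` must be increasing and positive (degrees).")
    }
    if (2 * n_fissures * halfwidth_range[2] >= 360) {
      rlang::abort("Fissures' total angular width must stay below 360 degrees.")
    }
  }
  structure(
    list(
      wood_radius = wood_radius, bt_max = bt_max,
      n_fissures = as.integer(n_fissures),
      depth_range = as.numeric(depth_range),
      halfwidth_range = as.numeric(halfwidth_range),
      shape = shape, seed = as.integer(seed), name = name
    ),
    class = "section_spec"
  )
}

# Uniform placement of non-overlapping arcs on the circle: fissure widths are
# drawn first, then the free arc is split into gaps with exponential spacings
# (uniform over the simplex) and the whole configuration gets a random
# rotation. Exact for any total width < 360 degrees.
place_fissures <- function(n, halfwidths) {
  widths <- 2 * halfwidths
  free <- 360 - sum(widths)
  if (free <= 0) {
    rlang::abort("Fissures' total angular width must stay below 360 degrees.")
  }
  gaps <- stats::rexp(n)
  gaps <- gaps / sum(gaps) * free
  start <- stats::runif(1, 0, 360)
  centers <- numeric(n)
  pos <- start
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    centers[i] <- pos + halfwidths[i]
    pos <- pos + widths[i]
  }
  centers %% 360
}

#' Realise a synthetic bark cross-section with known truth
#'
#' Draws fissure depths, half-widths and positions from a [section_spec()]
#' (deterministically, given its seed) and computes ground-truth summaries by
#' numerical integration of the bark thickness function `BT(theta)` on a fixed
#' midpoint grid of 108,000 panels:
#'
#' * `true_solid_area`: integral of `((wood_radius + BT)^2 - wood_radius^2) / 2`
#'   over the full circle, cm^2 -- the solid bark area;
#' * `true_bfi_area`: `true_solid_area` divided by the idealized annulus with
#'   `DoB = 2 * (wood_radius + bt_max)` -- what the digitized method measures;
#' * `true_bfi_thickness`: `mean(BT) / bt_max` -- what the thickness-ratio
#'   estimator `BT_f / BT_max` converges to;
#' * `thickness_cv`: population coefficient of variation of `BT(theta)`,
#'   percent, driving the sampling-error predictions of [error_for_n()].
#'
#' The two truths differ because solid area weights the outer (thicker) part
#' of the annulus; the gap closes in the thin-bark limit.
#'
#' @param spec A [section_spec()].
#' @return An object of class `bark_section`: the spec, the realised fissure
#'   table, `tape_dob = 2 * (wood_radius + bt_max)`, and the truth fields
#'   above.
#' @export
make_section <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  n <- spec$n_fissures
  fissures <- withr::with_seed(spec$seed, {
    if (n == 0) {
      tibble::tibble(
        center_deg = numeric(), halfwidth_deg = numeric(), depth_cm = numeric()
      )
    } else {
      depths <- stats::runif(n, spec$depth_range[1], spec$depth_range[2])
      halfwidths <- stats::runif(n, spec$halfwidth_range[1], spec$halfwidth_range[2])
      if (2 * sum(halfwidths) >= 360) {
        rlang::abort(sprintf(
          "Fissures drawn for seed %d exceed the circle; reduce widths or count.",
          spec$seed
        ))
      }
      tibble::tibble(
        center_deg = place_fissures(n, halfwidths),
        halfwidth_deg = halfwidths,
        depth_cm = depths
      )
    }
  })
  section <- structure(
    list(
      spec = spec, fissures = fissures,
      wood_radius = spec$wood_radius, bt_max = spec$bt_max, shape = spec$shape,
      tape_dob = 2 * (spec$wood_radius + spec$bt_max)
    ),
    class = "bark_section"
  )
  m <- 108000L
  theta <- (seq_len(m) - 0.5) * 360 / m
  bt <- bark_thickness_at(section, theta)
  r_w <- spec$wood_radius
  solid <- mean(((r_w + bt)^2 - r_w^2) / 2) * 2 * pi
  annulus <- pi * ((r_w + spec$bt_max)^2 - r_w^2)
  mean_bt <- mean(bt)
  section$true_solid_area <- solid
  section$true_bfi_area <- solid / annulus
  section$true_bfi_thickness <- mean_bt / spec$bt_max
  section$thickness_cv <- 100 * sqrt(mean((bt - mean_bt)^2)) / mean_bt
  section
}

#' @export
print.bark_section <- function(x, ...) {
  cat(sprintf(
    "Synthetic bark section%s: wood radius %.2f cm, bt_max %.2f cm, %d %s fissure(s)\n",
    if (is.null(x$spec$name)) "" else paste0(" '", x$spec$name, "'"),
    x$wood_radius, x$bt_max, nrow(x$fissures), x$shape
  ))
  cat(sprintf(
    "  true BFI (area) %.4f | true BFI (thickness) %.4f | thickness CV %.1f%%\n",
    x$true_bfi_area, x$true_bfi_thickness, x$thickness_cv
  ))
  invisible(x)
}

#' Bark thickness of a synthetic section at given angles
#'
#' Evaluates the section's thickness function `BT(theta)`: `bt_max` minus the
#' notch depth profile wherever `theta` falls inside a fissure. Angles are in
#' degrees and wrap around the circle.
#'
#' @param section A `bark_section` from [make_section()].
#' @param theta_deg Numeric vector of angles, degrees.
#' @return Bark thickness, cm, same length as `theta_deg`.
#' @export
bark_thickness_at <- function(section, theta_deg) {
  stopifnot(inherits(section, "bark_section"))
  th <- theta_deg %% 360
  deficit <- numeric(length(th))
  f <- section$fissures
  for (i in seq_len(nrow(f))) {
    delta <- abs(((th - f$center_deg[i] + 180) %% 360) - 180)
    inside <- delta < f$halfwidth_deg[i]
    if (!any(inside)) next
    dep <- if (section$shape == "rectangular") {
      f$depth_cm[i]
    } else {
      f$depth_cm[i] * (1 - delta[inside] / f$halfwidth_deg[i])
    }
    deficit[inside] <- deficit[inside] + dep
  }
  pmax(section$bt_max - deficit, 0)
}

#' Polygonize a synthetic section into digitizable contours
#'
#' Converts the analytic section into the polygon representation consumed by
#' [bfi_dm()]: the outer bark surface `r(theta) = wood_radius + BT(theta)` and
#' the wood circle, each sampled at `vertices_per_degree`. Vertices are
#' additionally inserted a hair's breadth either side of fissure edges (and at
#' triangular notch apexes) so that vertical notch walls are represented
#' exactly and `bfi_dm()` converges to `true_bfi_area` as density grows.
#'
#' @param section A `bark_section`.
#' @param vertices_per_degree Sampling density, `>= 1` (default 10).
#' @return Tibble with columns `contour` (`"outer"`/`"wood"`), `x`, `y` (cm)
#'   and a `tape_dob` attribute, ready for [bfi_dm()].
#' @export
to_profile <- function(section, vertices_per_degree = 10) {
  stopifnot(inherits(section, "bark_section"), vertices_per_degree >= 1)
  ang <- seq(0, 360, by = 1 / vertices_per_degree)
  ang <- ang[-length(ang)]
  f <- section$fissures
  if (nrow(f)) {
    edges <- c(f$center_deg - f$halfwidth_deg, f$center_deg + f$halfwidth_deg)
    eps <- 1e-7
    extra <- c((edges - eps) %% 360, (edges + eps) %% 360)
    if (section$shape == "triangular") extra <- c(extra, f$center_deg %% 360)
    ang <- sort(unique(c(ang, extra)))
  }
  r <- section$wood_radius + bark_thickness_at(section, ang)
  wang <- seq(0, 360, by = 1 / vertices_per_degree)
  wang <- wang[-length(wang)]
  profile <- dplyr::bind_rows(
    tibble::tibble(
      contour = "outer",
      x = r * cospi(ang / 180), y = r * sinpi(ang / 180)
    ),
    tibble::tibble(
      contour = "wood",
      x = section$wood_radius * cospi(wang / 180),
      y = section$wood_radius * sinpi(wang / 180)
    )
  )
  attr(profile, "tape_dob") <- section$tape_dob
  profile
}

#' Simulate bark-gauge readings on a synthetic section
#'
#' Draws `n` measurement angles -- uniformly at random, or systematically at
#' equal spacing with a random start -- and returns the section's bark
#' thickness at those angles plus an optional constant instrument bias,
#' floored at zero. Deterministic given `seed`.
#'
#' @param section A `bark_section`.
#' @param n Number of readings, `>= 1`.
#' @param seed Integer seed.
#' @param scheme `"random"` or `"systematic"`.
#' @param bias_cm Constant gauge bias added to every reading, cm (gauges tend
#'   to overestimate by about 0.05 cm).
#' @return Tibble with columns `section_id`, `angle_deg`, `reading_cm`,
#'   `scheme`.
#' @export
simulate_gauge <- function(section, n, seed = 20210114,
                           scheme = c("random", "systematic"), bias_cm = 0) {
  stopifnot(inherits(section, "bark_section"), n >= 1)
  scheme <- match.arg(scheme)
  ang <- withr::with_seed(seed, {
    if (scheme == "random") {
      stats::runif(n, 0, 360)
    } else {
      (stats::runif(1, 0, 360) + (seq_len(n) - 1) * 360 / n) %% 360
    }
  })
  tibble::tibble(
    section_id = section$spec$name %||% "section",
    angle_deg = ang,
    reading_cm = pmax(bark_thickness_at(section, ang) + bias_cm, 0),
    scheme = scheme
  )
}

#' Convert a synthetic section into a contour-gauge trace
#'
#' Bridges the simulator to [bfi_cm()]: samples the outer bark surface height
#' above the wood surface along an arc, and takes the three thickness anchors
#' at the start, centre and end of the profile. `anchor_rule = "local"` uses
#' the thickness exactly at those angles (what a gauge pushed in at the profile
#' ends would read); `"ridge"` uses `bt_max` for any anchor that falls inside a
#' fissure, mimicking a field crew anchoring on the nearest solid ridge.
#'
#' @param section A `bark_section`.
#' @param arc_span Degrees of circumference covered (default full circle).
#' @param start_deg Starting angle of the trace, degrees.
#' @param n_points Number of trace samples (default 3601).
#' @param anchor_rule `"local"` or `"ridge"` (see above).
#' @return List with elements `trace` (tibble `arc_cm`, `height_cm`),
#'   `anchors`, `arc_span`, `tape_dob`.
#' @export
section_to_trace <- function(section, arc_span = 360, start_deg = 0,
                             n_points = 3601,
                             anchor_rule = c("local", "ridge")) {
  stopifnot(inherits(section, "bark_section"), n_points >= 2)
  anchor_rule <- match.arg(anchor_rule)
  theta <- start_deg + seq(0, arc_span, length.out = n_points)
  radius_outer <- section$wood_radius + section$bt_max
  trace <- tibble::tibble(
    arc_cm = (theta - start_deg) * pi / 180 * radius_outer,
    height_cm = bark_thickness_at(section, theta)
  )
  anchor_theta <- start_deg + c(0, arc_span / 2, arc_span)
  anchors <- bark_thickness_at(section, anchor_theta)
  if (anchor_rule == "ridge") {
    anchors[anchors < section$bt_max] <- section$bt_max
  }
  list(
    trace = trace, anchors = anchors,
    arc_span = arc_span, tape_dob = section$tape_dob
  )
}

#' Monte Carlo validation of the bark-gauge BFI estimator
#'
#' For each candidate sample size, repeatedly simulates random-angle gauge
#' readings on the section, forms the thickness-ratio BFI estimate
#' `mean(readings) / bt_max` (with `bt_max` known from the spec), and reports
#' the estimator's mean, spread and empirical error against the section's
#' known truth, side by side with the t-formula prediction of [error_for_n()]
#' evaluated at the section's thickness CV. The empirical relative error is
#' the observed margin of error of the estimator: the t quantile used by the
#' prediction multiplied by the Monte Carlo standard deviation of the
#' estimates, relative to truth -- the direct empirical counterpart of
#' `CV * t / sqrt(n)`, which checks the variance model without mixing in the
#' t-versus-normal quantile gap. The 95th percentile of the absolute relative
#' deviation is also reported (`q95_dev_pct`).
#'
#' @param spec A [section_spec()].
#' @param n_values Sample sizes to evaluate.
#' @param replicates Monte Carlo replicates per sample size, `>= 2`.
#' @param seed Integer seed for all replicate draws.
#' @param scheme Passed to the angle draws (`"random"` or `"systematic"`).
#' @param bias_cm Constant gauge bias, cm.
#' @return Tibble of class `bgm_validation` with columns `n`, `mean_bfi`,
#'   `sd_bfi`, `bias`, `rel_error_pct`, `q95_dev_pct`, `predicted_error_pct`;
#'   the section's truths ride along as attributes (see
#'   [glance.bgm_validation()]).
#' @export
validate_bgm <- function(spec, n_values = c(5, 10, 15, 20, 30),
                         replicates = 200, seed = 20210114,
                         scheme = c("random", "systematic"), bias_cm = 0) {
  stopifnot(inherits(spec, "section_spec"), replicates >= 2)
  scheme <- match.arg(scheme)
  section <- make_section(spec)
  truth <- section$true_bfi_thickness
  rows <- withr::with_seed(seed, {
    purrr::map(n_values, function(n) {
      ang <- if (scheme == "random") {
        matrix(stats::runif(n * replicates, 0, 360), nrow = replicates)
      } else {
        offs <- stats::runif(replicates, 0, 360)
        (outer(offs, (seq_len(n) - 1) * 360 / n, `+`)) %% 360
      }
      bt <- bark_thickness_at(section, as.vector(ang))
      dim(bt) <- dim(ang)
      bt_f_hat <- rowMeans(pmax(bt + bias_cm, 0))
      bfi_hat <- pmin(bt_f_hat / section$bt_max, 1)
      rel <- abs(bfi_hat - truth) / truth * 100
      t_quantile <- stats::qt(0.975, df = n - 1)
      tibble::tibble(
        n = as.integer(n),
        mean_bfi = mean(bfi_hat),
        sd_bfi = stats::sd(bfi_hat),
        bias = mean(bfi_hat) - truth,
        rel_error_pct = 100 * t_quantile * stats::sd(bfi_hat) / truth,
        q95_dev_pct = unname(stats::quantile(rel, 0.95)),
        predicted_error_pct = error_for_n(section$thickness_cv, n)
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "true_bfi_thickness") <- truth
  attr(out, "true_bfi_area") <- section$true_bfi_area
  attr(out, "thickness_cv") <- section$thickness_cv
  attr(out, "replicates") <- replicates
  attr(out, "scheme") <- scheme
  class(out) <- c("bgm_validation", class(out))
  out
}

#' Default synthetic bark morphologies
#'
#' Four seeded section specifications spanning the bark types the estimator is
#' meant for: a deeply fissured ironbark-like section (thickness BFI around
#' 0.67, reading CV around 36%), a smooth section with occasional narrow
#' cracks (BFI around 0.95, CV around 16%), a scaly section with many shallow
#' fissures (BFI around 0.9), and a fibrous section with sparse box-shaped
#' fissures (CV around 38%). Notch parameters were derived from the closed-form
#' mean and variance of the deficit distribution so that each realised section
#' lands within 0.05 of its target.
#'
#' @return Named list of [section_spec()] objects: `deep_fissured`, `smooth`,
#'   `scaly`, `fibrous`.
#' @export
default_morphologies <- function() {
  list(
    deep_fissured = section_spec(
      wood_radius = 11.05, bt_max = 3.1, n_fissures = 12,
      depth_range = c(2.00, 2.67), halfwidth_range = c(12.0, 14.2),
      shape = "triangular", seed = 20210114, name = "deep_fissured"
    ),
    smooth = section_spec(
      wood_radius = 9.15, bt_max = 1.0, n_fissures = 5,
      depth_range = c(0.70, 0.84), halfwidth_range = c(4.2, 5.2),
      shape = "triangular", seed = 20210115, name = "smooth"
    ),
    scaly = section_spec(
      wood_radius = 11.6, bt_max = 1.1, n_fissures = 15,
      depth_range = c(0.43, 0.53), halfwidth_range = c(5.0, 6.0),
      shape = "triangular", seed = 20210116, name = "scaly"
    ),
    fibrous = section_spec(
      wood_radius = 13.1, bt_max = 0.9, n_fissures = 6,
      depth_range = c(0.74, 0.84), halfwidth_range = c(4.45, 5.45),
      shape = "rectangular", seed = 20210117, name = "fibrous"
    )
  )
}
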