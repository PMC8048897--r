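#' Area of a closed planar polygon
#'
#' Absolute shoelace (surveyor's) area of a polygon given by its vertices in
#' order. The polyline is treated as closed; a duplicated closing vertex is
#' tolerated. Orientation-independent and invariant under rigid motions.
#'
#' @param x Either a numeric vector of x coordinates (cm), a two-column
#'   matrix, or a data frame with `x`/`y` (or `x_cm`/`y_cm`) columns.
#' @param y Numeric vector of y coordinates when `x` is a vector.
#' @return Enclosed area, cm^2.
#' @examples
#' polygon_area(c(0, 1, 1, 0), c(0, 0, 1, 1)) # unit square
#' @export
polygon_area <- function(x, y = NULL) {
  p <- as_xy(x, y)
  n <- nrow(p)
  if (n >= 2 && all(p[1, ] == p[n, ])) {
    p <- p[-n, , drop = FALSE]
    n <- n - 1
  }
  if (n < 3) {
    rlang::abort("A polygon needs at least 3 distinct vertices.")
  }
  xs <- p[, 1]
  ys <- p[, 2]
  nxt <- c(2:n, 1)
  a <- abs(sum(xs * ys[nxt] - xs[nxt] * ys)) / 2
  scale <- max(diff(range(xs)), diff(range(ys)), 1)
  if (a <= 1e-12 * scale^2) {
    rlang::abort("Degenerate polygon: vertices are collinear or coincident.")
  }
  a
}

as_xy <- function(x, y) {
  if (is.data.frame(x)) {
    nm <- names(x)
    xcol <- intersect(c("x", "x_cm"), nm)[1]
    ycol <- intersect(c("y", "y_cm"), nm)[1]
    if (is.na(xcol) || is.na(ycol)) {
      rlang::abort("Data frame must have `x`/`y` (or `x_cm`/`y_cm`) columns.")
    }
    p <- cbind(x[[xcol]], x[[ycol]])
  } else if (is.matrix(x) && ncol(x) == 2) {
    p <- x
  } else if (is.numeric(x) && is.numeric(y)) {
    if (length(x) != length(y)) {
      rlang::abort("`x` and `y` must have the same length.")
    }
    p <- cbind(x, y)
  } else {
    rlang::abort("Supply coordinates as x/y vectors, a 2-column matrix, or a data frame.")
  }
  if (any(!is.finite(p))) {
    rlang::abort("All vertex coordinates must be finite.")
  }
  p
}

# TRUE if the closed polygon has no crossing edges. O(n^2) pairwise segment
# test, vectorised; skipped (returns NA) above `max_vertices` to keep large
# digitizations cheap.
is_simple_polygon <- function(x, y = NULL, max_vertices = 2000) {
  p <- as_xy(x, y)
  n <- nrow(p)
  if (n >= 2 && all(p[1, ] == p[n, ])) {
    p <- p[-n, , drop = FALSE]
    n <- n - 1
  }
  if (n > max_vertices) {
    return(NA)
  }
  ax <- p[, 1]; ay <- p[, 2]
  bx <- ax[c(2:n, 1)]; by <- ay[c(2:n, 1)]
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  adjacent <- (j - i == 1) | (i == 1 & j == n)
  i <- i[!adjacent]; j <- j[!adjacent]
  if (!length(i)) return(TRUE)
  cross <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  d1 <- cross(ax[i], ay[i], bx[i], by[i], ax[j], ay[j])
  d2 <- cross(ax[i], ay[i], bx[i], by[i], bx[j], by[j])
  d3 <- cross(ax[j], ay[j], bx[j], by[j], ax[i], ay[i])
  d4 <- cross(ax[j], ay[j], bx[j], by[j], bx[i], by[i])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Area of an idealized circular bark annulus
#'
#' `pi / 4 * (dob^2 - dub^2)`: the bark ring a diameter tape implies, i.e. the
#' area between the over-bark circle and the under-bark circle. Divided by the
#' over-bark disk area it equals the relative bark area of
#' [relative_bark_area()].
#'
#' @param dob Diameter over bark, cm.
#' @param dub Diameter under bark, cm, with `0 <= dub < dob`.
#' @return Annulus area, cm^2. Vectorised.
#' @export
annulus_area <- function(dob, dub) {
  if (any(!is.finite(dob)) || any(!is.finite(dub)) || any(dob <= 0)) {
    rlang::abort("`dob` must be positive and both diameters finite (cm).")
  }
  if (any(dub < 0) || any(dub >= dob)) {
    rlang::abort("`dub` must satisfy 0 <= dub < dob.")
  }
  pi / 4 * (dob^2 - dub^2)
}

new_bfi_estimate <- function(value, method, n, section_id = NULL, extra = list()) {
  structure(
    c(list(
      value = value, method = method, n = n,
      section_id = section_id %||% NA_character_
    ), extra),
    class = "bfi_estimate"
  )
}

#' @export
print.bfi_estimate <- function(x, ...) {
  cat(sprintf(
    "BFI (%s method): %.4f  [section %s, n = %d]\n",
    x$method, x$value, x$section_id, x$n
  ))
  invisible(x)
}

#' @export
as.double.bfi_estimate <- function(x, ...) x$value

#' Bark fissure index from a digitized cross-section (DM)
#'
#' The reference, destructive method: the solid bark area (outer bark polygon
#' minus wood polygon) is divided by the idealized bark annulus implied by the
#' tape-measured diameter over bark. The inner (under-bark) diameter of the
#' annulus is, by default, the area-equivalent diameter of the digitized wood
#' polygon, `2 * sqrt(area_wood / pi)`; alternatively
#' `dub_rule = "bt_max"` uses `tape_dob - 2 * bt_max`.
#'
#' @param profile Data frame of digitized contour vertices with columns
#'   `contour` (`"outer"` or `"wood"`), `x`, `y` (cm), vertices in traversal
#'   order; e.g. from [read_contours()] or [to_profile()].
#' @param tape_dob Diameter over bark measured by tape, cm. Defaults to the
#'   `tape_dob` attribute of `profile` when present.
#' @param dub_rule How the annulus inner diameter is derived (see above).
#' @param bt_max Maximum bark thickness, cm; required for
#'   `dub_rule = "bt_max"`.
#' @param section_id Optional label carried into the result.
#' @param check_simple Reject self-intersecting contours? (Checked only up to
#'   2000 vertices per contour; larger contours are assumed simple.)
#' @param clamp Clamp values above 1 to 1 with a warning.
#' @return A `bfi_estimate` object with `method = "DM"`; also carries
#'   `solid_area_cm2`, `annulus_area_cm2`, `outer_area_cm2`, `wood_area_cm2`.
#' @export
bfi_dm <- function(profile, tape_dob = NULL,
                   dub_rule = c("wood_equivalent", "bt_max"), bt_max = NULL,
                   section_id = NULL, check_simple = TRUE, clamp = TRUE) {
  dub_rule <- match.arg(dub_rule)
  stopifnot(is.data.frame(profile))
  if (!all(c("contour", "x", "y") %in% names(profile)) &&
    !all(c("contour", "x_cm", "y_cm") %in% names(profile))) {
    rlang::abort("`profile` needs columns `contour`, `x`, `y` (or `x_cm`, `y_cm`).")
  }
  tape_dob <- tape_dob %||% attr(profile, "tape_dob", exact = TRUE)
  if (is.null(tape_dob) || !is.finite(tape_dob) || tape_dob <= 0) {
    rlang::abort("`tape_dob` (tape-measured diameter over bark, cm) is required.")
  }
  outer <- profile[profile$contour == "outer", , drop = FALSE]
  wood <- profile[profile$contour == "wood", , drop = FALSE]
  if (nrow(outer) < 3 || nrow(wood) < 3) {
    rlang::abort("Both an `outer` and a `wood` contour with >= 3 vertices are required.")
  }
  if (isTRUE(check_simple)) {
    for (part in list(outer = outer, wood = wood)) {
      simple <- is_simple_polygon(part)
      if (isFALSE(simple)) {
        rlang::abort("Self-intersecting contour polygons are rejected, not repaired.")
      }
    }
  }
  a_outer <- polygon_area(outer)
  a_wood <- polygon_area(wood)
  # cheap containment check: the wood contour must sit inside the outer envelope
  ob <- apply(as_xy(outer, NULL), 2, range)
  wb <- apply(as_xy(wood, NULL), 2, range)
  tol <- 1e-9 * max(ob[2, ] - ob[1, ])
  if (any(wb[1, ] < ob[1, ] - tol) || any(wb[2, ] > ob[2, ] + tol) || a_wood >= a_outer) {
    rlang::abort("The wood contour must lie strictly inside the outer contour.")
  }
  solid <- a_outer - a_wood
  dub <- switch(dub_rule,
    wood_equivalent = 2 * sqrt(a_wood / pi),
    bt_max = {
      if (is.null(bt_max)) rlang::abort("`bt_max` is required for dub_rule = \"bt_max\".")
      tape_dob - 2 * bt_max
    }
  )
  denom <- annulus_area(tape_dob, dub)
  value <- solid / denom
  if (clamp && value > 1) {
    rlang::warn("BFI_DM exceeded 1 and was clamped to 1 (check tape_dob).")
    value <- 1
  }
  new_bfi_estimate(
    value, "DM", nrow(outer) + nrow(wood), section_id,
    extra = list(
      solid_area_cm2 = solid, annulus_area_cm2 = denom,
      outer_area_cm2 = a_outer, wood_area_cm2 = a_wood,
      tape_dob = tape_dob, dub_cm = dub
    )
  )
}

# trapezoid rule on (x, y) samples
trapz <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Bark fissure index from a contour-gauge trace (CM)
#'
#' The contour method: the outer bark surface is traced with a contour gauge
#' over part of the circumference and bark thickness is measured at three
#' anchor points (start, centre and end of the profile). The under-bark line is
#' reconstructed by subtracting the thickness field -- interpolated
#' piecewise-linearly in arc position between the anchors -- from the traced
#' profile. The solid bark area (between trace and reconstructed wood line) is
#' divided by the idealized envelope area between the projected outer surface
#' (the maximum trace height, which is what a diameter tape would register) and
#' the wood line. Areas are evaluated in unrolled (arc length x height)
#' coordinates, a thin-bark approximation whose error is of order
#' bark thickness / stem diameter.
#'
#' @param trace Data frame with columns `arc_cm` (position along the outer
#'   circumference) and `height_cm` (traced outer bark surface height above the
#'   wood-contact datum); at least 2 points.
#' @param anchors Numeric length-3 vector of bark thicknesses (cm) at the
#'   start, centre and end of the profile; positive.
#' @param arc_span Degrees of circumference covered by the trace, in
#'   `(0, 360]`. Used only for metadata scaling of absolute areas.
#' @param tape_dob Optional tape-measured diameter over bark, cm (metadata).
#' @param section_id Optional label.
#' @return A `bfi_estimate` with `method = "CM"`, carrying `solid_area_cm2`
#'   and `envelope_area_cm2`.
#' @examples
#' # a solid slab: flat profile, anchors equal to its height -> BFI = 1
#' tr <- tibble::tibble(arc_cm = 0:10, height_cm = 2)
#' bfi_cm(tr, anchors = c(2, 2, 2), arc_span = 90)$value
#' @export
bfi_cm <- function(trace, anchors, arc_span = 360, tape_dob = NULL,
                   section_id = NULL) {
  stopifnot(is.data.frame(trace))
  if (!all(c("arc_cm", "height_cm") %in% names(trace))) {
    rlang::abort("`trace` needs columns `arc_cm` and `height_cm`.")
  }
  if (nrow(trace) < 2) {
    rlang::abort("A trace needs at least 2 profile points.")
  }
  if (length(anchors) != 3 || any(!is.finite(anchors)) || any(anchors <= 0)) {
    rlang::abort("`anchors` must be 3 positive thicknesses (start, centre, end), cm.")
  }
  if (length(arc_span) != 1 || !is.finite(arc_span) || arc_span <= 0 || arc_span > 360) {
    rlang::abort("`arc_span` must be in (0, 360] degrees.")
  }
  trace <- trace[order(trace$arc_cm), , drop = FALSE]
  s <- trace$arc_cm
  h <- trace$height_cm
  if (any(!is.finite(s)) || any(!is.finite(h)) || any(h < 0)) {
    rlang::abort("Trace positions and heights must be finite and heights non-negative.")
  }
  s0 <- s[1]
  s1 <- s[length(s)]
  bt <- stats::approx(c(s0, (s0 + s1) / 2, s1), anchors, xout = s, rule = 2)$y
  wood <- h - bt
  if (any(wood < -1e-12)) {
    rlang::warn(
      "Anchor thickness exceeds the local profile height; wood line truncated at zero."
    )
    wood <- pmax(wood, 0)
  }
  env <- max(h)
  solid <- trapz(s, h - wood)
  envelope <- trapz(s, env - wood)
  if (envelope <= 0 || solid <= 0) {
    rlang::abort("Degenerate trace: solid bark or envelope area is non-positive.")
  }
  extra <- list(
    solid_area_cm2 = solid, envelope_area_cm2 = envelope, arc_span = arc_span
  )
  if (!is.null(tape_dob)) {
    extra$tape_dob <- tape_dob
    bt_env <- env - min(wood)
    if (tape_dob > 2 * bt_env) {
      extra$annulus_area_cm2 <-
        annulus_area(tape_dob, tape_dob - 2 * bt_env) * arc_span / 360
    }
  }
  new_bfi_estimate(min(solid / envelope, 1), "CM", nrow(trace), section_id, extra)
}
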