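test_that("shoelace area handles squares, closure and orientation", {
  expect_equal(polygon_area(c(0, 1, 1, 0), c(0, 0, 1, 1)), 1)
  expect_equal(polygon_area(c(0, 0, 1, 1), c(0, 1, 1, 0)), 1) # reversed order
  # duplicated closing vertex tolerated
  expect_equal(polygon_area(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0)), 1)
  expect_error(polygon_area(c(0, 1), c(0, 1)), "3")
  expect_error(polygon_area(c(0, 1, 2), c(0, 1, 2)), "Degenerate")
})

test_that("a fine regular polygon recovers the circle area", {
  p <- circle_poly(3.7, 3600)
  expect_equal(polygon_area(p), pi * 3.7^2, tolerance = 1e-4) # within 0.01%
})

test_that("shoelace area agrees with an independent implementation", {
  skip_if_not_installed("pracma")
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    r <- runif(n, 0.5, 3)
    th <- sort(runif(n, 0, 2 * pi)) # star-shaped, hence simple
    x <- r * cos(th)
    y <- r * sin(th)
    expect_equal(polygon_area(x, y), abs(pracma::polyarea(x, y)),
      tolerance = 1e-12
    )
  }
})

test_that("polygon area is invariant under rigid motions", {
  set.seed(5)
  base <- circle_poly(2, 40)
  a0 <- polygon_area(base)
  for (i in 1:10) {
    phi <- runif(1, 0, 2 * pi)
    dx <- runif(1, -50, 50)
    dy <- runif(1, -50, 50)
    x <- base$x * cos(phi) - base$y * sin(phi) + dx
    y <- base$x * sin(phi) + base$y * cos(phi) + dy
    expect_equal(polygon_area(x, y), a0, tolerance = 1e-10)
  }
})

test_that("annulus area matches direct evaluation and the RBA identity", {
  expect_equal(annulus_area(28.3, 22.1), pi / 4 * (28.3^2 - 22.1^2))
  expect_equal(annulus_area(9, 0), pi / 4 * 81) # full disk
  # cross-module identity: annulus / over-bark disk = relative bark area
  expect_equal(
    annulus_area(28.3, 22.1) / (pi / 4 * 28.3^2),
    relative_bark_area(28.3, 3.1),
    tolerance = 1e-12
  )
  expect_error(annulus_area(10, 10), "dub")
  expect_error(annulus_area(10, -1), "dub")
})

test_that("digitized BFI is exactly 1 for concentric circles", {
  profile <- dplyr::bind_rows(
    dplyr::mutate(circle_poly(11, 1440), contour = "outer"),
    dplyr::mutate(circle_poly(10, 1440), contour = "wood")
  )
  est <- bfi_dm(profile, tape_dob = 22)
  expect_equal(est$method, "DM")
  expect_equal(est$value, 1, tolerance = 1e-4)
})

test_that("a notch removing a quarter of the annulus gives BFI = 0.75", {
  # outer contour: radius 11 except radius 10 over a 90-degree arc
  n <- 7200
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  eps <- 1e-9
  th <- sort(c(th, pi / 2 - eps, pi / 2 + eps, pi - eps, pi + eps))
  r <- ifelse(th > pi / 2 & th < pi, 10, 11)
  profile <- dplyr::bind_rows(
    tibble::tibble(contour = "outer", x = r * cos(th), y = r * sin(th)),
    dplyr::mutate(circle_poly(10, n), contour = "wood")
  )
  est <- bfi_dm(profile, tape_dob = 22, check_simple = FALSE)
  expect_equal(est$value, 0.75, tolerance = 1e-4)
})

test_that("rectangular notches reduce BFI by exactly their area share", {
  # shoelace oracle on a constructed fixture: wood circle radius 10, envelope
  # radius 11, two box notches of known angular width going to full depth
  n <- 7200
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  spans <- list(c(0.3, 0.8), c(2.0, 2.9)) # radians
  eps <- 1e-9
  th <- sort(c(th, unlist(lapply(spans, function(s) c(s - eps, s + eps)))))
  r <- rep(11, length(th))
  for (s in spans) r[th > s[1] & th < s[2]] <- 10
  outer <- tibble::tibble(contour = "outer", x = r * cos(th), y = r * sin(th))
  profile <- dplyr::bind_rows(
    outer, dplyr::mutate(circle_poly(10, n), contour = "wood")
  )
  notch_area <- sum(vapply(spans, function(s) diff(s), 1)) / 2 * (11^2 - 10^2)
  annulus <- pi * (11^2 - 10^2)
  est <- bfi_dm(profile, tape_dob = 22, check_simple = FALSE)
  expect_equal(est$value, 1 - notch_area / annulus, tolerance = 1e-4)
  # removing material strictly decreases BFI
  full <- bfi_dm(
    dplyr::bind_rows(
      dplyr::mutate(circle_poly(11, n), contour = "outer"),
      dplyr::mutate(circle_poly(10, n), contour = "wood")
    ),
    tape_dob = 22, check_simple = FALSE
  )
  expect_lt(est$value, full$value)
})

test_that("the annulus inner diameter rule is selectable", {
  profile <- dplyr::bind_rows(
    dplyr::mutate(circle_poly(11, 720), contour = "outer"),
    dplyr::mutate(circle_poly(10, 720), contour = "wood")
  )
  a <- bfi_dm(profile, tape_dob = 22, dub_rule = "wood_equivalent")
  b <- bfi_dm(profile, tape_dob = 22, dub_rule = "bt_max", bt_max = 1)
  expect_equal(a$value, b$value, tolerance = 1e-3)
  expect_error(bfi_dm(profile, tape_dob = 22, dub_rule = "bt_max"), "bt_max")
})

test_that("self-intersecting and inconsistent contours are rejected", {
  bowtie <- tibble::tibble(
    contour = "outer",
    x = c(0, 2, 0, 2), y = c(0, 2, 2, 0)
  )
  profile <- dplyr::bind_rows(
    bowtie,
    dplyr::mutate(circle_poly(0.2, 30, cx = 1, cy = 1), contour = "wood")
  )
  expect_error(bfi_dm(profile, tape_dob = 3), "Self-intersecting")
  # wood contour outside the outer envelope
  off <- dplyr::bind_rows(
    dplyr::mutate(circle_poly(2, 60), contour = "outer"),
    dplyr::mutate(circle_poly(1, 60, cx = 5), contour = "wood")
  )
  expect_error(bfi_dm(off, tape_dob = 4), "inside")
})

test_that("contour method gives 1 for a solid slab", {
  tr <- tibble::tibble(arc_cm = seq(0, 12, by = 0.5), height_cm = 2)
  est <- bfi_cm(tr, anchors = c(2, 2, 2), arc_span = 90)
  expect_equal(est$method, "CM")
  expect_equal(est$value, 1)
})

test_that("a half-void sawtooth gives BFI = 0.5 under the reconstruction", {
  # teeth oscillate between 3 and 1; constant anchors of 1 put the wood line
  # 1 below the trace, so the fissures occupy exactly half the area between
  # the projected envelope (3) and the wood line
  s <- 0:20
  h <- rep(c(3, 1), length.out = 21)
  est <- bfi_cm(
    tibble::tibble(arc_cm = s, height_cm = h),
    anchors = c(1, 1, 1), arc_span = 180
  )
  # trapezoid oracle on the same polyline
  wood <- h - 1
  solid_oracle <- sum(diff(s) * (head(h - wood, -1) + tail(h - wood, -1)) / 2)
  env_oracle <- sum(diff(s) * (head(3 - wood, -1) + tail(3 - wood, -1)) / 2)
  expect_equal(est$value, solid_oracle / env_oracle, tolerance = 1e-12)
  expect_equal(est$value, 0.5, tolerance = 1e-12)
})

test_that("anchors larger than the local profile height truncate with warning", {
  tr <- tibble::tibble(arc_cm = 0:10, height_cm = c(rep(2, 5), 0.5, rep(2, 5)))
  expect_warning(est <- bfi_cm(tr, anchors = c(2, 2, 2), arc_span = 90), "truncated")
  expect_lte(est$value, 1)
  expect_gt(est$value, 0)
})

test_that("contour and digitized methods agree on moderately fissured sections", {
  for (name in c("smooth", "scaly", "fibrous")) {
    sec <- make_section(default_morphologies()[[name]])
    dm <- bfi_dm(to_profile(sec, 10))
    tr <- section_to_trace(sec)
    cm <- suppressWarnings(
      bfi_cm(tr$trace, tr$anchors, tr$arc_span, tr$tape_dob)
    )
    expect_lt(abs(cm$value - dm$value) / dm$value, 0.05)
  }
})

test_that("contour trace input is validated", {
  tr <- tibble::tibble(arc_cm = 0:5, height_cm = 1)
  expect_error(bfi_cm(tr, anchors = c(1, 1), arc_span = 90), "3 positive")
  expect_error(bfi_cm(tr, anchors = c(1, 1, 1), arc_span = 0), "arc_span")
  expect_error(bfi_cm(tr[1, ], anchors = c(1, 1, 1), arc_span = 90), "2 profile points")
})
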