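test_that("ridge BT_max averages within quadrants before averaging across", {
  expect_equal(
    bt_max_ridge(c(3.0, 3.2, 3.1, 2.9, 3.1, 3.3), quadrant = rep(1:2, each = 3)),
    3.1
  )
  expect_equal(bt_max_ridge(rep(2.4, 5)), 2.4)
  expect_equal(bt_max_ridge(1.1), 1.1)
  # unbalanced quadrants: quadrant means first, so the big quadrant cannot dominate
  expect_equal(bt_max_ridge(c(1, 1, 1, 1, 3), quadrant = c(1, 1, 1, 1, 2)), 2)
  expect_error(bt_max_ridge(numeric()), "non-empty")
})

test_that("smooth-bark BT_max is the mean of the three largest readings", {
  expect_equal(
    bt_max_smooth(c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0, 1.0, 1.1, 0.4, 0.3)),
    mean(c(1.1, 1.0, 1.0))
  )
  expect_equal(bt_max_smooth(rep(0.8, 10)), 0.8)
  expect_equal(bt_max_smooth(c(1, 2, 3)), 2)
  expect_error(bt_max_smooth(c(1, 2)), "bt_max_ridge")
})

test_that("BT_f summary uses the sample standard deviation and CV of the mean", {
  s <- bt_f_summary(c(1, 3))
  expect_equal(s$bt_f_cm, 2)
  expect_equal(s$sd_cm, sqrt(2)) # closed-form two-point sample sd
  expect_equal(s$cv_pct, 100 * sqrt(2) / 2)
  const <- bt_f_summary(rep(1.3, 8))
  expect_equal(const$sd_cm, 0)
  expect_equal(const$cv_pct, 0)
  expect_error(bt_f_summary(c(1, 2), scheme = "ridge_only"), "BT_max")
})

test_that("bt_max from the top-3 rule never falls below the overall mean", {
  set.seed(11)
  for (i in 1:30) {
    r <- runif(sample(3:40, 1), 0, 4)
    expect_gte(bt_max_smooth(r), mean(r))
  }
})

test_that("BFI via the gauge method matches the study ratios and clamps at 1", {
  expect_equal(bfi_bgm(2.1, 3.1), 2.1 / 3.1) # ~0.677, deeply fissured
  expect_equal(bfi_bgm(0.9, 1.0), 0.9)       # smooth bark
  expect_equal(bfi_bgm(1.4, 1.4), 1)
  expect_warning(v <- bfi_bgm(1.2, 1.0), "clamped")
  expect_equal(v, 1)
  expect_equal(bfi_bgm(1.2, 1.0, clamp = FALSE), 1.2)
  expect_error(bfi_bgm(1, 0), "bt_max")
})

test_that("t-quantile error formula reproduces frozen reference values", {
  # frozen from CV * t_{0.975, n-1} / sqrt(n) evaluated by hand
  expect_equal(error_for_n(35.75, 5), 44.38949, tolerance = 1e-6)
  expect_equal(error_for_n(15.77, 30), 5.888615, tolerance = 1e-6)
  expect_equal(error_for_n(0, 17), 0)
  expect_error(error_for_n(10, 1), "n")
})

test_that("error formula is strictly decreasing in n and linear in cv", {
  e <- error_for_n(20, 2:60)
  expect_true(all(diff(e) < 0))
  expect_equal(error_for_n(40, 12), 2 * error_for_n(20, 12), tolerance = 1e-12)
})

test_that("required_n is the exact inverse of the error formula", {
  for (cv in c(5, 15.35, 35.75, 80)) {
    for (target in c(5, 10, 20, 40)) {
      n <- required_n(cv, target)
      if (is.na(n)) next
      expect_lte(error_for_n(cv, n), target)
      if (n > 2) expect_gt(error_for_n(cv, n - 1), target)
    }
  }
  expect_equal(required_n(0, 1), 2L)
  expect_warning(n <- required_n(500, 0.1, n_max = 50), "not achievable")
  expect_true(is.na(n))
  expect_error(required_n(10, -1), "target_error")
})

test_that("sampling of fissured bark needs about three times more readings", {
  expect_equal(required_n(35.75, 20), 15L)
  expect_equal(required_n(15.77, 20), 5L)
})

test_that("error_table tabulates percent and self-consistent cm errors", {
  tab <- error_table(35.75, 2.08)
  expect_equal(tab$n, c(5L, 10L, 15L, 20L, 30L))
  expect_equal(tab$error_pct, error_for_n(35.75, tab$n))
  expect_equal(tab$error_cm, tab$error_pct * 2.08 / 100)
  expect_equal(round_half_up(error_table(15.35, 1.00, 5)$error_pct), 19)
  zero <- error_table(0, 1.5)
  expect_true(all(zero$error_pct == 0) && all(zero$error_cm == 0))
})

test_that("paired method comparison matches the textbook t computation", {
  set.seed(16)
  a <- runif(16, 0.6, 1)
  b <- pmin(a + rnorm(16, 0.02, 0.04), 1)
  cmp <- compare_bfi_methods(tibble::tibble(bgm = a, cm = b), bgm, cm,
    methods = c("BGM", "CM")
  )
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(16))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 15)
  expect_equal(cmp$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(cmp$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(cmp$mean_difference, mean(d), tolerance = 1e-12)
  td <- tidy(cmp)
  expect_equal(td$p.value, p_oracle)
  expect_equal(td$n_pairs, 16)
})

test_that("degenerate paired comparisons are reported, not crashed on", {
  same <- compare_bfi_methods(c(0.7, 0.8, 0.9), c(0.7, 0.8, 0.9))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$p_value, 1)
  offset <- compare_bfi_methods(c(0.7, 0.8, 0.9), c(0.6, 0.7, 0.8))
  expect_equal(offset$mean_difference, 0.1)
  expect_true(is.na(offset$p_value))
  expect_error(compare_bfi_methods(1, 2), "2 matched pairs")
})

test_that("per-tree gauge summary applies the protocol end to end", {
  readings <- tibble::tibble(
    tree_id = rep(c("t1", "t2"), each = 13),
    species = rep(c("fissured sp.", "smooth sp."), each = 13),
    dob_cm = rep(c(28.3, 20.3), each = 13),
    reading_cm = c(
      # t1: 10 gauge readings + 3 ridge readings
      2.0, 1.8, 2.4, 2.2, 1.9, 2.1, 2.3, 2.0, 2.2, 2.1, 3.0, 3.1, 3.2,
      # t2: 13 gauge readings, no ridges
      0.9, 0.8, 1.0, 0.95, 0.9, 0.85, 0.9, 1.0, 0.9, 0.95, 0.9, 0.85, 0.9
    ),
    reading_kind = c(rep("gauge", 10), rep("ridge", 3), rep("gauge", 13))
  )
  out <- bark_gauge_summary(readings)
  expect_equal(nrow(out), 2)
  t1 <- out[out$tree_id == "t1", ]
  expect_equal(t1$bt_max_cm, 3.1) # ridge mean
  expect_equal(t1$n, 10L)
  expect_equal(t1$bt_f_cm, 2.1)
  expect_equal(t1$bfi, 2.1 / 3.1)
  expect_equal(t1$rba, relative_bark_area(28.3, 3.1))
  t2 <- out[out$tree_id == "t2", ]
  # no ridge rows: top-3 rule, mean(1.0, 1.0, 0.95)
  expect_equal(t2$bt_max_cm, mean(sort(readings$reading_cm[14:26], TRUE)[1:3]))
  expect_equal(t2$bfi, t2$bt_f_cm / t2$bt_max_cm)
})

test_that("gauge bias correction shifts readings before summarising", {
  readings <- tibble::tibble(
    tree_id = "t1",
    reading_cm = c(1.05, 1.05, 1.05, 1.05)
  )
  out <- bark_gauge_summary(readings, bias_cm = 0.05)
  expect_equal(out$bt_f_cm, 1.0)
  expect_equal(out$bt_max_cm, 1.0)
})

test_that("per-quadrant BFI returns quadrant rows plus a pooled row", {
  d <- tibble::tibble(
    reading_cm = c(2, 2.2, 1.8, 2.0, 2.6, 2.4, 2.5, 2.5),
    quadrant = rep(1:2, each = 4)
  )
  out <- bfi_by_quadrant(d, bt_max = 3.1)
  expect_equal(nrow(out), 3)
  expect_equal(out$bfi[1], 2 / 3.1)
  expect_equal(out$bfi[2], 2.5 / 3.1)
  pooled <- out[is.na(out$quadrant), ]
  expect_equal(pooled$bt_f_cm, mean(d$reading_cm))
  expect_equal(pooled$n, 8L)
})
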