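# Monthly binning, OLS trend fits, cross-series statistics, share table.

test_that("monthly binning is calendar-correct and zero-filled", {
  w <- as.Date(c("2011-01-01", "2020-02-29"))
  empty <- make_events(character(0), character(0), window = w)
  s <- bin_monthly(empty, w)
  expect_s3_class(s, "monthly_series")
  expect_equal(length(s$y), 110L)
  expect_true(all(s$y == 0))

  ev <- make_events("DEATH", "X",
                    event_date = as.Date(c("2011-01-02", "2011-01-30",
                                           "2011-03-15")),
                    window = w)
  s <- bin_monthly(ev, w)
  expect_equal(s$y[1:3], c(2L, 0L, 1L))
  expect_equal(sum(s$y), 3L)
})

test_that("binning conserves event counts on random cohorts", {
  cfg <- small_config(seed = 31)
  cc <- cohort_from_events(generate_events(cfg), cfg$window)
  for (cls in c("BMS", "DES")) {
    for (oc in c("MALFUNCTION", "INJURY", "DEATH")) {
      s <- bin_monthly(cc$events, cfg$window, cls, oc)
      expect_equal(sum(s$y),
                   sum(cc$events$stent_class == cls & cc$events$outcome == oc))
    }
  }
})

test_that("trend fitting recovers exact lines and flags constant series", {
  f <- fit_linear_trend(2 * (0:9) + 1, x = 0:9)
  expect_equal(unname(coef(f)), c(1, 2))
  expect_equal(f$r, 1)

  f <- fit_linear_trend(rep(5, 12))
  expect_equal(unname(coef(f)), c(5, 0))
  expect_true(is.na(f$r))  # undefined, not 0

  expect_error(fit_linear_trend(c(1, 2)), "at least 3")
})

test_that("trend fitting agrees with the normal-equations oracle", {
  set.seed(41)
  for (n in c(5, 12, 60, 200)) {
    x <- 0:(n - 1)
    y <- rnorm(n, 10 + 0.3 * x, 4)
    f <- fit_linear_trend(y, x = x)
    want <- ols_oracle(x, y)
    expect_lt(abs(coef(f)[["intercept"]] - want[["intercept"]]), 1e-10)
    expect_lt(abs(coef(f)[["slope"]] - want[["slope"]]), 1e-10)
    expect_equal(f$r, cor(x, y))
  }
})

test_that("pearson R carries the slope's sign on noisy synthetic series", {
  set.seed(43)
  for (i in 1:25) {
    b0 <- runif(1, 20, 200)
    b1 <- runif(1, -0.5, 1.5)
    y <- sample_monthly_counts(trend_spec(b0, b1), 110)
    f <- fit_linear_trend(y)
    if (!is.na(f$r) && coef(f)[["slope"]] != 0) {
      expect_equal(sign(f$r), sign(coef(f)[["slope"]]))
    }
  }
})

test_that("fitted slopes recover the published generating trends", {
  # Poisson counts around each published malfunction trend line; the mean
  # fitted slope over 200 replicates must sit within 3 standard errors of
  # the generating slope.
  for (p in list(c(51.7, -0.38), c(190.1, 1.5))) {
    set.seed(47)
    slopes <- replicate(200, {
      y <- sample_monthly_counts(trend_spec(p[1], p[2]), 110)
      coef(fit_linear_trend(y))[["slope"]]
    })
    se <- sd(slopes) / sqrt(length(slopes))
    expect_lt(abs(mean(slopes) - p[2]), 3 * se)
  }
})

test_that("trend comparison ratios follow their closed forms", {
  bms <- fit_linear_trend(51.7 - 0.38 * (0:109), x = 0:109)
  des <- fit_linear_trend(190.1 + 1.5 * (0:109), x = 0:109)

  expect_equal(slope_to_intercept_ratio(bms), -0.38 / 51.7)
  expect_equal(slope_to_intercept_ratio(des), 1.5 / 190.1)
  expect_equal(slope_to_intercept_ratio(fit_linear_trend(rep(7, 10))), 0)
  origin_fit <- structure(list(coefficients = c(intercept = 0, slope = 1)),
                          class = "trend_fit")
  expect_error(slope_to_intercept_ratio(origin_fit), "undefined")

  expect_equal(magnitude_ratio(des, bms), 1.5 / 0.38)
  expect_equal(magnitude_ratio(des, des), 1)
  expect_error(magnitude_ratio(des, fit_linear_trend(rep(3, 10))), "zero")
  set.seed(13)
  for (i in 1:10) {
    a <- runif(1, -5, 5)
    b <- runif(1, 0.1, 5)
    expect_equal(magnitude_ratio(a, b), abs(a) / abs(b))
  }
})

test_that("series combine element-wise over a shared window", {
  w <- as.Date(c("2013-01-01", "2013-02-28"))
  ev_a <- make_events(rep("INJURY", 3), "X",
                      event_date = as.Date(c("2013-01-05", "2013-02-01",
                                             "2013-02-20")), window = w)
  a <- bin_monthly(ev_a, w, outcome = "INJURY")
  zero <- bin_monthly(make_events(character(0), character(0), window = w), w)
  expect_equal(combined_series(a, zero)$y, a$y)
  b <- a
  b$y <- c(3L, 4L)
  expect_equal(combined_series(a, b)$y, a$y + b$y)
  expect_equal(sum(combined_series(a, b)$y), sum(a$y) + sum(b$y))
  wrong <- bin_monthly(make_events(character(0), character(0)),
                       as.Date(c("2013-01-01", "2013-03-31")))
  expect_error(combined_series(a, wrong), "windows differ")
})

test_that("share table reproduces published-scale percentages and edge cases", {
  counts <- matrix(c(3182, 3144, 676,
                     29176, 26409, 5172,
                     31, 732, 96),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("BMS", "DES", "BVS"),
                                   c("MALFUNCTION", "INJURY", "DEATH")))
  st <- share_table(counts)
  expect_equal(st$total, 68618)
  expect_equal(unname(signif(st$class_percent, 3)), c(10.2, 88.5, 1.25))
  expect_equal(unname(signif(st$outcome_percent, 3)), c(47.2, 44.1, 8.66))
  expect_equal(sum(st$class_percent), 100)
  expect_equal(sum(st$outcome_percent), 100)
  # cells sum to marginals
  expect_equal(rowSums(st$counts), st$class_total)
  expect_equal(colSums(st$counts), st$outcome_total)

  one <- share_table(matrix(c(1, 0), 1, 2,
                            dimnames = list("BMS", c("MALFUNCTION", "INJURY"))))
  expect_equal(unname(one$cell_percent[1, 1]), 100)
  empty <- share_table(matrix(0, 2, 2))
  expect_true(all(is.na(empty$class_percent)))
})

test_that("cohort share table matches the cohort cell counts", {
  cfg <- small_config(seed = 33)
  cc <- cohort_from_events(generate_events(cfg), cfg$window)
  st <- outcome_share_table(cc$events)
  for (cls in c("BMS", "DES")) {
    for (oc in c("MALFUNCTION", "INJURY", "DEATH")) {
      expect_equal(unname(st$counts[cls, oc]),
                   sum(cc$events$stent_class == cls & cc$events$outcome == oc))
      s <- bin_monthly(cc$events, cfg$window, cls, oc)
      expect_equal(sum(s$y), unname(st$counts[cls, oc]))
    }
  }
})
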