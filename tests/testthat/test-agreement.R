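test_that("percent difference, bias and MAD evaluate their formulas", {
  expect_equal(percent_diff(10.5, 10), 5.0)
  expect_equal(percent_diff(10, 10), 0.0)
  expect_equal(percent_diff(9.5, 10), -5.0)
  expect_error(percent_diff(10, 0), "positive")

  expect_equal(percent_bias(c(5, -5)), 0)
  expect_equal(percent_bias(c(2, 4)), 3)
  expect_equal(percent_bias(7.3), 7.3)
  expect_error(percent_bias(numeric(0)), "non-empty")

  expect_equal(percent_mad(c(5, 5, 5)), 0)
  expect_equal(percent_mad(c(2, 4)), 1)     # |2-3|, |4-3| averaged
  expect_equal(percent_mad(c(-5, 5)), 5)
  expect_equal(percent_mad(c(2, 4), mode = "raw"), 3)
})

test_that("percent RSE matches an independent lm-based oracle", {
  crit <- c(10, 11, 12, 13)
  dev <- c(9.8, 11.3, 11.9, 13.2)
  expect_equal(percent_rse(crit, dev), oracle_rse(crit, dev))

  # collinear pairs with positive fitted values leave zero residual error
  expect_equal(percent_rse(c(8, 9, 10, 11), 1.02 * c(8, 9, 10, 11)), 0)
  expect_error(percent_rse(c(10, 11), c(10, 11)), "insufficient data")
})

test_that("MDC95 is 1.96*sqrt(2) times the percent SEM", {
  expect_equal(mdc95(0), 0)
  expect_equal(mdc95(1), 1.96 * sqrt(2))
  expect_equal(mdc95(1), 2.77186, tolerance = 1e-5)
  a <- runif(10, 0, 10)
  expect_equal(mdc95(a) / a, rep(1.96 * sqrt(2), 10))   # exact ratio always
  expect_error(mdc95(-1), "non-negative")
})

test_that("identical device and criterion values zero out every metric", {
  x <- c(8.1, 9.4, 7.7, 10.2, 8.8)
  d <- percent_diff(x, x)
  expect_equal(percent_bias(d), 0)
  expect_equal(percent_mad(d), 0)
  expect_equal(percent_rse(x, x), 0)
  expect_equal(mdc95(percent_rse(x, x)), 0)
})

test_that("bias and MAD transform predictably under scaling and shifts", {
  set.seed(8)
  crit <- runif(12, 7, 10)
  dev <- crit * (1 + rnorm(12, 0, 0.02))
  b0 <- percent_bias(percent_diff(dev, crit))
  # multiplying every device value by (1 + c) shifts %Bias by exactly 100c
  expect_equal(percent_bias(percent_diff(dev * 1.03, crit)), b0 + 3 + 0.03 * b0)
  # %MAD ignores a constant added to all percent differences
  d <- percent_diff(dev, crit)
  expect_equal(percent_mad(d + 2.5), percent_mad(d))
})

test_that("BCa bootstrap is reproducible, degenerate-safe and seed-stable", {
  set.seed(14)
  x <- rnorm(25)
  ci1 <- bootstrap_bca(x, mean, n_resamples = 1000, seed = 99)
  ci2 <- bootstrap_bca(x, mean, n_resamples = 1000, seed = 99)
  expect_identical(ci1, ci2)                            # bit-reproducible
  expect_true(ci1[1] <= attr(ci1, "t0") && attr(ci1, "t0") <= ci1[2])

  expect_warning(ci0 <- bootstrap_bca(rep(2, 10), mean, n_resamples = 200),
                 "degenerate")
  expect_equal(unname(ci0[1]), unname(ci0[2]))
  expect_equal(unname(ci0[1]), 2)

  # across seeds the endpoints move by much less than the interval width
  cis <- sapply(1:20, function(s) bootstrap_bca(x, mean, n_resamples = 5000,
                                                seed = s)[1:2])
  width <- mean(cis[2, ] - cis[1, ])
  expect_lt(sd(cis[1, ]), 0.1 * width)
  expect_lt(sd(cis[2, ]), 0.1 * width)
})

test_that("practical-significance classification handles all band relations", {
  expect_equal(classify_practical(-1, 2), "within")
  expect_equal(classify_practical(3, 7), "overlapping")
  expect_equal(classify_practical(6, 9), "outside")
  expect_equal(classify_practical(1, 4, band = "nonnegative"), "within")
  expect_equal(classify_practical(-2, 1, band = "nonnegative"), "overlapping")
  expect_error(classify_practical(3, 1), "lo")
})

test_that("the agreement report assembles metrics, intervals and flags", {
  set.seed(21)
  crit <- runif(16, 7, 10)
  pairs <- rbind(
    data.frame(parameter = "MSS", method = "time_velocity",
               unit_id = sprintf("u%02d", 1:16), criterion = crit,
               device = crit * (1 + rnorm(16, 0.01, 0.015))),
    data.frame(parameter = "TAU", method = "time_velocity",
               unit_id = sprintf("u%02d", 1:16), criterion = crit / 7,
               device = crit / 7 * (1 + rnorm(16, 0, 0.08)))
  )
  rep <- agreement_report(pairs, n_resamples = 500, seed = 4)
  expect_s3_class(rep, "agreement_report")
  expect_equal(nrow(rep), 6L)  # 2 parameters x 3 metrics
  expect_true(all(rep$ci_lo <= rep$estimate & rep$estimate <= rep$ci_hi))
  expect_true(all(rep$practical %in% c("within", "overlapping", "outside")))
  expect_true(all(rep$n == 16L))
  # mdc95 row equals 1.96*sqrt(2) times the group's rse by construction
  mss <- pairs[pairs$parameter == "MSS", ]
  expect_equal(rep$estimate[rep$parameter == "MSS" & rep$metric == "mdc95_pct"],
               mdc95(percent_rse(mss$criterion, mss$device)))

  # identical seeds give identical reports; skipping the bootstrap gives NAs
  rep2 <- agreement_report(pairs, n_resamples = 500, seed = 4)
  expect_identical(rep, rep2)
  rep0 <- agreement_report(pairs, n_resamples = 0)
  expect_true(all(is.na(rep0$ci_lo)))
})

test_that("paired-estimates CSV round-trips", {
  pairs <- data.frame(parameter = "MSS", method = "time_velocity",
                      unit_id = c("a", "b", "c"),
                      criterion = c(9, 8.5, 9.4), device = c(9.1, 8.4, 9.5))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(pairs, path, row.names = FALSE)
  back <- read_pairs_csv(path)
  expect_equal(back$criterion, pairs$criterion)
  expect_error(read_pairs_csv(withr::local_tempfile(lines = "a,b\n1,2",
                                                    fileext = ".csv")),
               "columns")
})
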