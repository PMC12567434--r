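test_that("samplers reproduce the closed-form moments of each family", {
  m <- 1e5
  rect <- sample_distribution(list(family = "rectangular", a = 0, b = 1),
                              m, seed = 101)
  # sd of sd estimate ~ sd / sqrt(2m); allow 3 standard errors
  expect_equal(sd(rect), 1 / sqrt(12), tolerance = 3 / sqrt(2 * m) * 1.5)
  expect_true(all(rect >= 0 & rect <= 1))

  tri <- sample_distribution(list(family = "triangular", a = 0, b = 1),
                             m, seed = 102)
  expect_equal(sd(tri), 1 / sqrt(24), tolerance = 3 / sqrt(2 * m) * 1.5)
  expect_equal(mean(tri), 0.5, tolerance = 3 / sqrt(24 * m) * 3)
  expect_true(all(tri >= 0 & tri <= 1))

  norm <- sample_distribution(list(family = "normal", mean = 1, sd = 5e-4),
                              m, seed = 103)
  expect_equal(mean(norm), 1, tolerance = 3 * 5e-4 / sqrt(m))

  expect_equal(sample_distribution(list(family = "normal", mean = 2, sd = 0),
                                   10, seed = 1), rep(2, 10))
  expect_error(sample_distribution(list(family = "cauchy", a = 0, b = 1), 10),
               "family")
  expect_error(sample_distribution(list(family = "normal", mean = 0, sd = 1), 0),
               ">= 1")
})

test_that("propagation is deterministic per seed and seed-sensitive", {
  y1 <- mcs_propagate(mpz, m = 5e3, seed = 7)
  y2 <- mcs_propagate(mpz, m = 5e3, seed = 7)
  expect_identical(as.numeric(y1), as.numeric(y2))
  s1 <- mcs_summarize(y1)
  s2 <- mcs_summarize(mcs_propagate(mpz, m = 5e3, seed = 7))
  expect_identical(glance(s1), glance(s2))

  y3 <- mcs_propagate(mpz, m = 5e3, seed = 8)
  expect_false(identical(as.numeric(y1), as.numeric(y3)))
  # different seeds agree to Monte Carlo error of the mean
  expect_equal(mean(y1), mean(y3), tolerance = 6 * sd(y1) / sqrt(5e3) / mean(y1))
})

test_that("quantities without distribution assignments stay at nominal", {
  b <- mpz
  b$distributions <- b$distributions[b$distributions$symbol == "At", ]
  y <- mcs_propagate(b, m = 2000, seed = 9)
  # only the test-area term varies: content sd ~ its tiny relative u
  expect_equal(sd(y) / mean(y), 3.12e-5, tolerance = 0.1)

  none <- mpz
  none$distributions <- none$distributions[0, ]
  expect_error(mcs_propagate(none, m = 10), "no distributions")
})

test_that("relative-effect factors sampled on their own scale enter as multipliers", {
  # Cx is drawn as N(0.2 mg/mL, 0.0004) and must contribute rel sd 0.002
  b <- mpz
  b$distributions <- b$distributions[b$distributions$symbol == "Cx", ]
  y <- mcs_propagate(b, m = 2e4, seed = 10)
  expect_equal(sd(y) / mean(y), 0.002, tolerance = 0.05)
  expect_equal(mean(y), evaluate_content(mpz), tolerance = 1e-4)
})

test_that("summary statistics, interval and empirical k behave as expected", {
  z <- withr::with_seed(12, rnorm(2e5))
  s <- mcs_summarize(z)
  expect_equal(s$interval[["lower"]], -1.96, tolerance = 0.02)
  expect_equal(s$interval[["upper"]], 1.96, tolerance = 0.02)
  expect_equal(s$k, 1.96, tolerance = 0.02)
  expect_lt(s$interval[["lower"]], s$mean)
  expect_gt(s$interval[["upper"]], s$mean)
  expect_equal(s$U, diff(s$interval) / 2, ignore_attr = TRUE)

  # perfectly symmetric sample has zero skewness
  sym <- c(z[1:1000], -z[1:1000])
  expect_equal(mcs_summarize(sym)$skewness, 0, tolerance = 1e-12)

  # wider coverage nests the narrower interval
  s99 <- mcs_summarize(z, coverage = 0.99)
  expect_gt(diff(s99$interval), diff(s$interval))

  expect_warning(s_small <- mcs_summarize(z[1:100]), "refused")
  expect_true(is.na(s_small$U))
  expect_false(is.na(s_small$mean))
})

test_that("fixture propagation agrees with the GUM combination to first order", {
  g <- gum_uncertainty(mpz)
  y <- mcs_propagate(mpz, m = 2e5, seed = 13)
  s <- mcs_summarize(y)
  expect_gt(s$sd / g$u, 0.97)
  expect_lt(s$sd / g$u, 1.03)
  expect_equal(s$mean, g$content, tolerance = 1e-4)
  # near-normal output: empirical coverage factor close to 1.96
  expect_gt(s$k, 1.93)
  expect_lt(s$k, 1.99)
})

test_that("convergence study reports stabilizing interval widths", {
  conv <- mcs_convergence(mpz, m_list = c(5e3, 2e4, 8e4), seed = 14)
  expect_named(conv, c("m", "width", "rel_change", "stable"))
  expect_true(is.na(conv$rel_change[1]))
  expect_true(all(conv$width > 0))
  expect_lt(conv$rel_change[3], 0.05)
  expect_error(mcs_convergence(mpz, m_list = c(10, 10)), "ascending")

  single <- mcs_convergence(mpz, m_list = 5e3, seed = 15)
  expect_equal(nrow(single), 1)
  expect_true(is.na(single$rel_change))
  expect_false(single$stable)
})

test_that("shortest-interval option never exceeds the percentile width", {
  y <- mcs_propagate(mpz, m = 2e4, seed = 16)
  pct <- mcs_summarize(y)
  short <- mcs_summarize(y, method = "shortest")
  expect_lte(diff(short$interval), diff(pct$interval) * (1 + 1e-12))
})

test_that("MCS report writes the summary and histogram CSVs", {
  y <- mcs_propagate(mpz, m = 5e3, seed = 17)
  s <- mcs_summarize(y)
  dir <- withr::local_tempdir()
  write_mcs_report(s, file.path(dir, "mcs.csv"), samples = y,
                   histogram_path = file.path(dir, "hist.csv"))
  stats <- readr::read_csv(file.path(dir, "mcs.csv"), show_col_types = FALSE)
  expect_true(all(c("mean", "sd", "k") %in% stats$statistic))
  h <- readr::read_csv(file.path(dir, "hist.csv"), show_col_types = FALSE)
  expect_named(h, c("bin_left", "bin_right", "count"))
  expect_equal(sum(h$count), 5e3)
})
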