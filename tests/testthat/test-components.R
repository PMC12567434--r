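test_that("Type A uncertainty is the standard deviation of the mean", {
  rt <- type_a_uncertainty(sd = 0.003807, m = 6)
  expect_equal(rt$u, 0.0015542, tolerance = 1e-5)
  expect_equal(rt$dof, 5L)
  area <- type_a_uncertainty(sd = 0.001568, m = 6)
  expect_equal(area$u, 0.00064013, tolerance = 1e-5)
  expect_equal(type_a_uncertainty(rep(3.2, 5))$u, 0)
  expect_error(type_a_uncertainty(c(1)), "2 observations")
  expect_error(type_a_uncertainty(sd = 0.1, m = 1), "m >= 2")
})

test_that("rectangular and triangular conversions match the sqrt(3)/sqrt(6) divisors", {
  expect_equal(rectangular_u(0.0001), 0.000058, tolerance = 1e-3)
  expect_equal(rectangular_u(0.02), 0.0115, tolerance = 5e-3)
  expect_equal(rectangular_u(0), 0)
  expect_equal(triangular_u(0.1), 0.04082, tolerance = 1e-3)
  expect_equal(triangular_u(0.04), 0.01633, tolerance = 1e-3)
  expect_equal(triangular_u(0.015), 0.00612, tolerance = 1e-3)
  expect_error(rectangular_u(-1), ">= 0")
  expect_error(triangular_u(-1), ">= 0")
})

test_that("rectangular exceeds triangular and both are linear in the half-width", {
  a <- withr::with_seed(3, runif(20, 1e-6, 10))
  expect_true(all(rectangular_u(a) > triangular_u(a)))
  expect_equal(rectangular_u(3 * a), 3 * rectangular_u(a))
  expect_equal(triangular_u(3 * a), 3 * triangular_u(a))
})

test_that("temperature-induced volume variation uses V * dT * alpha, rectangular", {
  t100 <- temperature_volume_u(100)
  expect_equal(t100$half_width, 0.084)
  expect_equal(t100$u, 0.04850, tolerance = 1e-4)
  t25 <- temperature_volume_u(25)
  expect_equal(t25$half_width, 0.021)
  expect_equal(t25$u, 0.01212, tolerance = 1e-3)
  t0 <- temperature_volume_u(10, delta_t = 0)
  expect_equal(t0$half_width, 0)
  expect_equal(t0$u, 0)
})

glassware <- tibble::tibble(
  instrument = c("2 mL pipette", "5 mL pipette", "25 mL flask", "100 mL flask"),
  volume = c(2, 5, 25, 100),
  tolerance = c(0.01, 0.015, 0.04, 0.1)
)

test_that("volumetric budget combines calibration and temperature in quadrature", {
  vb <- volume_budget(glassware)
  expect_equal(vb$u_volume, c(0.0042, 0.00659, 0.02034, 0.06339),
               tolerance = 1e-3)
  expect_equal(vb$u_rel[vb$volume == 2], 0.0021, tolerance = 1e-3)
  # no temperature effect: combined reduces to the calibration term
  flat <- volume_budget(glassware, delta_t = 0)
  expect_equal(flat$u_volume, flat$u_cal)
  # commutative and monotone in each component
  expect_equal(sqrt(0.004082^2 + 0.00097^2), sqrt(0.00097^2 + 0.004082^2))
  hotter <- volume_budget(glassware, delta_t = 8)
  expect_true(all(hotter$u_volume > vb$u_volume))
})

test_that("dilution relative uncertainty is the quadrature over instruments", {
  expect_equal(dilution_relative_u(volume_budget(glassware)), 0.002683,
               tolerance = 1e-3)
  expect_equal(dilution_relative_u(c(0.0021, 0.001318, 0.0008136, 0.0006339)),
               0.002683, tolerance = 1e-3)
  expect_equal(dilution_relative_u(0.005), 0.005)
  expect_equal(dilution_relative_u(c(0.003, 0.003)), 0.003 * sqrt(2))
  expect_error(dilution_relative_u(numeric()), "at least one")
})

test_that("calibration fit recovers exact lines and the design sum-of-squares", {
  pts <- tidyr::crossing(concentration = c(0.12, 0.16, 0.20, 0.24, 0.28),
                         rep = 1:3) |>
    dplyr::mutate(response = 2 * concentration)
  fit <- fit_calibration(pts)
  expect_equal(fit$a1, 2, tolerance = 1e-12)
  expect_equal(fit$a0, 0, tolerance = 1e-12)
  expect_equal(fit$s_res, 0, tolerance = 1e-9)
  expect_equal(fit$n, 15)
  expect_equal(fit$c_bar, 0.2)
  # SSDx = 3 * sum((level - 0.2)^2) = 3 * 0.016 = 0.048
  expect_equal(fit$ssd_x, 0.048, tolerance = 1e-12)

  expect_error(fit_calibration(pts[1:2, ]), "3 points")
  same <- tibble::tibble(concentration = rep(0.2, 5), response = 1:5)
  expect_error(fit_calibration(same), "singular")
})

test_that("residual sd estimates the noise sd (simulation oracle)", {
  d <- synthetic_design(sigma = 0.3)
  ratios <- withr::with_seed(21, purrr::map_dbl(1:300, function(i) {
    fit_calibration(simulate_calibration(d))$s_res / d$sigma
  }))
  expect_gt(mean(ratios), 0.9)
  expect_lt(mean(ratios), 1.1)
})

test_that("inverse-prediction uncertainty reproduces the worked budget value", {
  reg <- list(a1 = 1, s_res = 8.136e-4, n = 15, c_bar = 0.2, ssd_x = 0.048)
  expect_equal(prediction_u(reg, p = 6, cx = 0.2005), 0.000393,
               tolerance = 1e-3)
  reg0 <- modifyList(reg, list(s_res = 0))
  expect_equal(prediction_u(reg0, p = 6, cx = 0.2005), 0)
  expect_error(prediction_u(reg, p = 0, cx = 0.2), ">= 1")
})

test_that("prediction uncertainty is convex in cx and decreasing in p and n", {
  reg <- list(a1 = 350, s_res = 0.285, n = 15, c_bar = 0.2, ssd_x = 0.048)
  cx <- seq(0.12, 0.28, by = 0.01)
  u <- prediction_u(reg, p = 6, cx = cx)
  expect_equal(cx[which.min(u)], 0.2)
  expect_true(all(diff(u[cx >= 0.2]) > 0))
  expect_lt(prediction_u(reg, p = 6, cx = 0.25),
            prediction_u(reg, p = 1, cx = 0.25))
  reg_bigger_n <- modifyList(reg, list(n = 30))
  expect_lt(prediction_u(reg_bigger_n, p = 6, cx = 0.25),
            prediction_u(reg, p = 6, cx = 0.25))
})

test_that("pooled repeatability follows ANOVA pooling and SR = Sr/sqrt(n)", {
  flat <- tidyr::crossing(run = 1:3, replicate = 1:6) |>
    dplyr::mutate(value = 99.7)
  r <- pooled_repeatability(flat)
  expect_equal(r$s_r, 0)
  expect_equal(r$u, 0)
  expect_equal(r$n_total, 18)
  expect_equal(r$dof, 15)

  one_run <- dplyr::filter(flat, run == 1)
  expect_error(pooled_repeatability(one_run), "2 runs")

  # dof-weighted pooling equals the root mean of run variances for a
  # balanced design; check against a hand-computed two-run case
  d <- tibble::tibble(run = rep(1:2, each = 3),
                      value = c(1, 2, 3, 10, 12, 14))
  r2 <- pooled_repeatability(d)
  expect_equal(r2$s_r, sqrt((var(c(1, 2, 3)) + var(c(10, 12, 14))) / 2))
  expect_equal(r2$u, r2$s_r / sqrt(6))
})

test_that("pooled Sr recovers the true within-run sd (simulation oracle)", {
  d <- synthetic_design()
  ratios <- withr::with_seed(31, purrr::map_dbl(1:200, function(i) {
    pooled_repeatability(simulate_repeatability(d))$s_r / d$rep_sd
  }))
  expect_gt(mean(ratios), 0.9)
  expect_lt(mean(ratios), 1.1)
})

test_that("SST statistics summarize each channel against its CV criterion", {
  sst <- tibble::tibble(
    injection = 1:6,
    retention_time = series_with_sd(6, 3.808, 0.003807, seed = 5),
    area = series_with_sd(6, 70.509, 0.001568, seed = 6)
  )
  s <- sst_statistics(sst)
  expect_setequal(s$channel, c("retention_time", "area"))
  rt <- s[s$channel == "retention_time", ]
  expect_equal(rt$sd_of_mean, 0.0015542, tolerance = 1e-4)
  expect_equal(rt$cv_pct, 100 * 0.003807 / mean(sst$retention_time),
               tolerance = 1e-6)
  expect_equal(s$sd_of_mean[s$channel == "area"], 0.00064013, tolerance = 1e-4)
  expect_true(all(s$pass))

  const <- tibble::tibble(injection = 1:6, retention_time = rep(4, 6),
                          area = rep(70, 6))
  sc <- sst_statistics(const)
  expect_equal(sc$cv_pct, c(0, 0))
  expect_true(all(sc$pass))

  noisy <- tibble::tibble(injection = 1:6,
                          area = series_with_sd(6, 70, 70 * 0.05, seed = 7))
  expect_false(sst_statistics(noisy)$pass)
})

test_that("raw-data CSV readers validate required columns", {
  dir <- withr::local_tempdir()
  paths <- simulate_study_dir(synthetic_design(), dir, seed = 4)
  expect_named(read_calibration_csv(paths[["calibration"]]),
               c("concentration", "response"))
  expect_named(read_repeatability_csv(paths[["repeatability"]]),
               c("run", "replicate", "value"))
  expect_named(read_sst_csv(paths[["sst"]]),
               c("injection", "retention_time", "area"))
  bad <- file.path(dir, "bad.csv")
  readr::write_csv(tibble::tibble(x = 1), bad)
  expect_error(read_calibration_csv(bad), "concentration")
})
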