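#' Type A standard uncertainty: standard deviation of the mean
#'
#' For `m` repeated observations the Type A standard uncertainty of their
#' mean is \eqn{s/\sqrt{m}} with `m - 1` degrees of freedom.
#'
#' @param x Numeric vector of repeated observations, or `NULL` if `sd` and
#'   `m` are supplied directly (as when working from a published table).
#' @param sd Sample standard deviation (used with `m` when `x` is absent).
#' @param m Number of observations.
#' @return A one-row tibble: `mean` (`NA` when only `sd`/`m` are given),
#'   `sd`, `m`, `u` (= sd/sqrt(m)) and `dof` (= m - 1).
#' @export
#' @examples
#' type_a_uncertainty(sd = 0.003807, m = 6)  # u = 0.0015542
type_a_uncertainty <- function(x = NULL, sd = NULL, m = NULL) {
  if (!is.null(x)) {
    m <- length(x)
    if (m < 2) abort("Type A evaluation needs at least 2 observations.")
    sd <- stats::sd(x)
    mean_x <- mean(x)
  } else {
    if (is.null(sd) || is.null(m)) {
      abort("Provide observations `x`, or both `sd` and `m`.")
    }
    if (m < 2) abort("Type A evaluation needs m >= 2.")
    mean_x <- NA_real_
  }
  tibble::tibble(mean = mean_x, sd = sd, m = as.integer(m),
                 u = sd / sqrt(m), dof = as.integer(m) - 1L)
}

#' Type B conversions: rectangular and triangular half-widths
#'
#' Convert a bounded tolerance half-width into a standard uncertainty:
#' rectangular (uniform) distributions divide by \eqn{\sqrt 3}, triangular
#' by \eqn{\sqrt 6}. Rectangular is the conservative choice when only
#' limits are known; triangular suits manufacturer tolerances where values
#' near nominal are most likely.
#'
#' @param half_width Non-negative half-width of the bounded interval, in the
#'   quantity's unit.
#' @return Standard uncertainty in the same unit.
#' @export
#' @examples
#' rectangular_u(0.0001)  # purity certificate, 0.000058
#' triangular_u(0.1)      # 100 mL flask tolerance, 0.04082
rectangular_u <- function(half_width) {
  if (any(half_width < 0)) abort("`half_width` must be >= 0.")
  half_width / sqrt(3)
}

#' @rdname rectangular_u
#' @export
triangular_u <- function(half_width) {
  if (any(half_width < 0)) abort("`half_width` must be >= 0.")
  half_width / sqrt(6)
}

#' Temperature effect on a delivered volume
#'
#' The mismatch between the glassware calibration temperature and the
#' working temperature changes the delivered liquid volume by up to
#' \eqn{V \Delta T \alpha} (liquid expansion dominates over glass). The
#' variation over the temperature range is treated as rectangular.
#'
#' @param volume Nominal volume (mL), > 0.
#' @param delta_t Half-range of the working-temperature deviation (degrees
#'   C), >= 0. Default 4 (lab at 20 +/- 4 deg C against 20 deg C calibration).
#' @param alpha Volume expansion coefficient of the liquid (per deg C);
#'   default 2.1e-4 for aqueous solutions.
#' @return A one-row tibble with `half_width` (= V dT alpha, mL) and `u`
#'   (= half_width / sqrt(3), mL).
#' @export
#' @examples
#' temperature_volume_u(100)  # half-width 0.084 mL, u 0.04850 mL
temperature_volume_u <- function(volume, delta_t = 4, alpha = 2.1e-4) {
  if (any(volume <= 0)) abort("`volume` must be > 0.")
  if (any(delta_t < 0)) abort("`delta_t` must be >= 0.")
  if (any(alpha <= 0)) abort("`alpha` must be > 0.")
  hw <- volume * delta_t * alpha
  tibble::tibble(half_width = hw, u = rectangular_u(hw))
}

#' Volumetric glassware uncertainty budget
#'
#' Builds the per-instrument volume uncertainty table from calibration
#' tolerances (triangular) and temperature effects (rectangular), combining
#' the two in quadrature, and the combined relative uncertainty of the
#' whole dilution train (quadrature over instruments).
#'
#' @param data A data frame with one row per instrument and columns
#'   `volume` (nominal, mL) and `tolerance` (calibration half-width, mL);
#'   any extra columns (e.g. `instrument`) are carried through.
#' @param delta_t,alpha Passed to [temperature_volume_u()].
#' @return `volume_budget()`: the input tibble with `u_cal`, `temp_half_width`,
#'   `u_temp`, `u_volume` (quadrature) and `u_rel` (= u_volume / volume)
#'   appended. `dilution_relative_u()`: a single number,
#'   \eqn{\sqrt{\sum u_{rel,i}^2}}.
#' @export
#' @examples
#' glassware <- tibble::tibble(
#'   instrument = c("2 mL pipette", "5 mL pipette", "25 mL flask", "100 mL flask"),
#'   volume = c(2, 5, 25, 100),
#'   tolerance = c(0.01, 0.015, 0.04, 0.1)
#' )
#' vb <- volume_budget(glassware)
#' dilution_relative_u(vb)  # 0.002683
volume_budget <- function(data, delta_t = 4, alpha = 2.1e-4) {
  stopifnot(all(c("volume", "tolerance") %in% names(data)))
  temp <- temperature_volume_u(data$volume, delta_t, alpha)
  data |>
    tibble::as_tibble() |>
    dplyr::mutate(
      u_cal = triangular_u(.data$tolerance),
      temp_half_width = temp$half_width,
      u_temp = temp$u,
      u_volume = sqrt(.data$u_cal^2 + .data$u_temp^2),
      u_rel = .data$u_volume / .data$volume
    )
}

#' @rdname volume_budget
#' @param x For `dilution_relative_u()`: a `volume_budget()` tibble (its
#'   `u_rel` column is used) or a bare numeric vector of relative
#'   uncertainties.
#' @export
dilution_relative_u <- function(x) {
  rel <- if (is.data.frame(x)) x$u_rel else x
  if (length(rel) < 1) abort("Need at least one relative uncertainty.")
  sqrt(sum(rel^2))
}

#' Fit an ordinary least-squares calibration line
#'
#' Fits `response = a0 + a1 * concentration` by unweighted OLS and returns
#' the regression statistics the inverse-prediction uncertainty formula
#' needs: residual standard deviation \eqn{S_{res}} (on `n - 2` degrees of
#' freedom), the mean calibration concentration, and the concentration
#' sum-of-squares \eqn{SSD_x = \sum (c_i - \bar c)^2}.
#'
#' @param data Data frame of calibration points.
#' @param concentration,response Column names (unquoted) holding the
#'   concentrations (mg/mL) and instrument responses.
#' @return A `mu_calibration` object with fields `a0`, `a1`, `s_res`, `n`,
#'   `c_bar`, `ssd_x`, `r_squared` and the point data.
#' @export
#' @examples
#' pts <- tidyr::crossing(concentration = c(0.12, 0.16, 0.20, 0.24, 0.28),
#'                        rep = 1:3)
#' pts$response <- 350 * pts$concentration
#' fit <- fit_calibration(pts)
#' fit$ssd_x  # 0.048
fit_calibration <- function(data, concentration = concentration,
                            response = response) {
  conc <- dplyr::pull(data, {{ concentration }})
  resp <- dplyr::pull(data, {{ response }})
  n <- length(conc)
  if (n < 3) abort("Calibration needs at least 3 points.")
  if (length(unique(conc)) < 2) {
    abort("Calibration design is singular: all concentrations identical.")
  }
  fit <- stats::lm(resp ~ conc)
  a0 <- unname(coef(fit)[1])
  a1 <- unname(coef(fit)[2])
  s_res <- sqrt(sum(residuals(fit)^2) / (n - 2))
  c_bar <- mean(conc)
  ssd_x <- sum((conc - c_bar)^2)
  ss_tot <- sum((resp - mean(resp))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  structure(
    list(a0 = a0, a1 = a1, s_res = s_res, n = n, c_bar = c_bar,
         ssd_x = ssd_x, r_squared = r2,
         data = tibble::tibble(concentration = conc, response = resp)),
    class = "mu_calibration"
  )
}

#' @export
print.mu_calibration <- function(x, ...) {
  cat(sprintf("<mu_calibration> n = %d points\n", x$n))
  cat(sprintf("  response = %.5g + %.5g * c;  Sres = %.5g;  c_bar = %.4g;  SSDx = %.4g\n",
              x$a0, x$a1, x$s_res, x$c_bar, x$ssd_x))
  invisible(x)
}

#' Inverse-prediction standard uncertainty of a calibrated concentration
#'
#' Standard uncertainty of a concentration predicted from the calibration
#' line using the mean of `p` replicate responses:
#' \deqn{u(C_x) = \frac{S_{res}}{a_1}\sqrt{\frac 1 p + \frac 1 n +
#'   \frac{(C_x - \bar c)^2}{SSD_x}}.}
#' It is minimal at the calibration centroid \eqn{\bar c} and decreases with
#' both `p` and `n`.
#'
#' @param reg A `mu_calibration` object (or a list with `a1`, `s_res`, `n`,
#'   `c_bar`, `ssd_x`).
#' @param p Number of replicate sample measurements (>= 1).
#' @param cx Predicted concentration (mg/mL).
#' @return Standard uncertainty of `cx`, in mg/mL.
#' @export
prediction_u <- function(reg, p, cx) {
  if (any(p < 1)) abort("`p` must be >= 1.")
  (reg$s_res / reg$a1) *
    sqrt(1 / p + 1 / reg$n + (cx - reg$c_bar)^2 / reg$ssd_x)
}

#' Pooled repeatability of the analytical procedure
#'
#' Pools the within-run standard deviation over independent analytical runs
#' (dof-weighted root-mean-square of run variances, i.e. one-way ANOVA
#' pooling) and converts it to the standard uncertainty of the procedure
#' mean, \eqn{S_R = S_r / \sqrt{n}} with `n` the divisor count (all
#' `n_total` measurements by default).
#'
#' @param data Data frame of replicate determinations.
#' @param run,value Column names (unquoted): run identifier and measured
#'   content.
#' @param m Divisor count for the standard uncertainty of the mean; default
#'   `NULL` uses the total number of measurements.
#' @return A `mu_repeatability` object: `s_r` (pooled within-run sd),
#'   `n_total`, `n_runs`, `u` (= s_r / sqrt(m)), `dof` (= n_total - runs)
#'   and the per-run summary tibble.
#' @export
pooled_repeatability <- function(data, run = run, value = value, m = NULL) {
  runs <- dplyr::pull(data, {{ run }})
  vals <- dplyr::pull(data, {{ value }})
  per_run <- tibble::tibble(run = runs, value = vals) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     var = var(.data$value), .groups = "drop")
  if (nrow(per_run) < 2) {
    abort("Pooled repeatability needs at least 2 runs.")
  }
  if (any(per_run$n < 2)) {
    abort("Every run needs at least 2 replicates.")
  }
  dof <- sum(per_run$n - 1)
  s_r <- sqrt(sum((per_run$n - 1) * per_run$var) / dof)
  n_total <- sum(per_run$n)
  m <- m %||% n_total
  structure(
    list(s_r = s_r, n_total = n_total, n_runs = nrow(per_run),
         m = m, u = s_r / sqrt(m), dof = dof, runs = per_run),
    class = "mu_repeatability"
  )
}

#' @export
print.mu_repeatability <- function(x, ...) {
  cat(sprintf("<mu_repeatability> %d runs x %g replicates (n = %d)\n",
              x$n_runs, x$n_total / x$n_runs, x$n_total))
  cat(sprintf("  Sr = %.5g;  SR = Sr/sqrt(%d) = %.5g;  dof = %d\n",
              x$s_r, x$m, x$u, x$dof))
  invisible(x)
}

#' System suitability test statistics
#'
#' Summarizes a replicate-injection series per channel (retention time,
#' peak area): mean, standard deviation, percent coefficient of variation,
#' and the Type A standard deviation of the mean; each channel is checked
#' against its CV acceptance criterion (defaults: retention time < 1.0%,
#' area < 2.0%).
#'
#' @param data Data frame with one row per injection and one numeric column
#'   per channel (e.g. `retention_time`, `area`); an `injection` column, if
#'   present, is ignored.
#' @param criteria Named numeric vector of CV limits in percent, by channel.
#' @return A tibble: `channel`, `n`, `mean`, `sd`, `cv_pct`, `sd_of_mean`,
#'   `cv_limit`, `pass`.
#' @export
#' @examples
#' sst <- tibble::tibble(retention_time = rep(3.808, 6) + c(0, 1, -1, 2, -2, 0) * 1e-3,
#'                       area = rep(70.509, 6))
#' sst_statistics(sst)
sst_statistics <- function(data,
                           criteria = c(retention_time = 1.0, area = 2.0)) {
  channels <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                      "injection")
  if (length(channels) == 0) abort("No numeric channel columns found.")
  if (nrow(data) < 2) abort("SST series needs at least 2 injections.")
  purrr::map(channels, function(ch) {
    v <- data[[ch]]
    tibble::tibble(
      channel = ch, n = length(v), mean = mean(v), sd = stats::sd(v),
      cv_pct = 100 * stats::sd(v) / mean(v),
      sd_of_mean = stats::sd(v) / sqrt(length(v)),
      cv_limit = unname(criteria[ch])
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(pass = is.na(.data$cv_limit) | .data$cv_pct < .data$cv_limit)
}

#' Read raw-data CSV files
#'
#' Plain-CSV readers for the three raw-data layouts the evaluators consume:
#' calibration points (`concentration`, `response`), repeatability matrices
#' (`run`, `replicate`, `value`) and system-suitability series
#' (`injection`, `retention_time`, `area`). Header row required; decimal
#' point; UTF-8.
#'
#' @param path CSV file path.
#' @return A tibble with the validated columns.
#' @export
read_calibration_csv <- function(path) {
  read_checked_csv(path, c("concentration", "response"))
}

#' @rdname read_calibration_csv
#' @export
read_repeatability_csv <- function(path) {
  read_checked_csv(path, c("run", "replicate", "value"))
}

#' @rdname read_calibration_csv
#' @export
read_sst_csv <- function(path) {
  read_checked_csv(path, c("injection", "retention_time", "area"))
}

read_checked_csv <- function(path, required) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s.",
                  path, paste(missing, collapse = ", ")))
  }
  out
}
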