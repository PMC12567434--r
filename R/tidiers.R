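#' Tidy uncertainty results
#'
#' Broom-style methods. `tidy()` returns the per-component (or per-statistic)
#' table of a result; `glance()` returns a one-row summary.
#'
#' @param x A `mu_gum`, `mu_mcs`, `mu_validation`, `mu_calibration` or
#'   `mu_repeatability` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.mu_gum <- function(x, ...) {
  x$contributions
}

#' @rdname tidiers
#' @export
glance.mu_gum <- function(x, ...) {
  tibble::tibble(
    content = x$content, u_rel = x$u_rel, u = x$u, k = x$k, U = x$U,
    lower = x$interval[["lower"]], upper = x$interval[["upper"]],
    nu_eff = x$nu_eff %||% NA_real_, n_components = nrow(x$contributions)
  )
}

#' @rdname tidiers
#' @export
tidy.mu_mcs <- function(x, ...) {
  tibble::tibble(
    statistic = c("mean", "median", "sd", "skewness", "U", "k",
                  "interval_lower", "interval_upper"),
    value = c(x$mean, x$median, x$sd, x$skewness, x$U, x$k,
              x$interval[["lower"]], x$interval[["upper"]])
  )
}

#' @rdname tidiers
#' @export
glance.mu_mcs <- function(x, ...) {
  tibble::tibble(
    m = x$m, mean = x$mean, median = x$median, sd = x$sd,
    skewness = x$skewness, coverage = x$coverage,
    lower = x$interval[["lower"]], upper = x$interval[["upper"]],
    U = x$U, k = x$k
  )
}

#' @rdname tidiers
#' @export
tidy.mu_validation <- function(x, ...) {
  tibble::tibble(
    y = x$y, U = x$U,
    gum_lower = x$gum_interval[["lower"]], gum_upper = x$gum_interval[["upper"]],
    mcs_lower = x$mcs_interval[["lower"]], mcs_upper = x$mcs_interval[["upper"]],
    d_low = x$d_low, d_high = x$d_high,
    delta = x$delta, mantissa = x$c, exponent = x$l,
    validated = x$validated
  )
}

#' @rdname tidiers
#' @export
glance.mu_validation <- function(x, ...) {
  tibble::tibble(delta = x$delta, d_low = x$d_low, d_high = x$d_high,
                 validated = x$validated)
}

#' @rdname tidiers
#' @export
tidy.mu_calibration <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$a0, x$a1))
}

#' @rdname tidiers
#' @export
glance.mu_calibration <- function(x, ...) {
  tibble::tibble(a0 = x$a0, a1 = x$a1, s_res = x$s_res, n = x$n,
                 c_bar = x$c_bar, ssd_x = x$ssd_x, r_squared = x$r_squared)
}

#' @rdname tidiers
#' @export
tidy.mu_repeatability <- function(x, ...) {
  x$runs
}

#' @rdname tidiers
#' @export
glance.mu_repeatability <- function(x, ...) {
  tibble::tibble(s_r = x$s_r, u = x$u, n_total = x$n_total,
                 n_runs = x$n_runs, dof = x$dof)
}
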