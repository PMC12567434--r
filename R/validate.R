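#' Numerical validation tolerance for the GUM-vs-MCS comparison
#'
#' Writes the combined standard uncertainty as \eqn{u = c \cdot 10^l} with
#' `c` an integer of one or two significant digits (round half away from
#' zero), and returns the Supplement 1 numerical tolerance
#' \eqn{\delta = 0.5 \cdot 10^l}. The tolerance jumps an order of magnitude
#' at mantissa-digit boundaries, so the digit count is an explicit choice.
#'
#' @param u Combined standard uncertainty (> 0).
#' @param digits Significant digits of the mantissa, 1 or 2.
#' @return A list: `delta`, `c` (integer mantissa), `l` (integer exponent).
#' @export
#' @examples
#' validation_tolerance(0.3426)             # c = 3, l = -1, delta = 0.05
#' validation_tolerance(0.3426, digits = 2) # c = 34, l = -2, delta = 0.005
validation_tolerance <- function(u, digits = 1) {
  if (u <= 0) abort("`u` must be > 0.")
  if (!digits %in% c(1, 2)) abort("`digits` must be 1 or 2.")
  l <- floor(log10(u)) - (digits - 1)
  c_m <- round_half_away(u / 10^l)
  # rounding can carry (e.g. 0.96 -> 10 at 1 digit): renormalize
  if (c_m >= 10^digits) {
    l <- l + 1
    c_m <- round_half_away(u / 10^l)
  }
  list(delta = 0.5 * 10^l, c = as.integer(c_m), l = as.integer(l))
}

round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Validate a GUM coverage interval against a Monte Carlo interval
#'
#' Supplement 1 tolerance test: the GUM interval endpoints
#' \eqn{L_{low} = y - U}, \eqn{L_{high} = y + U} are compared with the
#' Monte Carlo coverage interval endpoints; the GUM result is validated
#' when both absolute endpoint differences
#' \eqn{d_{low} = |L_{low} - y_{low}|}, \eqn{d_{high} = |L_{high} - y_{high}|}
#' fall below the tolerance \eqn{\delta} (see [validation_tolerance()]).
#'
#' @param y Measurand estimate (GUM content value).
#' @param U Expanded uncertainty (>= 0).
#' @param mcs_interval Length-2 numeric, the Monte Carlo coverage interval
#'   (lower, upper), ordered.
#' @param u Combined standard uncertainty used to set the tolerance;
#'   default `U / k`.
#' @param k Coverage factor used for the default `u` (default 2).
#' @param digits Mantissa digits for the tolerance (1 or 2).
#' @param delta Override the tolerance directly (skips
#'   [validation_tolerance()]).
#' @return A `mu_validation` object: `delta`, `c`, `l`, `gum_interval`,
#'   `mcs_interval`, `d_low`, `d_high`, `validated`.
#' @export
#' @examples
#' v <- validate_intervals(99.41, 0.6853, c(98.7623, 100.0679), u = 0.3426)
#' v$d_low      # 0.0376
#' v$validated
validate_intervals <- function(y, U, mcs_interval, u = NULL, k = 2,
                               digits = 1, delta = NULL) {
  if (U < 0) abort("`U` must be >= 0.")
  if (length(mcs_interval) != 2 || mcs_interval[1] > mcs_interval[2]) {
    abort("`mcs_interval` must be an ordered (lower, upper) pair.")
  }
  if (is.null(delta)) {
    tol <- validation_tolerance(u %||% (U / k), digits = digits)
  } else {
    tol <- list(delta = delta, c = NA_integer_, l = NA_integer_)
  }
  gum_interval <- c(lower = y - U, upper = y + U)
  d_low <- abs(gum_interval[["lower"]] - mcs_interval[1])
  d_high <- abs(gum_interval[["upper"]] - mcs_interval[2])
  structure(
    list(delta = tol$delta, c = tol$c, l = tol$l,
         y = y, U = U,
         gum_interval = gum_interval,
         mcs_interval = c(lower = mcs_interval[1], upper = mcs_interval[2]),
         d_low = d_low, d_high = d_high,
         validated = d_low < tol$delta && d_high < tol$delta),
    class = "mu_validation"
  )
}

#' @export
print.mu_validation <- function(x, digits = 6, ...) {
  cat("<mu_validation> GUM vs MCS coverage-interval comparison\n")
  cat(sprintf("  GUM  [%s, %s]  (y = %s, U = %s)\n",
              signif(x$gum_interval[["lower"]], digits),
              signif(x$gum_interval[["upper"]], digits),
              signif(x$y, digits), signif(x$U, 4)))
  cat(sprintf("  MCS  [%s, %s]\n",
              signif(x$mcs_interval[["lower"]], digits),
              signif(x$mcs_interval[["upper"]], digits)))
  cat(sprintf("  d_low = %.4f, d_high = %.4f, delta = %g -> %s\n",
              x$d_low, x$d_high, x$delta,
              if (x$validated) "VALIDATED" else "NOT validated"))
  invisible(x)
}

#' Write the validation comparison report
#'
#' One-row CSV with the GUM and MCS endpoints, both endpoint differences,
#' the tolerance, its mantissa/exponent decomposition, and the verdict.
#'
#' @param result A `mu_validation` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(result, path) {
  stopifnot(inherits(result, "mu_validation"))
  readr::write_csv(tidy(result), path)
  invisible(path)
}
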