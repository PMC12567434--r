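#' Combine an uncertainty budget by the GUM law of propagation
#'
#' For a pure product/quotient content model the law of propagation of
#' uncertainty reduces to quadrature of relative standard uncertainties:
#' \deqn{\frac{u(C)}{C} = \sqrt{\sum_i \left(\frac{u(x_i)}{x_i}\right)^2},}
#' from which the combined standard uncertainty \eqn{u(C)}, the expanded
#' uncertainty \eqn{U = k\,u(C)} and the coverage interval
#' \eqn{[C - U,\ C + U]} follow. Per-quantity contribution shares are
#' variance shares, \eqn{r_i^2 / \sum r_j^2}, reported in Pareto order.
#'
#' @param budget A `mu_budget` object.
#' @param content Content value (%) to scale the relative uncertainty by.
#'   Default `NULL` evaluates the model at nominal values. Supply a value to
#'   reproduce a published budget whose content was reported separately.
#' @param k Coverage factor; default 2 (approximately 95% coverage for a
#'   normal measurand). Ignored when `welch = TRUE`.
#' @param welch If `TRUE`, derives `k` from the two-tailed Student t at the
#'   Welch--Satterthwaite effective degrees of freedom instead of using the
#'   fixed `k` (see [welch_satterthwaite()]).
#' @param level Coverage probability used when `welch = TRUE` (default 0.95).
#' @return A `mu_gum` object: `content`, `u_rel`, `u` (= u_rel * content),
#'   `k`, `U`, `interval`, `contributions` (tibble in Pareto order:
#'   `symbol`, `value`, `u`, `u_rel`, `share`, `cumulative_share`),
#'   `nu_eff` (when `welch = TRUE`).
#' @export
#' @examples
#' b <- mpz_budget()
#' g <- gum_uncertainty(b, content = b$reference$reported_content_pct)
#' g$u   # 0.3426
#' g$U   # 0.6852
gum_uncertainty <- function(budget, content = NULL, k = 2, welch = FALSE,
                            level = 0.95) {
  q <- budget$quantities
  if (nrow(q) == 0) abort("The budget has no quantities to combine.")
  if (any(!is.finite(q$u_rel))) {
    abort("Every quantity needs a finite relative uncertainty.")
  }
  content <- content %||% evaluate_content(budget)
  u_rel <- sqrt(sum(q$u_rel^2))
  nu_eff <- NULL
  if (welch) {
    ws <- welch_satterthwaite(q$u_rel, q$dof, level = level)
    nu_eff <- ws$nu_eff
    k <- ws$k
  }
  if (k <= 0) abort("`k` must be > 0.")
  u <- u_rel * content
  U <- expanded_uncertainty(u, k)
  contributions <- q |>
    dplyr::transmute(.data$symbol, .data$value, .data$u, .data$u_rel,
                     share = .data$u_rel^2 / sum(.data$u_rel^2)) |>
    dplyr::arrange(dplyr::desc(.data$share)) |>
    dplyr::mutate(cumulative_share = cumsum(.data$share))
  structure(
    list(content = content, u_rel = u_rel, u = u, k = k, U = U,
         interval = c(lower = content - U, upper = content + U),
         contributions = contributions, nu_eff = nu_eff,
         budget_name = budget$name),
    class = "mu_gum"
  )
}

#' Expanded uncertainty
#'
#' Scales a combined standard uncertainty by a coverage factor:
#' \eqn{U = k\,u}. With `k = 2` the interval covers roughly 95% for a
#' normal measurand; `k = 3` roughly 99.7%.
#'
#' @param u Combined standard uncertainty (>= 0).
#' @param k Coverage factor (> 0); default 2.
#' @return `k * u`.
#' @export
expanded_uncertainty <- function(u, k = 2) {
  if (any(u < 0)) abort("`u` must be >= 0.")
  if (any(k <= 0)) abort("`k` must be > 0.")
  k * u
}

#' Welch--Satterthwaite effective degrees of freedom
#'
#' \deqn{\nu_{eff} = \frac{u^4(y)}{\sum_i u_i^4(y)/\nu_i},}
#' where components with infinite degrees of freedom contribute nothing to
#' the denominator. The coverage factor is the two-tailed Student-t
#' quantile at `level` on `floor(nu_eff)` degrees of freedom; when every
#' component has infinite dof, the normal quantile (1.95996 at 95%) is
#' returned.
#'
#' @param u Component uncertainties (any common scale: absolute
#'   contributions or relative uncertainties of a product model).
#' @param dof Degrees of freedom per component (may be `Inf`).
#' @param level Coverage probability (default 0.95).
#' @return A list with `nu_eff` and `k`.
#' @export
#' @examples
#' welch_satterthwaite(c(1, 1), c(17, 17))  # nu_eff = 34
welch_satterthwaite <- function(u, dof, level = 0.95) {
  stopifnot(length(u) == length(dof))
  if (any(u < 0)) abort("Component uncertainties must be >= 0.")
  if (any(is.finite(dof) & dof < 1)) abort("Finite dof must be >= 1.")
  u_c <- sqrt(sum(u^2))
  denom <- sum(ifelse(is.finite(dof), u^4 / dof, 0))
  p <- 1 - (1 - level) / 2
  if (denom == 0) {
    return(list(nu_eff = Inf, k = qnorm(p)))
  }
  nu_eff <- u_c^4 / denom
  list(nu_eff = nu_eff, k = qt(p, df = floor(nu_eff)))
}

#' Numerical sensitivity-coefficient propagation (first-order oracle)
#'
#' Propagates the budget through the general first-order law
#' \eqn{u^2(y) = \sum_i c_i^2 u^2(x_i)} with sensitivity coefficients
#' \eqn{c_i = \partial C / \partial x_i} estimated by central finite
#' differences. For product/quotient models this agrees with the relative
#' quadrature of [gum_uncertainty()] to first order; it serves as an
#' independent check of the closed-form path and extends to non-product
#' models.
#'
#' Relative-effect factors (nominal value 1) are perturbed around 1 with
#' absolute uncertainty equal to their relative uncertainty.
#'
#' @param budget A `mu_budget` object.
#' @param step Relative finite-difference step (default 1e-6 of each
#'   nominal value).
#' @param f Optional model function taking a named list of quantity values
#'   and returning the measurand; defaults to the budget's product model.
#'   Lets the same propagation path be applied to non-product measurement
#'   equations.
#' @return A list: `u` (combined standard uncertainty on the computed
#'   content scale), `content`, and `sensitivities` (tibble: `symbol`,
#'   `c_i`, `u_i`, `contribution = c_i * u_i`).
#' @export
propagate_numeric <- function(budget, step = 1e-6, f = NULL) {
  q <- budget$quantities
  nominal <- as.list(setNames(q$value, q$symbol))
  f <- f %||% function(values) eval_product_model(budget$model, values)
  content <- f(nominal)
  if (!is.finite(content)) abort("Model value is not finite at the nominal point.")
  sens <- purrr::map(seq_len(nrow(q)), function(i) {
    sym <- q$symbol[i]
    x0 <- q$value[i]
    h <- step * abs(x0)
    up <- f(modifyList(nominal, setNames(list(x0 + h), sym)))
    dn <- f(modifyList(nominal, setNames(list(x0 - h), sym)))
    if (!is.finite(up) || !is.finite(dn)) {
      abort(sprintf("Model is not finite near the nominal value of `%s`.", sym))
    }
    c_i <- (up - dn) / (2 * h)
    u_i <- q$u[i]
    tibble::tibble(symbol = sym, c_i = c_i, u_i = u_i,
                   contribution = c_i * u_i)
  }) |> purrr::list_rbind()
  list(u = sqrt(sum(sens$contribution^2)), content = content,
       sensitivities = sens)
}

#' @export
print.mu_gum <- function(x, digits = 4, ...) {
  cat(format_gum_summary(x, digits = digits), sep = "\n")
  invisible(x)
}

#' Format / write a GUM budget report
#'
#' `format_gum_summary()` renders the standard one-line result statement
#' plus the combined-uncertainty details; `write_gum_report()` writes the
#' Pareto-ordered contribution table as CSV (`symbol`, `value`, `u`,
#' `u_rel`, `share`, `cumulative_share`) with the summary lines as a
#' sidecar `.txt`.
#'
#' @param result A `mu_gum` object.
#' @param digits Significant digits for the text summary.
#' @param path Output CSV path; the text summary goes to
#'   `sub("\\.csv$", ".txt", path)`.
#' @return `format_gum_summary()`: a character vector of lines.
#'   `write_gum_report()`: `path`, invisibly.
#' @export
format_gum_summary <- function(result, digits = 4) {
  c(
    sprintf("C = (%s ± %s)%% (k = %s)",
            signif(result$content, digits + 2), signif(result$U, 2),
            signif(result$k, digits)),
    sprintf("combined standard uncertainty u(C) = %s%% (relative %s)",
            signif(result$u, digits), signif(result$u_rel, digits)),
    sprintf("expanded uncertainty U = %s%%; interval [%s, %s]",
            signif(result$U, digits),
            signif(result$interval[["lower"]], digits + 2),
            signif(result$interval[["upper"]], digits + 2)),
    if (!is.null(result$nu_eff)) {
      sprintf("effective dof (Welch-Satterthwaite) = %s", signif(result$nu_eff, digits))
    }
  )
}

#' @rdname format_gum_summary
#' @export
write_gum_report <- function(result, path) {
  stopifnot(inherits(result, "mu_gum"))
  readr::write_csv(result$contributions, path)
  writeLines(format_gum_summary(result), sub("\\.csv$", ".txt", path))
  invisible(path)
}
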