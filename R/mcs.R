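# Run code with a locally-scoped RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Draw samples from an input-quantity distribution
#'
#' Samples the three distribution families used for Type A/B input
#' quantities: `normal(mean, sd)`, `rectangular` (uniform on `[a, b]`),
#' and symmetric `triangular` on `[a, b]`, generated as
#' \eqn{a + (b - a)/2\,(U_1 + U_2)} with independent standard uniforms.
#'
#' @param spec A distribution specification: a list or one-row data frame
#'   with `family` and either `mean`/`sd` or `a`/`b`.
#' @param m Number of draws (>= 1).
#' @param seed Optional integer seed (locally scoped).
#' @return Numeric vector of `m` draws.
#' @export
#' @examples
#' x <- sample_distribution(list(family = "triangular", a = 0, b = 1), 1e4, seed = 1)
#' sd(x)  # ~ 1/sqrt(24) = 0.2041
sample_distribution <- function(spec, m, seed = NULL) {
  if (m < 1) abort("`m` must be >= 1.")
  local_seed(seed, {
    switch(spec$family,
      normal = rnorm(m, mean = spec$mean, sd = spec$sd),
      rectangular = spec$a + (spec$b - spec$a) * runif(m),
      triangular = spec$a + (spec$b - spec$a) / 2 * (runif(m) + runif(m)),
      abort(sprintf("Unknown distribution family `%s`.", spec$family))
    )
  })
}

#' Monte Carlo propagation of the uncertainty budget
#'
#' Propagates the budget's probability distributions through the content
#' model by Monte Carlo simulation (distribution propagation, as in GUM
#' Supplement 1): every distribution component is sampled independently,
#' a quantity's per-trial value is its nominal value perturbed by the sum
#' of its components' relative deviations from their centers
#' \eqn{x = x_0 (1 + \sum_c (z_c - \mu_c)/\mu_c)}, and the model is
#' evaluated per trial. For a quantity with a single component centered at
#' its nominal value this reduces to using the draw directly; for
#' relative-effect factors whose distribution lives on another scale (a
#' predicted concentration in mg/mL, say) it converts the draw to the
#' dimensionless multiplier \eqn{z/\mu}. Quantities with no distribution
#' stay fixed at nominal.
#'
#' @param budget A `mu_budget` object with a non-empty `distributions`
#'   table.
#' @param m Number of Monte Carlo trials (default 1e6).
#' @param seed Integer seed; a fixed seed makes the run bit-reproducible.
#' @return Numeric vector of `m` simulated content values, with attributes
#'   `m` and `seed`. Summarize with [mcs_summarize()].
#' @seealso [mcs_summarize()], [mcs_convergence()]
#' @export
#' @examples
#' b <- mpz_budget()
#' y <- mcs_propagate(b, m = 1e4, seed = 42)
#' mcs_summarize(y)
mcs_propagate <- function(budget, m = 1e6, seed = NULL) {
  d <- budget$distributions
  if (nrow(d) == 0) {
    abort("The budget assigns no distributions; nothing to propagate.")
  }
  q <- budget$quantities
  modeled <- unique(c(budget$model$numerator, budget$model$denominator,
                      budget$model$factors))
  values <- local_seed(seed, {
    purrr::map(modeled, function(sym) {
      nominal <- q$value[q$symbol == sym]
      rows <- d[d$symbol == sym, ]
      if (nrow(rows) == 0) return(rep(nominal, m))
      rel_dev <- 0
      for (i in seq_len(nrow(rows))) {
        draw <- sample_distribution(rows[i, ], m)
        rel_dev <- rel_dev + (draw - rows$center[i]) / rows$center[i]
      }
      nominal * (1 + rel_dev)
    }) |> setNames(modeled)
  })
  samples <- eval_product_model(budget$model, values)
  attr(samples, "m") <- m
  attr(samples, "seed") <- seed
  samples
}

#' Summarize a Monte Carlo output distribution
#'
#' Computes the sample statistics of the simulated measurand: mean, median,
#' standard uncertainty (sample sd), skewness (third standardized central
#' moment), the equal-tailed coverage interval at the requested probability,
#' the expanded uncertainty `U` (half the interval width) and the empirical
#' coverage factor `k = U / sd`. A shortest-interval option is available
#' for asymmetric outputs.
#'
#' With fewer than 1000 samples the interval estimate is refused (a
#' warning) and only the moments are returned.
#'
#' @param samples Numeric vector of simulated measurand values (e.g. from
#'   [mcs_propagate()]).
#' @param coverage Coverage probability (default 0.95).
#' @param method `"percentile"` (equal-tailed, default) or `"shortest"`.
#' @return A `mu_mcs` object: `m`, `seed`, `mean`, `median`, `sd`,
#'   `skewness`, `coverage`, `interval` (`lower`, `upper`), `U`, `k`.
#' @export
mcs_summarize <- function(samples, coverage = 0.95,
                          method = c("percentile", "shortest")) {
  method <- match.arg(method)
  m <- length(samples)
  mu <- mean(samples)
  s <- stats::sd(samples)
  skew <- if (s > 0) mean((samples - mu)^3) / s^3 else 0
  out <- list(
    m = m, seed = attr(samples, "seed"),
    mean = mu, median = median(samples), sd = s, skewness = skew,
    coverage = coverage,
    interval = c(lower = NA_real_, upper = NA_real_),
    U = NA_real_, k = NA_real_, method = method
  )
  if (m < 1000) {
    warn(sprintf(
      "Only %d samples: coverage-interval estimate refused, moments only.", m))
  } else {
    ci <- if (method == "percentile") {
      alpha <- (1 - coverage) / 2
      unname(quantile(samples, c(alpha, 1 - alpha)))
    } else {
      shortest_interval(samples, coverage)
    }
    out$interval <- c(lower = ci[1], upper = ci[2])
    out$U <- (ci[2] - ci[1]) / 2
    out$k <- if (s > 0) out$U / s else NA_real_
  }
  structure(out, class = "mu_mcs")
}

shortest_interval <- function(samples, coverage) {
  x <- sort(samples)
  n <- length(x)
  w <- ceiling(coverage * n)
  if (w >= n) return(c(x[1], x[n]))
  widths <- x[(w + 1):n] - x[1:(n - w)]
  i <- which.min(widths)
  c(x[i], x[i + w])
}

#' @export
print.mu_mcs <- function(x, digits = 6, ...) {
  cat(sprintf("<mu_mcs> M = %d trials%s\n", x$m,
              if (!is.null(x$seed)) sprintf(" (seed %s)", x$seed) else ""))
  cat(sprintf("  mean %s, median %s, sd %s, skewness %.4f\n",
              signif(x$mean, digits), signif(x$median, digits),
              signif(x$sd, 4), x$skewness))
  if (!is.na(x$U)) {
    cat(sprintf("  %g%% interval [%s, %s]; U = %s; k = %.4f\n",
                100 * x$coverage, signif(x$interval[["lower"]], digits),
                signif(x$interval[["upper"]], digits), signif(x$U, 4), x$k))
  } else {
    cat("  (interval refused: fewer than 1000 samples)\n")
  }
  invisible(x)
}

#' Monte Carlo convergence study
#'
#' Reruns the propagation at increasing trial counts and tracks the
#' stabilization of the coverage-interval width: the relative change of
#' the width between successive trial counts, flagged stable when below
#' `tol`.
#'
#' @param budget A `mu_budget` object.
#' @param m_list Ascending vector of trial counts.
#' @param seed Integer base seed; run `i` uses `seed + i - 1`.
#' @param coverage Coverage probability (default 0.95).
#' @param tol Stability tolerance on the relative width change (default
#'   0.001, i.e. 0.1%).
#' @return A tibble: `m`, `width`, `rel_change` (`NA` for the first row),
#'   `stable`.
#' @export
mcs_convergence <- function(budget, m_list, seed = NULL, coverage = 0.95,
                            tol = 0.001) {
  if (is.unsorted(m_list, strictly = TRUE)) {
    abort("`m_list` must be strictly ascending.")
  }
  widths <- purrr::map_dbl(seq_along(m_list), function(i) {
    y <- mcs_propagate(budget, m = m_list[i],
                       seed = if (!is.null(seed)) seed + i - 1)
    s <- mcs_summarize(y, coverage = coverage)
    diff(s$interval)
  })
  rel_change <- c(NA_real_, abs(diff(widths)) /
                    ifelse(head(widths, -1) > 0, head(widths, -1), NA_real_))
  tibble::tibble(
    m = m_list, width = widths, rel_change = rel_change,
    stable = !is.na(rel_change) & rel_change < tol
  )
}

#' Write a Monte Carlo report
#'
#' Writes the summary-statistics table (parameter/value CSV) and,
#' optionally, a binned histogram of the samples
#' (`bin_left`, `bin_right`, `count`).
#'
#' @param result A `mu_mcs` object.
#' @param path Output CSV path.
#' @param samples Optional sample vector for the histogram export.
#' @param histogram_path Optional CSV path for the binned histogram.
#' @param bins Number of histogram bins (default 100).
#' @return `path`, invisibly.
#' @export
write_mcs_report <- function(result, path, samples = NULL,
                             histogram_path = NULL, bins = 100) {
  stopifnot(inherits(result, "mu_mcs"))
  readr::write_csv(tidy(result), path)
  if (!is.null(histogram_path) && !is.null(samples)) {
    h <- graphics::hist(samples, breaks = bins, plot = FALSE)
    readr::write_csv(tibble::tibble(
      bin_left = head(h$breaks, -1), bin_right = h$breaks[-1],
      count = h$counts
    ), histogram_path)
  }
  invisible(path)
}
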