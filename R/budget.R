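#' Load an uncertainty budget configuration
#'
#' Reads a budget configuration (JSON or YAML) describing a product-form
#' content model, its input quantities and, optionally, the probability
#' distributions assigned to each quantity for Monte Carlo propagation.
#'
#' A budget file has three required blocks:
#' \describe{
#'   \item{`model`}{`numerator` / `denominator` symbol lists, `factors`
#'     (dimensionless multipliers such as purity or relative-effect terms)
#'     and `constants` (exact scalars, e.g. a dose-ratio and a `scale` of
#'     100 for percent).}
#'   \item{`quantities`}{one entry per symbol with `value`, `unit`, either
#'     `standard_uncertainty` or `relative_uncertainty`, and `dof`
#'     (degrees of freedom; `"inf"` for Type B components).}
#'   \item{`distributions`}{zero or more named components per symbol, each
#'     a `normal` (`mean`, `sd`), `rectangular` or `triangular` (`a`, `b`)
#'     specification.}
#' }
#'
#' The loader validates the schema and cross-checks each quantity's declared
#' standard uncertainty against the uncertainty implied by its distribution
#' components (quadrature over components, within 3% relative).
#'
#' @param path Path to a `.json` or `.yaml`/`.yml` budget file.
#' @param text Alternatively, the configuration as a single JSON/YAML string.
#' @param format `"json"` or `"yaml"`; guessed from the file extension (or
#'   leading character of `text`) by default.
#'
#' @return An object of class `mu_budget`: a list with `quantities` (tibble:
#'   `symbol`, `description`, `value`, `unit`, `u`, `u_rel`, `dof`,
#'   `relative`), `model`, `distributions` (tibble: `symbol`, `component`,
#'   `family`, `mean`, `sd`, `a`, `b`, `center`, `u_implied`), `reference`
#'   (untouched metadata block, may be `NULL`) and `name`.
#' @seealso [mpz_budget()] for the packaged Metopimazine fixture,
#'   [evaluate_content()], [gum_uncertainty()], [mcs_propagate()].
#' @export
#' @examples
#' b <- mpz_budget()
#' b$quantities
#' evaluate_content(b)
load_budget <- function(path = NULL, text = NULL, format = NULL) {
  if (is.null(path) && is.null(text)) {
    abort("Provide either `path` or `text`.")
  }
  if (is.null(format)) {
    format <- if (!is.null(path)) {
      if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "json"
    } else {
      if (grepl("^\\s*\\{", text)) "json" else "yaml"
    }
  }
  raw <- if (format == "json") {
    jsonlite::fromJSON(text %||% path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else {
    if (!is.null(path)) yaml::read_yaml(path) else yaml::yaml.load(text)
  }
  parse_budget(raw, source = path %||% "<text>")
}

#' The packaged Metopimazine HPLC-UV budget fixture
#'
#' Loads the uncertainty budget for the HPLC-UV assay of Metopimazine (MPZ)
#' content in an injectable solution: 11 input quantities (peak areas,
#' reference mass, four dilution volumes, specimen volume, purity, and the
#' repeatability and calibration-prediction relative-effect factors) with
#' their standard uncertainties, plus the 16 probability-distribution
#' components used for Monte Carlo propagation.
#'
#' The fixture's `reference` block carries the published summary values
#' (content 99.41%, combined u 0.3426%, Monte Carlo statistics) as
#' metadata. Note that the product model evaluated at nominal values yields
#' 99.700%, not the published 99.41%; [evaluate_content()] reports the
#' computed value and the reference block preserves the published one.
#'
#' @return A `mu_budget` object.
#' @export
mpz_budget <- function() {
  load_budget(system.file("extdata", "mpz_budget.json", package = "mubudget",
                          mustWork = TRUE))
}

dist_center <- function(family, mean, a, b) {
  ifelse(family == "normal", mean, (a + b) / 2)
}

dist_implied_u <- function(family, sd, a, b) {
  dplyr::case_when(
    family == "normal"      ~ sd,
    family == "rectangular" ~ (b - a) / (2 * sqrt(3)),
    family == "triangular"  ~ (b - a) / (2 * sqrt(6))
  )
}

parse_budget <- function(raw, source = "<list>") {
  for (block in c("model", "quantities")) {
    if (is.null(raw[[block]])) {
      abort(sprintf("Budget config is missing the `%s` block (%s).", block, source))
    }
  }
  model <- raw$model
  model$numerator   <- as.character(model$numerator %||% character())
  model$denominator <- as.character(model$denominator %||% character())
  model$factors     <- as.character(model$factors %||% character())
  model$constants   <- lapply(model$constants %||% list(), as.numeric)

  if (length(raw$quantities) == 0) {
    abort(sprintf("Budget config declares no quantities (%s).", source))
  }

  q <- purrr::imap(raw$quantities, function(entry, sym) {
    val <- entry$value
    if (is.null(val) || !is.numeric(val) || !is.finite(val)) {
      abort(sprintf("quantities.%s: `value` must be a finite number.", sym))
    }
    if (val <= 0) {
      abort(sprintf("quantities.%s: `value` must be > 0 for a product model.", sym))
    }
    u <- entry$standard_uncertainty
    rel <- entry$relative_uncertainty
    if (is.null(u) && is.null(rel)) {
      abort(sprintf("quantities.%s: need `standard_uncertainty` or `relative_uncertainty`.", sym))
    }
    relative_effect <- sym %in% model$factors && val == 1 && !is.null(rel)
    if (!is.null(u) && !is.null(rel) && !relative_effect) {
      if (abs(rel - u / val) > 1e-6 * abs(rel)) {
        abort(sprintf(
          "quantities.%s: relative_uncertainty (%g) inconsistent with standard_uncertainty/value (%g).",
          sym, rel, u / val))
      }
    }
    if (is.null(u)) u <- rel * val
    if (is.null(rel)) rel <- u / val
    dof <- entry$dof %||% Inf
    if (identical(dof, "inf") || identical(dof, "Inf")) dof <- Inf
    dof <- as.numeric(dof)
    if (is.finite(dof) && dof < 1) {
      abort(sprintf("quantities.%s: finite `dof` must be >= 1.", sym))
    }
    tibble::tibble(
      symbol = sym,
      description = entry$description %||% NA_character_,
      value = val,
      unit = entry$unit %||% NA_character_,
      u = u,
      u_rel = rel,
      dof = dof,
      relative = relative_effect
    )
  }) |> purrr::list_rbind()

  referenced <- unique(c(model$numerator, model$denominator, model$factors))
  missing <- setdiff(referenced, q$symbol)
  if (length(missing) > 0) {
    abort(sprintf("Model references undefined quantity symbol(s): %s.",
                  paste(missing, collapse = ", ")))
  }

  d <- parse_distributions(raw$distributions %||% list(), q)

  structure(
    list(
      name = raw$name %||% NA_character_,
      description = raw$description %||% NA_character_,
      model = model,
      quantities = q,
      distributions = d,
      reference = raw$reference,
      source = source
    ),
    class = "mu_budget"
  )
}

parse_distributions <- function(dists, quantities) {
  if (length(dists) == 0) {
    return(tibble::tibble(
      symbol = character(), component = character(), family = character(),
      mean = double(), sd = double(), a = double(), b = double(),
      center = double(), u_implied = double()
    ))
  }
  d <- purrr::imap(dists, function(components, sym) {
    purrr::imap(components, function(spec, comp) {
      fam <- spec$family
      if (is.null(fam) || !fam %in% c("normal", "rectangular", "triangular")) {
        abort(sprintf("distributions.%s.%s: unknown family `%s`.",
                      sym, comp, fam %||% "<missing>"))
      }
      if (fam == "normal") {
        if (is.null(spec$mean) || is.null(spec$sd)) {
          abort(sprintf("distributions.%s.%s: normal needs `mean` and `sd`.", sym, comp))
        }
        if (spec$sd <= 0) {
          abort(sprintf("distributions.%s.%s: `sd` must be > 0.", sym, comp))
        }
      } else {
        if (is.null(spec$a) || is.null(spec$b)) {
          abort(sprintf("distributions.%s.%s: %s needs bounds `a` and `b`.",
                        sym, comp, fam))
        }
        if (spec$a >= spec$b) {
          abort(sprintf("distributions.%s.%s: need a < b (got a = %g, b = %g).",
                        sym, comp, spec$a, spec$b))
        }
      }
      tibble::tibble(
        symbol = sym, component = comp, family = fam,
        mean = spec$mean %||% NA_real_, sd = spec$sd %||% NA_real_,
        a = spec$a %||% NA_real_, b = spec$b %||% NA_real_
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  d <- d |>
    dplyr::mutate(
      center = dist_center(.data$family, .data$mean, .data$a, .data$b),
      u_implied = dist_implied_u(.data$family, .data$sd, .data$a, .data$b)
    )

  unknown <- setdiff(d$symbol, quantities$symbol)
  if (length(unknown) > 0) {
    abort(sprintf("Distributions declared for undefined symbol(s): %s.",
                  paste(unknown, collapse = ", ")))
  }

  # Cross-check: per-symbol implied relative uncertainty (quadrature over
  # components, each relative to its own center) must agree with the declared
  # relative uncertainty within 3%.
  implied <- d |>
    dplyr::group_by(.data$symbol) |>
    dplyr::summarise(rel_implied = sqrt(sum((.data$u_implied / .data$center)^2)),
                     .groups = "drop") |>
    dplyr::left_join(quantities[, c("symbol", "u_rel")], by = "symbol")
  bad <- implied |>
    dplyr::filter(abs(.data$rel_implied - .data$u_rel) > 0.03 * .data$u_rel)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Distribution-implied uncertainty disagrees with the declared value (> 3%%) for: %s.",
      paste(sprintf("%s (implied rel %.3g vs declared %.3g)",
                    bad$symbol, bad$rel_implied, bad$u_rel), collapse = "; ")))
  }
  d
}

#' Serialize a budget back to JSON or YAML
#'
#' Writing then re-loading a budget reproduces the same quantities, model
#' and distribution assignments (round-trip property).
#'
#' @param budget A `mu_budget` object.
#' @param path Output file path; the extension selects the format unless
#'   `format` is given.
#' @param format `"json"` or `"yaml"`.
#' @return `path`, invisibly.
#' @export
write_budget <- function(budget, path, format = NULL) {
  stopifnot(inherits(budget, "mu_budget"))
  if (is.null(format)) {
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "json"
  }
  quantities <- budget$quantities |>
    split(factor(budget$quantities$symbol,
                 levels = unique(budget$quantities$symbol))) |>
    lapply(function(row) {
      out <- list(description = row$description, value = row$value, unit = row$unit)
      if (row$relative) {
        out$relative_uncertainty <- row$u_rel
      } else {
        out$standard_uncertainty <- row$u
      }
      out$dof <- if (is.finite(row$dof)) row$dof else "inf"
      out
    })
  dists <- NULL
  if (nrow(budget$distributions) > 0) {
    dists <- budget$distributions |>
      split(factor(budget$distributions$symbol,
                   levels = unique(budget$distributions$symbol))) |>
      lapply(function(rows) {
        specs <- lapply(seq_len(nrow(rows)), function(i) {
          r <- rows[i, ]
          if (r$family == "normal") {
            list(family = r$family, mean = r$mean, sd = r$sd)
          } else {
            list(family = r$family, a = r$a, b = r$b)
          }
        })
        setNames(specs, rows$component)
      })
  }
  raw <- list(
    name = budget$name, description = budget$description,
    model = budget$model, quantities = quantities,
    distributions = dists, reference = budget$reference
  )
  raw <- raw[!vapply(raw, is.null, logical(1))]
  if (format == "json") {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}

#' @export
print.mu_budget <- function(x, ...) {
  cat(sprintf("<mu_budget> %s\n", x$name))
  cat(sprintf("  %d quantities, %d distribution components\n",
              nrow(x$quantities), nrow(x$distributions)))
  cat(sprintf("  model: (%s) / (%s) * %s * constants(%s)\n",
              paste(x$model$numerator, collapse = " * "),
              paste(x$model$denominator, collapse = " * "),
              paste(x$model$factors, collapse = " * "),
              paste(sprintf("%s = %g", names(x$model$constants),
                            unlist(x$model$constants)), collapse = ", ")))
  print(x$quantities, ...)
  invisible(x)
}
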