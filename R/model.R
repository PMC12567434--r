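#' Evaluate the product-form content model
#'
#' Computes the measurand (drug content, %) as the product of the numerator
#' quantities over the denominator quantities, times the dimensionless
#' factors and the exact scalar constants:
#' \deqn{C = \frac{\prod x_{num}}{\prod x_{den}} \prod x_{fac} \prod const.}
#' For the packaged assay model this is
#' \eqn{(A_t/A_{st})(P_t/V_{t1})(V_p/V_{t2})(V_t/V_{Sample}) \cdot P \cdot
#' \delta_r \cdot C_x \cdot V_{mDose} \cdot 100}.
#'
#' The evaluation is a pure product with no rounding. `overrides` may carry
#' vectors (all of a common length), in which case a vector of contents is
#' returned; this is the evaluation path the Monte Carlo engine uses.
#'
#' @param budget A `mu_budget` object (or anything with `$model` and
#'   `$quantities` in the same shape).
#' @param overrides Optional named list/vector of quantity values replacing
#'   the nominal ones (e.g. `list(At = 70.6)`); names must be model symbols.
#' @return The content, as a numeric scalar (or vector under vectorized
#'   overrides), in the model's output unit (percent for the packaged assay).
#' @export
#' @examples
#' b <- mpz_budget()
#' evaluate_content(b)                      # computed content, %
#' evaluate_content(b, list(At = b$quantities$value[b$quantities$symbol == "Ast"]))
evaluate_content <- function(budget, overrides = NULL) {
  values <- as.list(setNames(budget$quantities$value, budget$quantities$symbol))
  if (!is.null(overrides)) {
    overrides <- as.list(overrides)
    unknown <- setdiff(names(overrides), names(values))
    if (length(unknown) > 0) {
      abort(sprintf("Override(s) for unknown symbol(s): %s.",
                    paste(unknown, collapse = ", ")))
    }
    values[names(overrides)] <- overrides
  }
  eval_product_model(budget$model, values)
}

# Vectorized product-model evaluation over a named list of numeric vectors.
eval_product_model <- function(model, values) {
  get_val <- function(sym) {
    v <- values[[sym]]
    if (is.null(v)) {
      abort(sprintf("Model symbol `%s` has no value.", sym))
    }
    v
  }
  num <- 1
  for (sym in c(model$numerator, model$factors)) num <- num * get_val(sym)
  den <- 1
  for (sym in model$denominator) {
    v <- get_val(sym)
    if (any(v <= 0)) {
      abort(sprintf("Denominator quantity `%s` is zero or negative.", sym))
    }
    den <- den * v
  }
  const <- prod(unlist(model$constants))
  num / den * const
}
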