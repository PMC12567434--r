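# Shared fixtures built in code.

# The packaged assay budget, loaded once per test run.
mpz <- mpz_budget()

# Build a mu_budget from plain lists via the JSON round-trip, so the same
# schema validation applies as for user files.
make_budget <- function(quantities, model, distributions = NULL,
                        name = "test") {
  raw <- list(name = name, model = model, quantities = quantities)
  if (!is.null(distributions)) raw$distributions <- distributions
  load_budget(text = jsonlite::toJSON(raw, auto_unbox = TRUE, digits = NA))
}

# Minimal one-factor budget: y = x with relative uncertainty `rel`.
single_factor_budget <- function(rel = 0.01, value = 1) {
  make_budget(
    quantities = list(x = list(value = value, unit = "1",
                               standard_uncertainty = rel * value)),
    model = list(numerator = list("x"), denominator = list(),
                 factors = list(), constants = list())
  )
}

# A vector of n values with exactly the requested mean and sd.
series_with_sd <- function(n, mean, sd, seed = 99) {
  v <- withr::with_seed(seed, rnorm(n))
  v <- (v - base::mean(v)) / stats::sd(v)
  mean + sd * v
}

# The printed relative standard uncertainties of the assay budget, used as
# an independent hand-quadrature oracle.
mpz_printed_rel <- c(
  delta_r = 0.0005, Cx = 0.002, At = 3.12017e-5, Ast = 3.11112e-5,
  Pt = 0.0001155, Vt1 = 0.0006339, Vt2 = 0.0008136, Vp = 0.001318,
  Vt = 0.0006339, VSample = 0.0021, P = 5.80058e-5
)
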