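#' Run the full uncertainty pipeline
#'
#' One call through the complete analysis: load (or accept) a budget,
#' combine it by GUM propagation, propagate the assigned distributions by
#' Monte Carlo, and validate the GUM coverage interval against the Monte
#' Carlo interval with the Supplement 1 tolerance. Optionally writes the
#' per-stage reports (CSV + text) into `out_dir`.
#'
#' @param budget A `mu_budget` object, or a path to a budget config file.
#' @param m Monte Carlo trials (default 1e6).
#' @param seed Integer seed for the Monte Carlo stage.
#' @param coverage Coverage probability (default 0.95).
#' @param digits Mantissa digits for the validation tolerance (1 or 2).
#' @param content Content value (%) for the GUM stage; default computes it
#'   from the model.
#' @param out_dir Optional output directory for reports.
#' @return A `mu_pipeline` list: `budget`, `gum` (`mu_gum`), `mcs`
#'   (`mu_mcs`), `validation` (`mu_validation`), and `manifest` (tibble of
#'   run parameters and output paths).
#' @export
#' @examples
#' res <- run_pipeline(mpz_budget(), m = 2e4, seed = 7)
#' glance(res$gum)
#' glance(res$validation)
run_pipeline <- function(budget, m = 1e6, seed = NULL, coverage = 0.95,
                         digits = 1, content = NULL, out_dir = NULL) {
  if (is.character(budget)) budget <- load_budget(budget)
  gum <- gum_uncertainty(budget, content = content)
  samples <- mcs_propagate(budget, m = m, seed = seed)
  mcs <- mcs_summarize(samples, coverage = coverage)
  validation <- validate_intervals(
    y = gum$content, U = gum$U,
    mcs_interval = unname(mcs$interval),
    u = gum$u, digits = digits
  )
  paths <- character()
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- c(
      gum = file.path(out_dir, "gum_budget.csv"),
      mcs = file.path(out_dir, "mcs_summary.csv"),
      validation = file.path(out_dir, "validation.csv")
    )
    write_gum_report(gum, paths[["gum"]])
    write_mcs_report(mcs, paths[["mcs"]], samples = samples,
                     histogram_path = file.path(out_dir, "mcs_histogram.csv"))
    write_validation_report(validation, paths[["validation"]])
  }
  manifest <- tibble::tibble(
    budget = budget$name, m = m,
    seed = seed %||% NA_integer_, coverage = coverage, digits = digits,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    version = as.character(utils::packageVersion("mubudget")),
    outputs = paste(paths, collapse = ";")
  )
  structure(
    list(budget = budget, gum = gum, mcs = mcs, validation = validation,
         manifest = manifest),
    class = "mu_pipeline"
  )
}

#' @export
print.mu_pipeline <- function(x, ...) {
  cat("<mu_pipeline>\n\n")
  print(x$gum)
  cat("\n")
  print(x$mcs)
  cat("\n")
  print(x$validation)
  invisible(x)
}
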