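#' Synthetic raw-data study design
#'
#' Defines the raw-data layouts the analysis consumes, with defaults
#' mirroring the assay's validation design: a 5-level calibration from
#' 0.12 to 0.28 mg/mL (60--140% of the 0.2 mg/mL target) with 3
#' replicates per level and homoscedastic normal residuals; a 3-run x
#' 6-replicate repeatability study; and a 6-injection system-suitability
#' series.
#'
#' Default true parameters: slope 350 response units per mg/mL (of the
#' order of the observed peak area 70.5 at 0.2 mg/mL; inverse-prediction
#' uncertainty depends only on the ratio `sigma / slope`), intercept 0,
#' residual sd 0.285 response units (so `sigma/slope` is about 8e-4, the
#' order observed in the assay's calibration). Repeatability defaults to a
#' within-run relative sd of 5e-4 around a content of 99.7%.
#'
#' @param levels Calibration concentration levels (mg/mL).
#' @param reps Replicates per calibration level.
#' @param slope,intercept,sigma True calibration line and residual sd.
#' @param rep_runs,rep_reps Repeatability layout (runs x replicates).
#' @param rep_mean True content (%); `rep_sd` the within-run sd.
#' @param rep_sd Within-run standard deviation of content (%).
#' @param sst_n Injections in the system-suitability series.
#' @param sst_rt_mean,sst_rt_sd,sst_area_mean,sst_area_sd True
#'   retention-time and peak-area means and sds.
#' @return A `mu_design` list of the above fields.
#' @export
synthetic_design <- function(levels = c(0.12, 0.16, 0.20, 0.24, 0.28),
                             reps = 3,
                             slope = 350, intercept = 0, sigma = 0.285,
                             rep_runs = 3, rep_reps = 6,
                             rep_mean = 99.7, rep_sd = 5e-4 * 99.7,
                             sst_n = 6,
                             sst_rt_mean = 3.808, sst_rt_sd = 0.003807,
                             sst_area_mean = 70.509, sst_area_sd = 0.001568) {
  if (any(levels <= 0)) abort("Calibration levels must be > 0.")
  if (sigma < 0 || rep_sd < 0 || sst_rt_sd < 0 || sst_area_sd < 0) {
    abort("Standard deviations must be >= 0.")
  }
  structure(
    list(levels = levels, reps = reps, slope = slope, intercept = intercept,
         sigma = sigma, rep_runs = rep_runs, rep_reps = rep_reps,
         rep_mean = rep_mean, rep_sd = rep_sd, sst_n = sst_n,
         sst_rt_mean = sst_rt_mean, sst_rt_sd = sst_rt_sd,
         sst_area_mean = sst_area_mean, sst_area_sd = sst_area_sd),
    class = "mu_design"
  )
}

#' Generate synthetic raw data
#'
#' Deterministic-per-seed generators for the three raw-data layouts:
#' calibration points (`response = a0 + a1 c + N(0, sigma)`,
#' homoscedastic), a repeatability run x replicate table (normal within-run
#' noise around the true mean), and a system-suitability series. The
#' output tibbles round-trip through the matching `read_*_csv()` readers.
#'
#' @param design A [synthetic_design()] object.
#' @param seed Optional integer seed (locally scoped).
#' @return Tibbles in the reader layouts: `simulate_calibration()` gives
#'   `concentration`, `response`; `simulate_repeatability()` gives `run`,
#'   `replicate`, `value`; `simulate_sst()` gives `injection`,
#'   `retention_time`, `area`.
#' @export
#' @examples
#' d <- synthetic_design(sigma = 0)
#' fit <- fit_calibration(simulate_calibration(d, seed = 1))
#' c(fit$a1, fit$s_res)  # exact slope, zero residual sd
simulate_calibration <- function(design, seed = NULL) {
  conc <- rep(design$levels, each = design$reps)
  local_seed(seed, tibble::tibble(
    concentration = conc,
    response = design$intercept + design$slope * conc +
      rnorm(length(conc), 0, design$sigma)
  ))
}

#' @rdname simulate_calibration
#' @export
simulate_repeatability <- function(design, seed = NULL) {
  local_seed(seed, tidyr::crossing(run = seq_len(design$rep_runs),
                                   replicate = seq_len(design$rep_reps)) |>
    dplyr::mutate(value = design$rep_mean +
                    rnorm(dplyr::n(), 0, design$rep_sd)))
}

#' @rdname simulate_calibration
#' @export
simulate_sst <- function(design, seed = NULL) {
  local_seed(seed, tibble::tibble(
    injection = seq_len(design$sst_n),
    retention_time = rnorm(design$sst_n, design$sst_rt_mean, design$sst_rt_sd),
    area = rnorm(design$sst_n, design$sst_area_mean, design$sst_area_sd)
  ))
}

#' Materialize a complete synthetic study directory
#'
#' Writes `calibration.csv`, `repeatability.csv` and `sst.csv` for one
#' simulated study into `dir`, in the layouts the `read_*_csv()` readers
#' accept.
#'
#' @param design A [synthetic_design()] object.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named character vector of the three file paths, invisibly.
#' @export
simulate_study_dir <- function(design, dir, seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(calibration = file.path(dir, "calibration.csv"),
             repeatability = file.path(dir, "repeatability.csv"),
             sst = file.path(dir, "sst.csv"))
  local_seed(seed, {
    readr::write_csv(simulate_calibration(design), paths[["calibration"]])
    readr::write_csv(simulate_repeatability(design), paths[["repeatability"]])
    readr::write_csv(simulate_sst(design), paths[["sst"]])
  })
  invisible(paths)
}

#' Parameter-recovery check of the inverse-prediction uncertainty
#'
#' Empirically validates the closed-form inverse-prediction uncertainty:
#' repeatedly (i) simulate a calibration set from the design, (ii) fit the
#' line, (iii) simulate `p` replicate responses at the true concentration
#' and invert the fitted line through the mean response,
#' \eqn{\hat C_x = (\bar A - a_0) / a_1}. The empirical sd of the predicted
#' concentrations across repetitions is compared with the closed-form value
#' evaluated at the true parameters.
#'
#' @param design A [synthetic_design()] object.
#' @param p Replicate sample measurements per prediction (default 6).
#' @param cx_true True concentration to predict (default 0.2005 mg/mL).
#' @param repetitions Simulation repetitions (>= 1000 recommended for a
#'   stable ratio; default 2000).
#' @param seed Integer seed.
#' @return A list: `empirical_sd`, `formula_u` (closed form at true
#'   parameters), `ratio` (empirical / formula), `repetitions`.
#' @export
recovery_u_cx <- function(design, p = 6, cx_true = 0.2005,
                          repetitions = 2000, seed = NULL) {
  if (repetitions < 1) abort("`repetitions` must be >= 1.")
  preds <- local_seed(seed, purrr::map_dbl(seq_len(repetitions), function(i) {
    fit <- fit_calibration(simulate_calibration(design))
    resp <- design$intercept + design$slope * cx_true +
      rnorm(p, 0, design$sigma)
    (mean(resp) - fit$a0) / fit$a1
  }))
  n <- length(design$levels) * design$reps
  c_bar <- mean(rep(design$levels, each = design$reps))
  ssd_x <- sum((rep(design$levels, each = design$reps) - c_bar)^2)
  formula_u <- (design$sigma / design$slope) *
    sqrt(1 / p + 1 / n + (cx_true - c_bar)^2 / ssd_x)
  empirical_sd <- stats::sd(preds)
  list(empirical_sd = empirical_sd, formula_u = formula_u,
       ratio = if (formula_u > 0) empirical_sd / formula_u else NA_real_,
       repetitions = repetitions)
}
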