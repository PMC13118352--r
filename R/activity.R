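#' Catalase activity-assay configuration
#'
#' Fixed constants of the spectrophotometric H2O2-decomposition assay:
#' the decrease of absorbance at 240 nm is converted to molar units with
#' the H2O2 extinction coefficient, and to enzyme units (1 U = 1 umol
#' H2O2 decomposed per minute in the cuvette).
#'
#' @param epsilon_h2o2 molar absorptivity of H2O2 at 240 nm
#'   (M^-1 cm^-1); the standard value is 43.6.
#' @param path_cm cuvette path length (cm).
#' @param reaction_volume_L total reaction volume (L); default 2 mL.
#' @param sample_volume_L enzyme sample volume added (L); default 40 uL.
#' @param linear_window_min optional `c(t_lo, t_hi)` (minutes) restricting
#'   the slope fit; `NULL` uses the full trace.
#' @return A list of class `activity_config`.
#' @export
activity_config <- function(epsilon_h2o2 = 43.6, path_cm = 1.0,
                            reaction_volume_L = 2e-3,
                            sample_volume_L = 40e-6,
                            linear_window_min = NULL) {
  .assert(epsilon_h2o2 > 0, "epsilon_h2o2 must be positive",
          "fluorbind_param_error")
  .assert(path_cm > 0 && reaction_volume_L > 0 && sample_volume_L > 0,
          "path and volumes must be positive", "fluorbind_param_error")
  structure(list(epsilon_h2o2 = epsilon_h2o2, path_cm = path_cm,
                 reaction_volume_L = reaction_volume_L,
                 sample_volume_L = sample_volume_L,
                 linear_window_min = linear_window_min),
            class = "activity_config")
}

#' Catalase activity from an A240 kinetic trace
#'
#' Estimates the H2O2 decomposition rate as the OLS slope of A240 versus
#' time over the linear window (expected negative; its magnitude is
#' used), converts it to molar units via Beer-Lambert
#' (`rate_M_per_min = |slope| / (epsilon * path)`), and to enzyme units
#' (`units_U = rate_M_per_min * reaction_volume_L * 1e6`, i.e. umol
#' H2O2 decomposed per minute in the cuvette). A per-mL-of-enzyme-sample
#' value is reported alongside.
#'
#' @param trace a `kinetic_trace` in absorbance units (time in minutes).
#' @param cfg an [activity_config()].
#' @return An object of class `activity_result` with `rate_dA_per_min`,
#'   `rate_M_per_min`, `units_U`, `units_per_mL_sample`, `slope_se` and
#'   the underlying `lm`.
#' @examples
#' tr <- generate_activity_trace(rate_dA_per_min = 0.0436)
#' activity_from_trace(tr)  # 2 U in a 2 mL cuvette
#' @export
activity_from_trace <- function(trace, cfg = activity_config()) {
  .assert(is.data.frame(trace) && all(c("time", "value") %in% names(trace)),
          "trace must have columns time and value", "fluorbind_param_error")
  d <- trace
  if (!is.null(cfg$linear_window_min)) {
    w <- cfg$linear_window_min
    d <- d[d$time >= w[1] & d$time <= w[2], , drop = FALSE]
  }
  .assert(nrow(d) >= 4, "need at least 4 points in the linear window",
          "fluorbind_insufficient_data")
  fit <- stats::lm(value ~ time, data = d)
  slope <- unname(stats::coef(fit)[2])
  se <- .lm_stats(fit)$se_slope
  if (slope > max(2 * se, 1e-12)) {
    warning("A240 increases over the window (slope ", signif(slope, 3),
            "); check assay direction")
  }
  rate_dA <- abs(slope)
  rate_M <- rate_dA / (cfg$epsilon_h2o2 * cfg$path_cm)
  units_U <- rate_M * cfg$reaction_volume_L * 1e6
  structure(list(rate_dA_per_min = rate_dA, rate_M_per_min = rate_M,
                 units_U = units_U,
                 units_per_mL_sample = units_U / (cfg$sample_volume_L * 1e3),
                 slope_se = se, config = cfg, lm = fit),
            class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat("Catalase activity (A240 kinetics)\n")
  cat(sprintf("  rate = %.4g A/min = %.4g M/min\n",
              x$rate_dA_per_min, x$rate_M_per_min))
  cat(sprintf("  %.4g U in cuvette (%.4g U per mL enzyme sample)\n",
              x$units_U, x$units_per_mL_sample))
  invisible(x)
}

#' Normalise values to a control (percent of control)
#'
#' Expresses each value as a percentage of the control entry, the shared
#' normalisation of the spectrophotometric activity assay and of zymogram
#' band-intensity tables (control band = 100 percent).
#'
#' @param values numeric vector (activities or band intensities).
#' @param control_index index of the control entry (default 1); its value
#'   must be positive and maps to exactly 100.
#' @return Numeric vector of percentages, same length and names.
#' @examples
#' percent_of_control(c(1000, 740, 359))  # 100, 74, 35.9
#' @export
percent_of_control <- function(values, control_index = 1) {
  .assert(control_index >= 1 && control_index <= length(values),
          "control_index out of range", "fluorbind_param_error")
  ctrl <- values[control_index]
  .assert(is.finite(ctrl) && ctrl > 0,
          "control value must be positive for normalisation",
          "fluorbind_normalization_error")
  values * 100 / ctrl
}
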