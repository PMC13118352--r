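#' van't Hoff analysis of temperature-dependent association constants
#'
#' Linear regression of `ln Ka` on `1/T`:
#' `ln Ka = -dH/(R T) + dS/R`, so the binding enthalpy is `-R * slope`
#' and the binding entropy `R * intercept` (R = 8.314 J mol^-1 K^-1).
#' The free-energy change at each input temperature is computed by the
#' Gibbs-Helmholtz relation `dG = dH - T dS`, with the direct estimate
#' `-R T ln Ka` from the observed constant reported alongside; a
#' disagreement beyond 0.2 kJ mol^-1 between the two routes is flagged.
#'
#' @param temperature_K absolute temperatures (K); at least 2 distinct
#'   values. Duplicated temperatures are collapsed by the geometric mean
#'   of their Ka values, with a warning.
#' @param Ka association constants (M^-1), positive, one per temperature.
#' @return An object of class `vant_hoff` with components `dH` (J mol^-1),
#'   `dS` (J mol^-1 K^-1), `dG` (named vector, J mol^-1, Gibbs-Helmholtz
#'   route), `dG_obs` (-RT ln Ka at the observed constants), `slope`,
#'   `intercept`, `r_squared`, `flagged` (temperatures where the two dG
#'   routes disagree by > 200 J mol^-1) and the underlying `lm`.
#' @examples
#' vh <- vant_hoff_fit(c(298, 303, 310), c(1.37e5, 1.27e5, 1.04e5))
#' vh
#' coef(vh)
#' @export
vant_hoff_fit <- function(temperature_K, Ka) {
  .assert(length(temperature_K) == length(Ka),
          "temperature_K and Ka lengths differ", "fluorbind_param_error")
  .assert(all(Ka > 0), "all Ka must be positive", "fluorbind_param_error")
  .assert(all(temperature_K > 0), "temperatures must be in kelvin (> 0)",
          "fluorbind_param_error")
  if (anyDuplicated(temperature_K)) {
    warning("duplicate temperatures collapsed by geometric-mean Ka")
    lnka <- tapply(log(Ka), temperature_K, mean)
    temperature_K <- as.numeric(names(lnka))
    Ka <- exp(as.numeric(lnka))
  }
  .assert(length(temperature_K) >= 2,
          "need at least 2 distinct temperatures for a van't Hoff fit",
          "fluorbind_insufficient_data")
  d <- data.frame(lnKa = log(Ka), invT = 1 / temperature_K)
  fit <- stats::lm(lnKa ~ invT, data = d)
  cf <- stats::coef(fit)
  slope <- unname(cf[2]); intercept <- unname(cf[1])
  dH <- -.R_GAS * slope
  dS <- .R_GAS * intercept
  dG <- gibbs_energy(dH, dS, temperature_K)
  names(dG) <- as.character(temperature_K)
  dG_obs <- dg_from_ka(Ka, temperature_K)
  names(dG_obs) <- as.character(temperature_K)
  flagged <- temperature_K[abs(dG - dG_obs) > 200]
  if (length(flagged)) {
    message("vant_hoff_fit: Gibbs-Helmholtz and -RT ln Ka routes disagree ",
            "by > 0.2 kJ/mol at T = ", paste(flagged, collapse = ", "), " K")
  }
  r2 <- if (length(temperature_K) > 2) .lm_stats(fit)$r_squared else 1
  structure(list(dH = dH, dS = dS, dG = dG, dG_obs = dG_obs,
                 slope = slope, intercept = intercept, r_squared = r2,
                 temperature_K = temperature_K, Ka = Ka,
                 flagged = flagged, lm = fit),
            class = "vant_hoff")
}

#' @export
print.vant_hoff <- function(x, ...) {
  cat("van't Hoff binding thermodynamics\n")
  cat(sprintf("  dH = %s kJ/mol, dS = %.2f J/mol/K  (R^2 = %.4f)\n",
              .kj(x$dH), x$dS, x$r_squared))
  for (i in seq_along(x$dG)) {
    cat(sprintf("  dG(%s K) = %s kJ/mol  [-RT ln Ka: %s]\n",
                names(x$dG)[i], .kj(x$dG[i]), .kj(x$dG_obs[i])))
  }
  invisible(x)
}

#' @export
coef.vant_hoff <- function(object, ...) {
  c(dH = object$dH, dS = object$dS)
}

#' Predict the association constant on the fitted van't Hoff line
#'
#' @param object a [vant_hoff_fit()].
#' @param temperature_K temperatures (K) at which to evaluate Ka.
#' @param ... unused.
#' @return Ka (M^-1) on the fitted line.
#' @export
predict.vant_hoff <- function(object, temperature_K = object$temperature_K,
                              ...) {
  exp(object$intercept + object$slope / temperature_K)
}

#' Gibbs free-energy change from enthalpy and entropy
#'
#' The Gibbs-Helmholtz relation `dG = dH - T dS`. Negative values
#' indicate spontaneous binding.
#'
#' @param dH enthalpy change (J mol^-1).
#' @param dS entropy change (J mol^-1 K^-1).
#' @param temperature_K absolute temperature(s) (K), positive.
#' @return dG (J mol^-1), vectorised over `temperature_K`.
#' @export
gibbs_energy <- function(dH, dS, temperature_K) {
  .assert(all(temperature_K > 0), "temperature must be positive (kelvin)",
          "fluorbind_param_error")
  dH - temperature_K * dS
}

#' Gibbs free-energy change directly from an association constant
#'
#' `dG = -R T ln Ka`, the standard cross-check on the van't Hoff /
#' Gibbs-Helmholtz route.
#'
#' @param Ka association constant (M^-1), positive.
#' @param temperature_K absolute temperature (K), positive.
#' @return dG (J mol^-1).
#' @export
dg_from_ka <- function(Ka, temperature_K) {
  .assert(all(Ka > 0), "Ka must be positive", "fluorbind_param_error")
  .assert(all(temperature_K > 0), "temperature must be positive (kelvin)",
          "fluorbind_param_error")
  -.R_GAS * temperature_K * log(Ka)
}
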