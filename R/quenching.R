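#' Inner-filter-effect correction of measured fluorescence
#'
#' Undoes the attenuation of excitation and emission light by an absorbing
#' ligand:
#' `Fc = F_obs * 10^((A_em * d_em + A_ex * d_ex) / 2)`.
#' With zero absorbance the measured value is returned unchanged; the
#' corrected value is never smaller than the measured one.
#'
#' @param F_obs measured fluorescence (a.u.), non-negative; vectorised.
#' @param A_ex,A_em ligand absorbance at the excitation and emission
#'   wavelengths (absorbance units), non-negative; recycled against
#'   `F_obs`.
#' @param d_ex,d_em optical path lengths (cm), positive.
#' @return Corrected fluorescence, same length as `F_obs`.
#' @examples
#' inner_filter_correct(100, A_ex = 0.1, A_em = 0.05)  # 118.85
#' @export
inner_filter_correct <- function(F_obs, A_ex, A_em, d_ex = 1, d_em = 1) {
  .assert(all(F_obs >= 0), "F_obs must be non-negative",
          "fluorbind_param_error")
  .assert(all(A_ex >= 0) && all(A_em >= 0),
          "absorbances must be non-negative", "fluorbind_param_error")
  .assert(all(d_ex > 0) && all(d_em > 0), "path lengths must be positive",
          "fluorbind_param_error")
  F_obs * 10^((A_em * d_em + A_ex * d_ex) / 2)
}

#' Free/bound ligand partitioning from corrected fluorescence
#'
#' Converts inner-filter-corrected fluorescence intensities into a binding
#' isotherm under the static-quenching assumption that the fractional
#' fluorescence decrement equals the bound-protein fraction:
#' `Lb = ((F0 - Fc)/F0) * Pt`, `Lf = Lt - Lb`, `r = Lb / Pt`.
#'
#' Points with `Fc > F0` (apparent enhancement, typically noise) are
#' clipped to zero binding with a warning. A point whose implied bound
#' ligand exceeds the total ligand present is a data inconsistency and
#' raises an error naming the point.
#'
#' @param Lt total ligand concentrations (M), one per point.
#' @param Fc inner-filter-corrected fluorescence at each point.
#' @param F0 fluorescence of the protein without ligand (> 0).
#' @param Pt total protein concentration (M).
#' @return An object of class `binding_isotherm`: a data frame with
#'   columns `Lt`, `Lf`, `Lb`, `r`, `Fc` and attributes `F0`, `Pt`.
#' @export
binding_isotherm <- function(Lt, Fc, F0, Pt) {
  .assert(F0 > 0, "F0 must be positive", "fluorbind_param_error")
  .assert(Pt > 0, "Pt must be positive", "fluorbind_param_error")
  .assert(length(Lt) == length(Fc), "Lt and Fc lengths differ",
          "fluorbind_param_error")
  .assert(all(Lt >= 0), "Lt must be non-negative", "fluorbind_param_error")
  if (any(Fc > F0)) {
    warning(sum(Fc > F0), " point(s) with Fc > F0 clipped to zero binding")
  }
  Lb <- pmax((F0 - pmin(Fc, F0)) / F0 * Pt, 0)
  bad <- which(Lb > Lt + 1e-12 * pmax(Lt, Pt))
  if (length(bad)) {
    stop(errorCondition(
      paste0("implied bound ligand exceeds total ligand at point(s) ",
             paste(bad, collapse = ", "),
             " (Lt = ", paste(signif(Lt[bad], 4), collapse = ", "), " M)"),
      class = c("fluorbind_data_error", "fluorbind_error")))
  }
  Lf <- Lt - Lb
  structure(data.frame(Lt = Lt, Lf = Lf, Lb = Lb, r = Lb / Pt, Fc = Fc),
            F0 = F0, Pt = Pt,
            class = c("binding_isotherm", "data.frame"))
}

#' Klotz double-reciprocal affinity fit
#'
#' Ordinary least squares of `1/r` on `1/Lf` (the Klotz linearisation of
#' an n-identical-site isotherm), from which the site number and the
#' association constant follow as `n = 1/intercept` and
#' `Ka = intercept/slope`. Zero-ligand points (r = 0 or Lf = 0) are
#' excluded, since their reciprocals are undefined.
#'
#' This reproduces the classical plot-based procedure. For a
#' statistically better-behaved estimate on noisy data see
#' [isotherm_nls_fit()], which fits the untransformed isotherm.
#'
#' @param isotherm a [binding_isotherm()] (or data frame with columns
#'   `r` and `Lf`).
#' @return An object of class `klotz_fit` with components `Ka` (M^-1),
#'   `n`, `slope`, `intercept`, `r_squared`, `n_points` and the
#'   underlying `lm` fit.
#' @export
klotz_fit <- function(isotherm) {
  use <- isotherm$r > 0 & isotherm$Lf > 0
  d <- data.frame(inv_r = 1 / isotherm$r[use], inv_Lf = 1 / isotherm$Lf[use])
  .assert(nrow(d) >= 3,
          "need at least 3 points with r > 0 and Lf > 0 for a Klotz fit",
          "fluorbind_insufficient_data")
  .assert(diff(range(d$inv_Lf)) > 0,
          "all points share the same free-ligand concentration; fit degenerate",
          "fluorbind_fit_degenerate")
  fit <- stats::lm(inv_r ~ inv_Lf, data = d)
  cf <- stats::coef(fit)
  intercept <- unname(cf[1]); slope <- unname(cf[2])
  .assert(is.finite(slope) && slope > 0 && intercept > 0,
          "non-positive slope or intercept; Ka undefined (fit degenerate)",
          "fluorbind_fit_degenerate")
  structure(list(Ka = intercept / slope, n = 1 / intercept,
                 slope = slope, intercept = intercept,
                 r_squared = .lm_stats(fit)$r_squared,
                 n_points = nrow(d), lm = fit),
            class = "klotz_fit")
}

#' @export
print.klotz_fit <- function(x, ...) {
  cat("Klotz double-reciprocal binding fit\n")
  cat(sprintf("  Ka = %.4g M^-1, n = %.3f sites  (%d points, R^2 = %.4f)\n",
              x$Ka, x$n, x$n_points, x$r_squared))
  invisible(x)
}

#' @export
coef.klotz_fit <- function(object, ...) {
  c(Ka = object$Ka, n = object$n)
}

#' Nonlinear binding-isotherm fit (cross-check estimator)
#'
#' Direct nonlinear least squares of `r = n * Ka * Lf / (1 + Ka * Lf)`,
#' the untransformed form of the isotherm the Klotz plot linearises.
#' On noiseless data the two agree to high precision; on noisy data this
#' fit avoids the reciprocal transform's noise amplification at low
#' occupancy and is the preferable estimator.
#'
#' @param isotherm a [binding_isotherm()].
#' @param start optional named list of starting values `Ka`, `n`;
#'   defaults are derived from the data (or from a Klotz fit if possible).
#' @return An object of class `klotz_fit` (same accessors) with an extra
#'   `method = "nls"` field.
#' @export
isotherm_nls_fit <- function(isotherm, start = NULL) {
  use <- isotherm$Lf > 0 & isotherm$r >= 0
  d <- data.frame(r = isotherm$r[use], Lf = isotherm$Lf[use])
  .assert(nrow(d) >= 3, "need at least 3 points for an isotherm fit",
          "fluorbind_insufficient_data")
  if (is.null(start)) {
    start <- tryCatch({
      k0 <- klotz_fit(isotherm)
      list(Ka = k0$Ka, n = k0$n)
    }, error = function(e) list(Ka = 1 / stats::median(d$Lf),
                                n = max(d$r) * 2))
  }
  # scaleOffset makes the relative-offset criterion usable on the
  # zero-residual fits that arise with noiseless synthetic data
  fit <- stats::nls(r ~ n * Ka * Lf / (1 + Ka * Lf), data = d,
                    start = start,
                    control = stats::nls.control(maxiter = 500,
                                                 scaleOffset = 1))
  cf <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((d$r - mean(d$r))^2)
  structure(list(Ka = unname(cf["Ka"]), n = unname(cf["n"]),
                 slope = NA_real_, intercept = NA_real_,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n_points = nrow(d), lm = fit, method = "nls"),
            class = "klotz_fit")
}

#' Stern-Volmer quenching fit
#'
#' Ordinary least squares of `F0/F` on the quencher concentration:
#' `F0/F = 1 + Ksv [Q]`. The intercept is fitted freely as a linearity
#' diagnostic (it should be close to 1; a deviation beyond 5 percent
#' triggers a warning). The bimolecular quenching rate constant follows
#' as `kq = Ksv / tau0`; values far above the diffusion limit
#' (~1e10 M^-1 s^-1) indicate static quenching via ground-state complex
#' formation.
#'
#' @param Q quencher concentrations (M), at least 3 points.
#' @param F fluorescence at each `Q` (positive). Use inner-filter-
#'   corrected values for an absorbing quencher.
#' @param F0 fluorescence without quencher (> 0).
#' @param tau0 unquenched fluorophore lifetime (s); default 5e-9, the
#'   literature lifetime for catalase.
#' @return An object of class `sv_fit` with `Ksv` (M^-1),
#'   `kq` (M^-1 s^-1), `tau0`, `intercept`, `r_squared` and the
#'   underlying `lm`.
#' @export
stern_volmer_fit <- function(Q, F, F0, tau0 = 5e-9) {
  .assert(length(Q) == length(F), "Q and F lengths differ",
          "fluorbind_param_error")
  .assert(length(Q) >= 3, "need at least 3 points for a Stern-Volmer fit",
          "fluorbind_insufficient_data")
  .assert(all(F > 0), "all fluorescence values must be positive",
          "fluorbind_param_error")
  .assert(F0 > 0 && tau0 > 0, "F0 and tau0 must be positive",
          "fluorbind_param_error")
  d <- data.frame(ratio = F0 / F, Q = Q)
  fit <- stats::lm(ratio ~ Q, data = d)
  cf <- stats::coef(fit)
  Ksv <- unname(cf[2]); intercept <- unname(cf[1])
  # warn only on a meaningfully negative slope, not fp round-off on a
  # flat ratio (Ksv is of order 1e4-1e6 M^-1 when quenching is real)
  if (Ksv < -max(2 * .lm_stats(fit)$se_slope, 1e-6)) {
    warning("negative Stern-Volmer slope (", signif(Ksv, 3),
            "); reported as-is")
  }
  if (abs(intercept - 1) > 0.05) {
    warning("Stern-Volmer intercept ", signif(intercept, 4),
            " deviates from 1 by more than 5%; check linearity")
  }
  structure(list(Ksv = Ksv, kq = Ksv / tau0, tau0 = tau0,
                 intercept = intercept,
                 r_squared = .lm_stats(fit)$r_squared,
                 n_points = length(Q), lm = fit),
            class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat("Stern-Volmer quenching fit\n")
  cat(sprintf("  Ksv = %.4g M^-1, kq = %.4g M^-1 s^-1 (tau0 = %g s)\n",
              x$Ksv, x$kq, x$tau0))
  cat(sprintf("  intercept = %.4f, R^2 = %.4f, %d points\n",
              x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.sv_fit <- function(object, ...) {
  c(Ksv = object$Ksv, kq = object$kq)
}
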