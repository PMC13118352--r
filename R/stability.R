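#' Fit a two-state thermal unfolding curve and extract Tm
#'
#' Fits the Boltzmann sigmoid
#' `ratio(T) = pre + (post - pre) / (1 + exp((Tm - T)/k))`
#' to an F330/F350 (or comparable) melt curve by nonlinear least squares.
#' The melting temperature is the inflection point of the sigmoid, which
#' for this parameterisation is exactly `Tm`. Starting values come from
#' the plateau means and the maximum-|slope| point of a lightly smoothed
#' numerical derivative; `nls` (port algorithm, Tm bounded to the observed
#' range) is tried first with a Nelder-Mead fallback.
#'
#' A curve without a detectable transition (ratio span below 3x the local
#' noise level, estimated from first differences) raises a no-transition
#' error rather than returning a meaningless Tm.
#'
#' @param curve a [generate_melt()] result, or any data frame with columns
#'   `temperature_c` (strictly increasing) and `ratio`.
#' @return An object of class `melt_fit` with `Tm`, `pre_baseline`,
#'   `post_baseline`, `steepness` (all degrees C where applicable),
#'   `r_squared`, `fitted` values and the input `curve`.
#' @examples
#' mc <- generate_melt(Tm = 57.8)
#' fit_melting(mc)
#' @export
fit_melting <- function(curve) {
  .assert(is.data.frame(curve) &&
            all(c("temperature_c", "ratio") %in% names(curve)),
          "curve must have columns temperature_c and ratio",
          "fluorbind_param_error")
  Tc <- curve$temperature_c
  y <- curve$ratio
  .assert(.is_increasing(Tc), "temperatures must be strictly increasing",
          "fluorbind_param_error")
  .assert(length(Tc) >= 8, "need at least 8 points spanning both plateaus",
          "fluorbind_insufficient_data")
  # local noise level from lag-1 differences (sd(diff)/sqrt(2) estimates
  # the point noise when the underlying curve is smooth)
  noise <- stats::sd(diff(y)) / sqrt(2)
  if (!is.finite(noise)) noise <- 0
  # transition amplitude as the plateau-mean difference; a raw range would
  # be inflated by noise extremes on a flat curve
  span <- abs(mean(utils::head(y, 3)) - mean(utils::tail(y, 3)))
  .assert(span > 3 * noise && span > 0,
          "no detectable sigmoidal transition (ratio span within noise)",
          "fluorbind_no_transition")

  # smoothed derivative for initialisation
  k_sm <- min(5, length(y))
  ys <- stats::filter(y, rep(1 / k_sm, k_sm), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  dy <- diff(as.numeric(ys)) / diff(Tc)
  i0 <- which.max(abs(dy))
  start <- list(pre = mean(utils::head(y, 3)),
                post = mean(utils::tail(y, 3)),
                Tm = mean(Tc[i0 + 0:1]),
                k = max(diff(range(Tc)) / 20, min(diff(Tc))))

  model <- function(p) p[1] + (p[2] - p[1]) / (1 + exp((p[3] - Tc) / p[4]))
  fit <- tryCatch(
    stats::nls(ratio ~ pre + (post - pre) / (1 + exp((Tm - temperature_c) / k)),
               data = curve, start = start, algorithm = "port",
               lower = c(pre = -Inf, post = -Inf, Tm = min(Tc), k = 1e-3),
               upper = c(pre = Inf, post = Inf, Tm = max(Tc),
                         k = diff(range(Tc))),
               control = stats::nls.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # fall back to direct RSS minimisation
    obj <- function(p) sum((y - model(p))^2)
    op <- stats::optim(unlist(start), obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    if (op$convergence != 0) {
      stop(errorCondition(
        paste0("melt fit did not converge (nls: ",
               conditionMessage(fit), "; optim code ", op$convergence, ")"),
        class = c("fluorbind_fit_error", "fluorbind_error")))
    }
    p <- op$par
    fitted_vals <- model(p)
    cf <- c(pre = unname(p[1]), post = unname(p[2]),
            Tm = unname(p[3]), k = unname(p[4]))
  } else {
    cf <- stats::coef(fit)
    fitted_vals <- as.numeric(stats::fitted(fit))
  }
  ss_res <- sum((y - fitted_vals)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(Tm = unname(cf["Tm"]),
                 pre_baseline = unname(cf["pre"]),
                 post_baseline = unname(cf["post"]),
                 steepness = unname(cf["k"]),
                 r_squared = 1 - ss_res / ss_tot,
                 fitted = fitted_vals, curve = curve),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("Two-state thermal melt fit\n")
  cat(sprintf("  Tm = %.2f degC (steepness %.2f degC, R^2 = %.4f)\n",
              x$Tm, x$steepness, x$r_squared))
  cat(sprintf("  plateaus: %.4g (folded) -> %.4g (unfolded)\n",
              x$pre_baseline, x$post_baseline))
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(Tm = object$Tm, pre_baseline = object$pre_baseline,
    post_baseline = object$post_baseline, steepness = object$steepness)
}

#' Predict the fitted melt sigmoid
#' @param object a `melt_fit`.
#' @param temperature_c temperatures (degrees C).
#' @param ... unused.
#' @export
predict.melt_fit <- function(object,
                             temperature_c = object$curve$temperature_c,
                             ...) {
  with(object, pre_baseline + (post_baseline - pre_baseline) /
         (1 + exp((Tm - temperature_c) / steepness)))
}

#' @export
residuals.melt_fit <- function(object, ...) {
  object$curve$ratio - object$fitted
}

#' Plot a melt curve and its fitted sigmoid
#' @param x a `melt_fit`.
#' @param ... passed to `plot`.
#' @export
plot.melt_fit <- function(x, ...) {
  graphics::plot(x$curve$temperature_c, x$curve$ratio,
                 xlab = "Temperature (degC)", ylab = "F330/F350", ...)
  tt <- seq(min(x$curve$temperature_c), max(x$curve$temperature_c),
            length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "red3")
  graphics::abline(v = x$Tm, lty = 2, col = "grey40")
  invisible(x)
}

#' Oxidative-protection metrics from fluorescence time courses
#'
#' Compares three decay traces recorded over the same time range: protein
#' plus oxidant plus candidate protectant (`treated`), protein plus
#' oxidant (`oxidant_only`), and protein alone (`untreated`). Each trace
#' is summarised by its retained fraction `RF = value(t_end)/value(t_0)`
#' at the last common time point, and the protection index is
#' `(RF_treated - RF_oxidant) / (RF_untreated - RF_oxidant)`:
#' 0 means no protection, 1 full protection. The index is clipped to
#' `[-0.1, 1.1]`, with a warning whenever it falls outside `[0, 1]`.
#'
#' @param treated,oxidant_only,untreated `kinetic_trace` objects (or data
#'   frames with columns `time`, `value`) with positive initial values.
#' @return A list of class `oxidation_metrics` with `rf_treated`,
#'   `rf_oxidant`, `rf_untreated`, `protection_index`, `t_end`.
#' @export
oxidation_metrics <- function(treated, oxidant_only, untreated) {
  traces <- list(treated = treated, oxidant_only = oxidant_only,
                 untreated = untreated)
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    .assert(is.data.frame(tr) && all(c("time", "value") %in% names(tr)),
            paste0(nm, " must have columns time and value"),
            "fluorbind_param_error")
    .assert(tr$value[1] > 0, paste0(nm, ": initial value must be positive"),
            "fluorbind_param_error")
  }
  t_end <- min(vapply(traces, function(tr) max(tr$time), numeric(1)))
  t_start <- max(vapply(traces, function(tr) min(tr$time), numeric(1)))
  .assert(t_end > t_start, "traces do not share a common time range",
          "fluorbind_param_error")
  rf <- vapply(traces, function(tr) {
    v0 <- stats::approx(tr$time, tr$value, xout = t_start)$y
    v1 <- stats::approx(tr$time, tr$value, xout = t_end)$y
    v1 / v0
  }, numeric(1))
  .assert(rf[["untreated"]] > rf[["oxidant_only"]],
          "untreated retains no more signal than oxidant-only; protection index undefined",
          "fluorbind_index_undefined")
  idx <- (rf[["treated"]] - rf[["oxidant_only"]]) /
    (rf[["untreated"]] - rf[["oxidant_only"]])
  if (idx < 0 || idx > 1) {
    warning("protection index ", signif(idx, 4),
            " outside [0, 1]; clipped to [-0.1, 1.1]")
    idx <- min(max(idx, -0.1), 1.1)
  }
  structure(list(rf_treated = rf[["treated"]],
                 rf_oxidant = rf[["oxidant_only"]],
                 rf_untreated = rf[["untreated"]],
                 protection_index = idx, t_end = t_end),
            class = "oxidation_metrics")
}

#' @export
print.oxidation_metrics <- function(x, ...) {
  cat("Oxidative-protection metrics\n")
  cat(sprintf("  retained fraction at t = %g: treated %.3f, oxidant-only %.3f, untreated %.3f\n",
              x$t_end, x$rf_treated, x$rf_oxidant, x$rf_untreated))
  cat(sprintf("  protection index = %.3f\n", x$protection_index))
  invisible(x)
}

#' First-order decay rate of a kinetic trace
#'
#' Log-linear OLS estimate of the effective decay rate of an exponential
#' trace; used to compare recovered oxidation rates with generator truth.
#'
#' @param trace a `kinetic_trace` with positive values.
#' @return Decay rate in reciprocal time units of the trace.
#' @export
decay_rate <- function(trace) {
  .assert(all(trace$value > 0),
          "trace values must be positive for a log-linear rate",
          "fluorbind_param_error")
  -unname(stats::coef(stats::lm(log(value) ~ time, data = trace))[2])
}
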