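# Internal helpers shared across modules.

# Universal gas constant, J mol^-1 K^-1 (value used throughout the
# thermodynamics module; kept at 4 significant figures on purpose so that
# reported energies match conventional spectroscopy practice).
.R_GAS <- 8.314

# Reference temperature (K) at which Ka_ref of a binding ground truth is
# anchored.
.T_REF <- 298

#' @keywords internal
.assert <- function(cond, msg, class = "fluorbind_error") {
  if (!isTRUE(cond)) {
    stop(errorCondition(msg, class = c(class, "fluorbind_error")))
  }
  invisible(TRUE)
}

# Multiplicative Gaussian noise, floored at zero. Photon-counting-like
# behaviour at desk simplicity: sigma scales with the signal.
.apply_noise <- function(x, sigma_rel) {
  if (sigma_rel == 0) return(x)
  pmax(x * (1 + stats::rnorm(length(x), sd = sigma_rel)), 0)
}

# Seed handling for generators: set the RNG once per generator call so that
# identical (seed, parameters) always yield bit-identical datasets.
.seed_rng <- function(seed) {
  if (!is.null(seed)) {
    .assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "seed must be a single finite number", "fluorbind_param_error")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

.is_increasing <- function(x, strict = TRUE) {
  d <- diff(x)
  if (strict) all(d > 0) else all(d >= 0)
}

# Format an energy stored in J/mol as kJ/mol with 2 decimals (report style).
.kj <- function(x_j) sprintf("%.2f", x_j / 1000)

# R^2 and slope standard error of a simple linear fit, computed directly
# (summary.lm warns on zero-residual fits, which are routine here when
# validating against noiseless synthetic data).
.lm_stats <- function(fit) {
  res <- stats::resid(fit)
  y <- res + stats::fitted(fit)
  x <- stats::model.matrix(fit)[, 2]
  n <- length(y)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  sigma2 <- if (n > 2) ss_res / (n - 2) else 0
  list(r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       se_slope = sqrt(sigma2 / sum((x - mean(x))^2)))
}
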