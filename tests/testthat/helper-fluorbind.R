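# Shared fixtures built in code.

# Gaussian band on a wavelength grid (emission-like spectrum).
gaussian_spectrum <- function(center = 340, sigma = 20, amp = 1,
                              grid = seq(290, 440, by = 1), ...) {
  spectrum(grid, amp * exp(-(grid - center)^2 / (2 * sigma^2)), ...)
}

# Closed-form OLS (slope, intercept) independent of stats::lm.
ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(slope = slope, intercept = my - slope * mx)
}

# Noiseless isotherm points straight from the n-identical-site law,
# bypassing the titration forward model entirely.
law_isotherm <- function(Ka, n, Lf) {
  data.frame(Lf = Lf, r = n * Ka * Lf / (1 + Ka * Lf))
}
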