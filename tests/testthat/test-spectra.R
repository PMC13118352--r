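test_that("spectrum constructor enforces its invariants", {
  expect_s3_class(spectrum(1:5, rep(1, 5)), "spectrum")
  expect_error(spectrum(c(1, 2, 2, 3), rep(1, 4)), class = "fluorbind_grid_error")
  expect_error(spectrum(1:4, 1:3), class = "fluorbind_grid_error")
  expect_error(spectrum(1:4, c(1, NA, 3, 4)), class = "fluorbind_grid_error")
})

test_that("blank subtraction is pointwise and preserves sample metadata", {
  s <- spectrum(c(300, 310), c(10, 20), series = "sample", temperature = 25)
  b <- spectrum(c(300, 310), c(1, 2), series = "blank")
  out <- subtract_blank(s, b)
  expect_equal(out$intensity, c(9, 18))
  expect_identical(out$meta$series, "sample")
  expect_equal(out$meta$temperature, 25)

  # identity cases
  expect_equal(subtract_blank(s, s)$intensity, c(0, 0))
  zero <- spectrum(c(300, 310), c(0, 0))
  expect_equal(subtract_blank(s, zero)$intensity, s$intensity)

  # mismatched grids refuse to subtract
  b2 <- spectrum(c(300, 311), c(1, 2))
  expect_error(subtract_blank(s, b2), class = "fluorbind_grid_error")
})

test_that("subtracting then re-adding a blank restores the sample exactly", {
  grid <- seq(290, 440, by = 0.5)
  set.seed(11)
  s <- spectrum(grid, runif(length(grid), 10, 100))
  b <- spectrum(grid, runif(length(grid), 0, 5))
  diffed <- subtract_blank(s, b)
  expect_equal(diffed$intensity + b$intensity, s$intensity)
})

test_that("peak reading finds the grid maximum, with deterministic tie-break", {
  g <- gaussian_spectrum(center = 340)
  pk <- peak_intensity(g, 290, 440)
  expect_equal(pk$wavelength, 340)

  mono <- spectrum(300:400, seq(100, 0, length.out = 101))
  expect_equal(peak_intensity(mono, 300, 400)$wavelength, 300)

  # two equal maxima: lowest wavelength wins
  tied <- spectrum(seq(300, 400, by = 10),
                   c(1, 1, 1, 5, 1, 5, 1, 1, 1, 1, 1))
  expect_equal(peak_intensity(tied)$wavelength, 330)

  # invariant under uniform intensity scaling
  g2 <- spectrum(g$wavelength, g$intensity * 137)
  expect_equal(peak_intensity(g2)$wavelength, pk$wavelength)

  expect_error(peak_intensity(g, 1000, 1010), class = "fluorbind_window_error")
})

test_that("intensity ratio interpolates linearly and guards the denominator", {
  flat <- spectrum(300:400, rep(5, 101))
  expect_equal(intensity_ratio(flat, 330, 350), 1)

  s <- spectrum(c(320, 330, 340, 350, 360), c(90, 120, 110, 100, 80))
  expect_equal(intensity_ratio(s, 330, 350), 1.2)
  # off-grid read uses linear interpolation: I(335) = 115
  expect_equal(intensity_ratio(s, 335, 350), 1.15)

  expect_error(intensity_ratio(s, 250, 350), class = "fluorbind_window_error")
  neg <- spectrum(c(320, 330, 340), c(1, 1, -2))
  expect_error(intensity_ratio(neg, 320, 340), class = "fluorbind_ratio_error")
})

test_that("fourth derivative annihilates cubics and recovers quartic curvature", {
  x <- seq(260, 320, by = 0.1)
  cubic <- spectrum(x, 2 + 0.5 * x - 0.01 * x^2 + 1e-4 * x^3,
                    kind = "absorbance")
  d4 <- fourth_derivative(cubic, window_points = 101, poly_order = 6)
  expect_lt(max(abs(d4$intensity)), 1e-8 * max(abs(cubic$intensity)))

  # centred quartic: d4/dx4 of (x - 290)^4 is 24 everywhere
  quart <- spectrum(x, (x - 290)^4, kind = "absorbance")
  d4q <- fourth_derivative(quart, window_points = 101, poly_order = 6)
  expect_equal(d4q$intensity, rep(24, length(d4q$intensity)),
               tolerance = 1e-6)
})

test_that("fourth derivative of a Gaussian band matches the analytic form", {
  x <- seq(260, 320, by = 0.1)
  s_nm <- 8  # realistic aromatic band width
  y <- exp(-(x - 290)^2 / (2 * s_nm^2))
  d4 <- fourth_derivative(spectrum(x, y, kind = "absorbance"),
                          window_points = 101, poly_order = 6)
  z <- (d4$wavelength - 290) / s_nm
  analytic <- exp(-z^2 / 2) * (z^4 - 6 * z^2 + 3) / s_nm^4
  expect_lt(max(abs(d4$intensity - analytic)) / max(abs(analytic)), 0.01)
})

test_that("fourth derivative rejects bad configurations", {
  s <- gaussian_spectrum(grid = seq(300, 360, by = 1))
  expect_error(fourth_derivative(s, window_points = 100),
               class = "fluorbind_config_error")
  expect_error(fourth_derivative(s, window_points = 7, poly_order = 3),
               class = "fluorbind_config_error")
  expect_error(fourth_derivative(s, window_points = 101),
               class = "fluorbind_config_error")  # window > spectrum
  nonuni <- spectrum(c(1, 2, 4, 8, 16, 32, 64, 128, 256, 300, 310, 320),
                     rep(1, 12))
  expect_error(fourth_derivative(nonuni, window_points = 7, poly_order = 4),
               class = "fluorbind_config_error")
})
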