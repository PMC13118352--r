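test_that("inner-filter correction reproduces the textbook values", {
  expect_equal(inner_filter_correct(100, 0, 0), 100)
  expect_equal(inner_filter_correct(100, A_ex = 0.1, A_em = 0.05),
               100 * 10^0.075, tolerance = 1e-12)   # 118.85
  expect_equal(inner_filter_correct(100, A_ex = 0.2, A_em = 0.2),
               100 * 10^0.2, tolerance = 1e-12)     # 158.49
  # correction never reduces the signal
  set.seed(3)
  Fo <- runif(20, 1, 100); Ae <- runif(20, 0, 0.3); Am <- runif(20, 0, 0.3)
  expect_true(all(inner_filter_correct(Fo, Ae, Am) >= Fo))
  expect_error(inner_filter_correct(-1, 0, 0), class = "fluorbind_param_error")
})

test_that("free/bound partitioning follows the fluorescence decrement", {
  iso <- binding_isotherm(Lt = 1e-6, Fc = 90, F0 = 100, Pt = 1e-7)
  expect_equal(iso$Lb, 1e-8)
  expect_equal(iso$Lf, 9.9e-7)
  expect_equal(iso$r, 0.1)

  # no quench -> no binding
  iso0 <- binding_isotherm(Lt = 1e-6, Fc = 100, F0 = 100, Pt = 1e-7)
  expect_equal(iso0$Lb, 0)
  expect_equal(iso0$Lf, 1e-6)

  # conservation at machine precision on a realistic ladder
  Lt <- seq(1e-7, 1e-6, by = 1e-7)
  iso2 <- binding_isotherm(Lt, Fc = seq(99, 90, by = -1), F0 = 100, Pt = 1e-7)
  expect_equal(iso2$Lf + iso2$Lb, Lt, tolerance = 1e-15)

  # apparent enhancement clipped with warning
  expect_warning(
    iso3 <- binding_isotherm(c(1e-7, 2e-7, 3e-7), c(101, 99, 98), 100, 1e-7),
    "clipped")
  expect_equal(iso3$Lb[1], 0)

  # implied bound exceeding total ligand is a data inconsistency
  expect_error(binding_isotherm(Lt = 1e-7, Fc = 50, F0 = 100, Pt = 1e-6),
               class = "fluorbind_data_error")
})

test_that("Klotz fit inverts the n-site law on noiseless points", {
  Lf <- seq(2e-6, 5e-5, length.out = 10)
  iso <- law_isotherm(Ka = 1e5, n = 1, Lf)
  kf <- klotz_fit(iso)
  expect_equal(kf$Ka, 1e5, tolerance = 1e-3)
  expect_equal(kf$n, 1, tolerance = 1e-3)
  expect_equal(kf$Ka, kf$intercept / kf$slope)   # defining relation
  expect_gt(kf$r_squared, 0.999999)

  # a 2-site protein
  kf2 <- klotz_fit(law_isotherm(Ka = 5e4, n = 2, Lf))
  expect_equal(kf2$n, 2, tolerance = 1e-3)

  expect_error(klotz_fit(law_isotherm(1e5, 1, rep(1e-6, 5))),
               class = "fluorbind_fit_degenerate")
  expect_error(klotz_fit(law_isotherm(1e5, 1, c(1e-6, 2e-6))),
               class = "fluorbind_insufficient_data")
})

test_that("closed-loop titration at study conditions recovers Ka within 1%", {
  # protein 0.1 uM, ligand ladder 0.1-1 uM, Ka = 1.37e5, zero noise
  tr <- binding_truth(Ka_ref = 1.37e5, dH = 0)
  tt <- generate_titration(tr, Pt = 1e-7, Lt = seq(0, 1e-6, by = 1e-7),
                           temperatures_K = 298)
  Fc <- inner_filter_correct(tt$F_obs, tt$A_ex, tt$A_em)
  iso <- binding_isotherm(tt$Lt_M, Fc, F0 = Fc[tt$Lt_M == 0], Pt = 1e-7)
  kf <- klotz_fit(iso)
  expect_equal(kf$Ka, 1.37e5, tolerance = 0.01)
  expect_equal(kf$n, 1, tolerance = 0.01)
})

test_that("linearised Klotz and nonlinear isotherm fits agree at zero noise", {
  tr <- binding_truth(Ka_ref = 2.5e5, dH = 0)
  tt <- generate_titration(tr, Lt = seq(0, 2e-5, by = 2e-6),
                           temperatures_K = 298)
  Fc <- inner_filter_correct(tt$F_obs, tt$A_ex, tt$A_em)
  iso <- binding_isotherm(tt$Lt_M, Fc, F0 = Fc[tt$Lt_M == 0], Pt = 1e-7)
  lin <- klotz_fit(iso)
  nl <- isotherm_nls_fit(iso)
  expect_equal(nl$Ka, lin$Ka, tolerance = 1e-3)
  expect_equal(nl$n, lin$n, tolerance = 1e-3)
  # and an oracle fit written directly against stats::nls
  oracle <- stats::nls(r ~ n * Ka * Lf / (1 + Ka * Lf),
                       data = iso[iso$Lf > 0, ],
                       start = list(Ka = 1e5, n = 1),
                       control = stats::nls.control(scaleOffset = 1))
  expect_equal(lin$Ka, unname(coef(oracle)["Ka"]), tolerance = 1e-3)
})

test_that("binding estimates are invariant under uniform fluorescence scaling", {
  tr <- binding_truth(Ka_ref = 1.37e5, dH = 0)
  tt <- generate_titration(tr, temperatures_K = 298)
  run <- function(scale) {
    Fc <- inner_filter_correct(tt$F_obs * scale, tt$A_ex, tt$A_em)
    iso <- binding_isotherm(tt$Lt_M, Fc, F0 = Fc[tt$Lt_M == 0], Pt = 1e-7)
    c(coef(klotz_fit(iso)),
      Ksv = stern_volmer_fit(tt$Lt_M, Fc, Fc[tt$Lt_M == 0])$Ksv)
  }
  expect_equal(run(1), run(17.3), tolerance = 1e-9)
})

test_that("Stern-Volmer fit extracts Ksv and kq with the catalase lifetime", {
  Q <- seq(1e-7, 1e-6, by = 1e-7)
  # no quenching
  sv0 <- stern_volmer_fit(Q, F = rep(500, 10), F0 = 500)
  expect_lt(abs(sv0$Ksv), 1e-6)            # zero up to fp round-off
  expect_identical(sv0$kq, sv0$Ksv / 5e-9)

  # exact Stern-Volmer lines at the two reported constants
  for (case in list(c(Ksv = 2.18e5, kq = 4.36e13),
                    c(Ksv = 1.73e5, kq = 3.46e13))) {
    F0 <- 100
    F_ <- F0 / (1 + case[["Ksv"]] * Q)
    sv <- stern_volmer_fit(Q, F_, F0, tau0 = 5e-9)
    expect_equal(sv$Ksv, case[["Ksv"]], tolerance = 1e-9)
    expect_equal(sv$kq, case[["kq"]], tolerance = 1e-9)
    expect_equal(sv$intercept, 1, tolerance = 1e-9)
    # kq/Ksv is 1/tau0 exactly by construction
    expect_identical(sv$kq, sv$Ksv / sv$tau0)
  }

  expect_warning(stern_volmer_fit(Q, F = 100 * (1 + 2e5 * Q), F0 = 100),
                 "negative")
  expect_error(stern_volmer_fit(c(1, 2), c(1, 2), 1),
               class = "fluorbind_insufficient_data")
})
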