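test_that("binding truth derives a consistent entropy from Ka_ref", {
  tr <- binding_truth(Ka_ref = 1.37e5, dH = -17800)
  expect_equal(ka_at_temperature(tr, 298), 1.37e5, tolerance = 1e-12)
  # explicit dH/dS that contradict Ka_ref are flagged
  expect_warning(binding_truth(Ka_ref = 1e5, dH = -17800, dS = 50),
                 "disagrees")
  expect_error(binding_truth(q = 0), class = "fluorbind_param_error")
  expect_error(binding_truth(Ka_ref = -1), class = "fluorbind_param_error")
})

test_that("titration forward model honours its boundary cases", {
  tr <- binding_truth(F0 = 100, eps_ex = 1e4, eps_em = 1e3)
  tt <- generate_titration(tr)
  # Lt = 0: no quench, no inner filter, F = F0 at every temperature
  expect_equal(tt$F_obs[tt$Lt_M == 0], rep(100, 3))
  # absorbances recorded per point
  expect_equal(tt$A_ex, 1e4 * tt$Lt_M)
  expect_equal(tt$A_em, 1e3 * tt$Lt_M)
  expect_error(generate_titration(tr, temperatures_K = 500),
               class = "fluorbind_param_error")
})

test_that("same seed and parameters give bit-identical datasets", {
  tr <- binding_truth()
  a <- generate_titration(tr, sigma_rel = 0.01, seed = 123)
  b <- generate_titration(tr, sigma_rel = 0.01, seed = 123)
  expect_identical(a, b)
  m1 <- generate_melt(sigma_rel = 0.01, seed = 9)
  m2 <- generate_melt(sigma_rel = 0.01, seed = 9)
  expect_identical(m1, m2)
  o1 <- generate_oxidation(sigma_rel = 0.02, seed = 5)
  o2 <- generate_oxidation(sigma_rel = 0.02, seed = 5)
  expect_identical(o1, o2)
})

test_that("mass-action occupancy satisfies the equilibrium residual", {
  for (Ka in c(1e4, 1e5, 1e6)) {
    tr <- binding_truth(Ka_ref = Ka, dH = -17800, n_sites = 2)
    Pt <- 1e-7
    tt <- generate_titration(tr, Pt = Pt, Lt = seq(0, 3e-5, by = 3e-6),
                             temperatures_K = 298)
    KaT <- ka_at_temperature(tr, 298)
    S <- tr$n_sites * Pt
    # reconstruct bound ligand from the noiseless fluorescence
    b <- (1 - tt$F_obs / tr$F0) * S
    resid <- KaT * (tt$Lt_M - b) * (S - b) - b
    expect_lt(max(abs(resid)), 1e-10 * Pt)
  }
})

test_that("generated Ka ratio across temperatures follows van't Hoff exactly", {
  tr <- binding_truth(dH = -17800)
  ratio <- ka_at_temperature(tr, 298) / ka_at_temperature(tr, 310)
  expect_equal(ratio, exp(17800 / 8.314 * (1 / 298 - 1 / 310)),
               tolerance = 1e-12)
})

test_that("with q = 1 and n = 1 the fluorescence decrement recovers free ligand exactly", {
  tr <- binding_truth(Ka_ref = 2e5, dH = 0, q = 1, n_sites = 1)
  Pt <- 1e-7
  tt <- generate_titration(tr, Pt = Pt, temperatures_K = 298)
  Fc <- inner_filter_correct(tt$F_obs, tt$A_ex, tt$A_em)
  Lb_est <- (tr$F0 - Fc) / tr$F0 * Pt
  Lf_est <- tt$Lt_M - Lb_est
  KaT <- ka_at_temperature(tr, 298)
  # independent root-finding oracle for the bound concentration
  Lb_true <- vapply(tt$Lt_M, function(Lt) {
    if (Lt == 0) return(0)
    stats::uniroot(function(b) KaT * (Lt - b) * (Pt - b) - b,
                   c(0, min(Lt, Pt)), tol = 1e-18)$root
  }, numeric(1))
  expect_equal(Lf_est, tt$Lt_M - Lb_true, tolerance = 1e-9)
})

test_that("melt generator places the sigmoid midpoint at Tm", {
  Tm <- 57.8
  mc <- generate_melt(Tm = Tm, pre_ratio = 1.2, post_ratio = 0.85,
                      T_grid = c(seq(37, 57, by = 2), Tm, seq(59, 81, by = 2)))
  at_tm <- mc$ratio[mc$temperature_c == Tm]
  expect_equal(at_tm, (1.2 + 0.85) / 2, tolerance = 1e-12)
  # very shallow transition approaches a linear ramp between the plateaus
  shallow <- generate_melt(Tm = 59, steepness = 1e4, T_grid = 37:81)
  expect_lt(diff(range(diff(shallow$ratio))), 1e-6)
})

test_that("oxidation generator follows first-order decay with protection", {
  flat <- generate_oxidation(F_init = 80, protection_factor = 1)
  expect_equal(flat$value, rep(80, nrow(flat)))
  ox <- generate_oxidation(F_init = 100, decay_rate_per_min = 0.05,
                           protection_factor = 0,
                           t_grid_min = seq(0, 30, by = 5))
  expect_equal(ox$value[ox$time == 30] / ox$value[ox$time == 0],
               exp(-1.5), tolerance = 1e-12)
  # doubling the rate halves the time to reach any fixed fraction
  ox2 <- generate_oxidation(decay_rate_per_min = 0.1,
                            t_grid_min = seq(0, 30, by = 0.5))
  expect_equal(ox2$value[ox2$time == 7.5], ox$value[ox$time == 15],
               tolerance = 1e-12)
  expect_error(generate_oxidation(protection_factor = 1.2),
               class = "fluorbind_param_error")
})

test_that("activity trace is linear and clips at zero", {
  const <- generate_activity_trace(rate_dA_per_min = 0, A0 = 0.4)
  expect_equal(const$value, rep(0.4, nrow(const)))
  tr <- generate_activity_trace(rate_dA_per_min = 0.0436, A0 = 0.5,
                                t_grid_min = 0:3)
  expect_equal(tr$value[tr$time == 3], 0.5 - 3 * 0.0436, tolerance = 1e-12)
  clipped <- generate_activity_trace(rate_dA_per_min = 1, A0 = 0.5,
                                     t_grid_min = 0:10)
  expect_equal(clipped$value[clipped$time >= 1], rep(0, 10))
})
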