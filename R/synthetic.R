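#' Define the ground truth for a synthetic binding experiment
#'
#' Collects the parameters of the forward model used by
#' [generate_titration()]: a 1:1 (or n identical independent sites)
#' mass-action binding equilibrium with static quenching, a van't Hoff
#' temperature dependence of the association constant, and ligand
#' inner-filter attenuation.
#'
#' The association constant at temperature T follows
#' `Ka(T) = exp(-dH/(R T) + dS/R)`. When `dS` is not supplied it is derived
#' from `Ka_ref` (anchored at 298 K) and `dH`, so that `Ka(298) == Ka_ref`
#' exactly. When both `dH` and `dS` are given they take precedence; if
#' `Ka_ref` is also supplied explicitly and disagrees with them by more
#' than 0.1 percent a warning flags the inconsistency.
#'
#' @param Ka_ref association constant at 298 K (M^-1). Default 1.37e5,
#'   a moderate drug-protein affinity.
#' @param n_sites identical independent binding sites per protein (>= 1).
#' @param dH binding enthalpy (J mol^-1); default -17800 (mildly
#'   exothermic).
#' @param dS binding entropy (J mol^-1 K^-1), or `NULL` to derive from
#'   `Ka_ref` and `dH`.
#' @param q quench completeness: fraction of a bound protein's fluorescence
#'   lost on complexation, in (0, 1]. The free/bound partitioning estimator
#'   assumes q = 1; smaller values are model-mismatch territory useful for
#'   bias studies.
#' @param F0 unquenched fluorescence amplitude (arbitrary units).
#' @param eps_ex,eps_em ligand molar absorptivity at the excitation and
#'   emission wavelengths (M^-1 cm^-1); drive the inner-filter effect.
#' @return An object of class `binding_truth`.
#' @export
binding_truth <- function(Ka_ref = 1.37e5, n_sites = 1, dH = -17800,
                          dS = NULL, q = 1, F0 = 100,
                          eps_ex = 0, eps_em = 0) {
  .assert(Ka_ref > 0, "Ka_ref must be positive", "fluorbind_param_error")
  .assert(n_sites >= 1, "n_sites must be >= 1", "fluorbind_param_error")
  .assert(q > 0 && q <= 1, "q must lie in (0, 1]", "fluorbind_param_error")
  .assert(eps_ex >= 0 && eps_em >= 0,
          "molar absorptivities must be non-negative",
          "fluorbind_param_error")
  ka_given <- !missing(Ka_ref)
  if (is.null(dS)) {
    dS <- .R_GAS * log(Ka_ref) + dH / .T_REF
  } else if (ka_given) {
    ka_implied <- exp(-dH / (.R_GAS * .T_REF) + dS / .R_GAS)
    if (abs(ka_implied / Ka_ref - 1) > 1e-3) {
      warning("dH/dS imply Ka(298) = ", signif(ka_implied, 4),
              " which disagrees with Ka_ref = ", signif(Ka_ref, 4),
              "; dH/dS take precedence")
    }
  }
  structure(list(Ka_ref = Ka_ref, n_sites = n_sites, dH = dH, dS = dS,
                 q = q, F0 = F0, eps_ex = eps_ex, eps_em = eps_em),
            class = "binding_truth")
}

#' @export
print.binding_truth <- function(x, ...) {
  cat("<binding_truth>\n")
  cat(sprintf("  Ka(298 K) %.4g M^-1, n = %g site(s), q = %g\n",
              ka_at_temperature(x, .T_REF), x$n_sites, x$q))
  cat(sprintf("  dH %s kJ/mol, dS %.2f J/mol/K\n", .kj(x$dH), x$dS))
  cat(sprintf("  F0 %g a.u., eps_ex %g, eps_em %g M^-1 cm^-1\n",
              x$F0, x$eps_ex, x$eps_em))
  invisible(x)
}

#' Association constant of a binding ground truth at a given temperature
#'
#' @param truth a `binding_truth`.
#' @param temperature_K absolute temperature(s) in K.
#' @return Ka (M^-1), vectorised over `temperature_K`.
#' @export
ka_at_temperature <- function(truth, temperature_K) {
  exp(-truth$dH / (.R_GAS * temperature_K) + truth$dS / .R_GAS)
}

# Bound-ligand concentration from 1:1 mass action with site concentration
# S = n * Pt: Ka = b / ((Lt - b)(S - b)). Solved as the stable root of the
# quadratic Ka b^2 - (Ka (Lt + S) + 1) b + Ka Lt S = 0 lying in
# [0, min(Lt, S)]. Vectorised over Lt.
.solve_bound <- function(Ka, Lt, S) {
  bq <- Ka * (Lt + S) + 1
  disc <- bq^2 - 4 * Ka^2 * Lt * S
  .assert(all(disc >= 0),
          "mass-action quadratic has no real root in the valid interval",
          "fluorbind_internal_error")
  b <- (bq - sqrt(disc)) / (2 * Ka)
  b <- pmin(pmax(b, 0), pmin(Lt, S))
  resid <- abs(Ka * (Lt - b) * (S - b) - b)
  .assert(all(resid <= 1e-8 * pmax(S, Lt, 1e-300) * pmax(Ka * S, 1)),
          "mass-action residual check failed", "fluorbind_internal_error")
  b
}

#' Generate a synthetic fluorescence quenching titration
#'
#' Forward model for a steady-state quenching titration of a fluorescent
#' protein by an absorbing ligand, per temperature:
#' \enumerate{
#'   \item `Ka(T)` from the van't Hoff relation encoded in `truth`;
#'   \item bound ligand per point from 1:1 mass action (quadratic root in
#'     `[0, min(Lt, n Pt)]`);
#'   \item true fluorescence `F_true = F0 (1 - q * occupancy)` (static
#'     quenching of the complexed protein);
#'   \item observed fluorescence attenuated by the ligand inner-filter
#'     effect, `F_obs = F_true * 10^-((A_ex d_ex + A_em d_em)/2)` with
#'     `A = eps * Lt * d`;
#'   \item multiplicative Gaussian noise, floored at zero.
#' }
#' Ligand absorbances at both wavelengths are recorded per point so that
#' the analysis chain can undo the inner-filter attenuation exactly.
#'
#' @param truth a [binding_truth()].
#' @param Pt total protein concentration (M). Default 1e-7 (0.1 uM).
#' @param Lt total ligand ladder (M), non-negative and increasing; the
#'   default spans 0 to 1 uM in 0.1 uM steps, the zero point supplying F0.
#' @param temperatures_K absolute temperatures (K) within 273-373.
#' @param sigma_rel relative Gaussian noise level (0 = noiseless).
#' @param seed integer seed; identical seed and parameters give
#'   bit-identical datasets. `NULL` leaves the RNG state untouched.
#' @param d_ex,d_em optical path lengths (cm).
#' @param tau0 unquenched fluorophore lifetime (s), carried as metadata
#'   for downstream Stern-Volmer analysis.
#' @return An object of class `titration_set`: a data frame with columns
#'   `temperature_K`, `Lt_M`, `F_obs`, `A_ex`, `A_em` and attributes
#'   `Pt`, `d_ex`, `d_em`, `tau0`, `truth`, `seed`.
#' @examples
#' tt <- generate_titration(binding_truth(), seed = 1)
#' head(tt)
#' @export
generate_titration <- function(truth, Pt = 1e-7,
                               Lt = seq(0, 1e-6, by = 1e-7),
                               temperatures_K = c(298, 303, 310),
                               sigma_rel = 0, seed = NULL,
                               d_ex = 1, d_em = 1, tau0 = 5e-9) {
  .assert(inherits(truth, "binding_truth"), "truth must be a binding_truth",
          "fluorbind_param_error")
  .assert(Pt > 0, "Pt must be positive", "fluorbind_param_error")
  .assert(all(Lt >= 0) && .is_increasing(Lt),
          "Lt ladder must be non-negative and increasing",
          "fluorbind_param_error")
  .assert(all(temperatures_K >= 273 & temperatures_K <= 373),
          "temperatures must lie within 273-373 K", "fluorbind_param_error")
  .assert(sigma_rel >= 0, "sigma_rel must be non-negative",
          "fluorbind_param_error")
  .seed_rng(seed)
  S <- truth$n_sites * Pt
  rows <- lapply(temperatures_K, function(Tk) {
    Ka <- ka_at_temperature(truth, Tk)
    b <- .solve_bound(Ka, Lt, S)
    occupancy <- b / S
    F_true <- truth$F0 * (1 - truth$q * occupancy)
    A_ex <- truth$eps_ex * Lt * d_ex
    A_em <- truth$eps_em * Lt * d_em
    F_obs <- F_true * 10^(-(A_ex * d_ex + A_em * d_em) / 2)
    data.frame(temperature_K = Tk, Lt_M = Lt, F_obs = F_obs,
               A_ex = A_ex, A_em = A_em)
  })
  out <- do.call(rbind, rows)
  out$F_obs <- .apply_noise(out$F_obs, sigma_rel)
  structure(out, Pt = Pt, d_ex = d_ex, d_em = d_em, tau0 = tau0,
            truth = truth, seed = seed, sigma_rel = sigma_rel,
            class = c("titration_set", "data.frame"))
}

#' Generate a synthetic thermal-melt ratio curve
#'
#' Two-state unfolding monitored by the F330/F350 intrinsic-fluorescence
#' ratio: `ratio(T) = pre + (post - pre) / (1 + exp((Tm - T)/steepness))`,
#' a Boltzmann sigmoid whose inflection lies exactly at `Tm`, plus
#' multiplicative Gaussian noise.
#'
#' Defaults emulate a folded-protein ratio near 1.2 dropping to 0.85 on
#' unfolding over a transition a few degrees wide, scanned from 37 to
#' 81 degrees C in 1 degree steps.
#'
#' @param Tm melting temperature (degrees C).
#' @param pre_ratio,post_ratio plateau ratios before/after the transition.
#' @param steepness transition width parameter (degrees C), > 0.
#' @param T_grid increasing temperature grid (degrees C).
#' @param sigma_rel relative noise level.
#' @param seed integer seed or `NULL`.
#' @param label series label.
#' @return A `melt_curve`: data frame with columns `temperature_c`, `ratio`.
#' @export
generate_melt <- function(Tm = 57.8, pre_ratio = 1.20, post_ratio = 0.85,
                          steepness = 1.5, T_grid = 37:81,
                          sigma_rel = 0, seed = NULL, label = "melt") {
  .assert(.is_increasing(T_grid), "T_grid must be increasing",
          "fluorbind_param_error")
  .assert(steepness > 0, "steepness must be positive",
          "fluorbind_param_error")
  .seed_rng(seed)
  ratio <- pre_ratio + (post_ratio - pre_ratio) /
    (1 + exp((Tm - T_grid) / steepness))
  ratio <- .apply_noise(ratio, sigma_rel)
  structure(data.frame(temperature_c = as.numeric(T_grid), ratio = ratio),
            label = label, seed = seed,
            truth = list(Tm = Tm, pre_ratio = pre_ratio,
                         post_ratio = post_ratio, steepness = steepness),
            class = c("melt_curve", "data.frame"))
}

#' Generate a synthetic oxidative fluorescence-decay trace
#'
#' First-order loss of intrinsic fluorescence under a radical generator:
#' `F(t) = F_init * exp(-decay_rate * (1 - protection_factor) * t)`.
#' A protection factor of 1 (full protection by a bound ligand) yields a
#' flat trace; 0 is the unprotected oxidant-only decay.
#'
#' @param F_init initial fluorescence (a.u.).
#' @param decay_rate_per_min first-order decay rate (min^-1).
#' @param protection_factor fraction of the oxidative decay suppressed,
#'   in `[0, 1]`.
#' @param t_grid_min increasing time grid (minutes); default 0-30 min.
#' @param sigma_rel relative noise level.
#' @param seed integer seed or `NULL`.
#' @param label series label.
#' @return A `kinetic_trace` (columns `time`, `value`; unit attribute
#'   `"min"`, signal `"fluorescence"`).
#' @export
generate_oxidation <- function(F_init = 100, decay_rate_per_min = 0.05,
                               protection_factor = 0,
                               t_grid_min = seq(0, 30, by = 1),
                               sigma_rel = 0, seed = NULL,
                               label = "oxidation") {
  .assert(protection_factor >= 0 && protection_factor <= 1,
          "protection_factor must lie in [0, 1]", "fluorbind_param_error")
  .assert(.is_increasing(t_grid_min), "t_grid_min must be increasing",
          "fluorbind_param_error")
  .seed_rng(seed)
  v <- F_init * exp(-decay_rate_per_min * (1 - protection_factor) *
                      t_grid_min)
  v <- .apply_noise(v, sigma_rel)
  kinetic_trace(t_grid_min, v, unit = "min", signal = "fluorescence",
                label = label)
}

#' Generate a synthetic catalase activity (A240) trace
#'
#' Zero-order decomposition of hydrogen peroxide followed as a linear
#' decrease of absorbance at 240 nm, clipped at zero:
#' `A240(t) = max(A0 - rate * t, 0)`.
#'
#' @param rate_dA_per_min absorbance decrease rate (A min^-1).
#' @param A0 initial absorbance.
#' @param t_grid_min increasing time grid (minutes); default a 3-minute
#'   assay sampled every 0.1 min.
#' @param sigma_rel relative noise level.
#' @param seed integer seed or `NULL`.
#' @param label series label.
#' @return A `kinetic_trace` with signal `"absorbance"`.
#' @export
generate_activity_trace <- function(rate_dA_per_min = 0.0436, A0 = 0.5,
                                    t_grid_min = seq(0, 3, by = 0.1),
                                    sigma_rel = 0, seed = NULL,
                                    label = "activity") {
  .assert(.is_increasing(t_grid_min), "t_grid_min must be increasing",
          "fluorbind_param_error")
  .seed_rng(seed)
  v <- pmax(A0 - rate_dA_per_min * t_grid_min, 0)
  v <- .apply_noise(v, sigma_rel)
  kinetic_trace(t_grid_min, v, unit = "min", signal = "absorbance",
                label = label)
}

#' Construct a kinetic trace
#'
#' A time-indexed signal (fluorescence decay, A240 kinetics, ...).
#'
#' @param time increasing time points.
#' @param value signal values, same length.
#' @param unit time unit tag (`"min"` or `"s"`).
#' @param signal signal kind tag.
#' @param label series label.
#' @return An object of class `kinetic_trace` (a data frame).
#' @export
kinetic_trace <- function(time, value, unit = "min", signal = "fluorescence",
                          label = "") {
  .assert(length(time) == length(value), "time and value lengths differ",
          "fluorbind_param_error")
  .assert(.is_increasing(time), "time must be strictly increasing",
          "fluorbind_param_error")
  structure(data.frame(time = as.numeric(time), value = as.numeric(value)),
            unit = unit, signal = signal, label = label,
            class = c("kinetic_trace", "data.frame"))
}
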