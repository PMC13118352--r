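---
title: "Fluorescence-quenching binding analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluorescence-quenching binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorbind)
```

## The measurement and the model

A fluorescence-quenching titration follows the intrinsic (tryptophan /
tyrosine) emission of a protein at fixed concentration `P_t` while an
absorbing ligand is added in steps `L_t`. Two physical effects reduce the
measured signal: genuine quenching by complex formation, and the trivial
absorption of excitation and emission light by the ligand itself (the
inner-filter effect). The analysis chain separates them and converts the
quenching into equilibrium constants.

**Inner-filter correction.** With ligand absorbances `A_ex`, `A_em` at the
excitation and emission wavelengths and path lengths `d_ex`, `d_em` (cm),

    F_c = F_obs * 10^((A_em * d_em + A_ex * d_ex) / 2)

which assumes absorption through half the cuvette on each leg. The
correction is exact against the generator's forward model by construction,
so any residual bias downstream is attributable to the binding model, not
the optics.

**Static-quenching partitioning.** The estimator interprets the fractional
fluorescence decrement as the bound-protein fraction:

    L_b = ((F_0 - F_c) / F_0) * P_t,   L_f = L_t - L_b,   r = L_b / P_t

This is exact when complexation abolishes the fluorescence of the bound
protein completely (quench completeness q = 1) and each protein carries one
site. The generator exposes `q < 1` and `n_sites > 1` so users can measure
the estimator's bias under model mismatch, but those settings are
deliberately outside the estimator's assumptions.

**Affinity.** The Klotz double-reciprocal linearisation of an n-identical-
site isotherm,

    1/r = 1/(n * Ka * L_f) + 1/n

is fitted by unweighted OLS, matching the classical plot-based procedure:
`n = 1/intercept`, `Ka = intercept/slope`. The zero-ligand point is
excluded (its reciprocals are undefined). Reciprocal transforms amplify
noise at low occupancy, so `isotherm_nls_fit()` fits the untransformed
isotherm `r = n*Ka*L_f/(1 + Ka*L_f)` directly as a cross-check; at zero
noise the two agree to better than 0.1%, and the test suite enforces this
equivalence against an independently written `nls` call.

**Quenching mechanism.** The Stern–Volmer fit `F_0/F = 1 + Ksv*[Q]` keeps
its intercept free as a linearity diagnostic (a deviation beyond 5% warns).
`kq = Ksv/tau0` with the catalase lifetime τ₀ = 5 ns by default; values
orders of magnitude above the ~1e10 M⁻¹s⁻¹ diffusion limit indicate a
ground-state complex rather than collisional quenching — which is also why
the synthetic generator implements a static-quenching forward model only.

**Thermodynamics.** `ln Ka` against `1/T` (R = 8.314 J mol⁻¹ K⁻¹) gives
ΔH = −R·slope and ΔS = R·intercept; ΔG(T) = ΔH − T·ΔS. The package always
logs the direct route −RT·ln Ka alongside and flags disagreements beyond
0.2 kJ mol⁻¹: for published tables it is often unclear which route produced
the printed ΔG, so both are surfaced and neither is asserted as canonical.

## Companion stages

**Thermal melt.** F330/F350 ratio curves are fitted with the two-state
Boltzmann sigmoid `ratio(T) = pre + (post − pre)/(1 + exp((Tm − T)/k))`,
whose inflection is analytically at Tm. Baselines are constant in this
version: over a typical 37–81 °C scan at 1 °C steps the plateaus are short
and sloped baselines would be poorly identifiable; a sloped-baseline
variant is a listed extension. Initialisation uses plateau means and the
maximum-|slope| point of a 5-point-smoothed derivative; `nls` (port, Tm
bounded to the observed range) with a Nelder–Mead fallback. A transition
gate rejects flat curves: the plateau-mean difference (first 3 vs last 3
points) must exceed 3× the point noise estimated from lag-1 differences.
A raw range check would not work — the range of ~45 pure-noise points is
about 4.4σ, so flat noisy curves would always pass it.

**Oxidative protection.** Traces are summarised by the retained fraction
RF = value(t_end)/value(t_0) at the last common time point, and

    protection_index = (RF_treated − RF_oxidant) / (RF_untreated − RF_oxidant)

normalises against the untreated control rather than raw 1.0, because
untreated traces can drift. The index is clipped to [−0.1, 1.1] with a
warning outside [0, 1]; an untreated trace retaining no more than the
oxidant-only trace makes the index undefined (error). Note the index is a
trace-level summary, not the generator's `protection_factor`: for
exponential decays the two coincide only in the small-rate limit, so
recovery tests compare effective decay rates (log-linear slopes) instead.

**Activity.** The A240 slope over a configurable window (default: full
3-minute trace) converts via Beer–Lambert: `rate = |slope|/(ε·d)` with
ε(H₂O₂) = 43.6 M⁻¹cm⁻¹, and 1 U = 1 µmol H₂O₂ decomposed per minute in
the cuvette (`rate · V_reaction · 1e6`). Because the dilution bookkeeping
of such assays varies between labs, a per-mL-of-enzyme-sample value is
emitted alongside the per-cuvette units. `percent_of_control()` is shared
between the spectrophotometric assay and zymogram densitometry tables.

**Fourth-derivative spectra.** Savitzky–Golay weights are built from a
local least-squares polynomial (abscissa scaled to [−1, 1]; without that
scaling a 101-point design matrix at order 6 is numerically singular).
The window default is 101 points — the nearest odd width to the customary
100-point window, since symmetric smoothing requires odd length — which is
10.1 nm at the usual 0.1 nm sampling. The polynomial order defaults to 6:
orders 4–5 bias an 8 nm-wide Gaussian band's fourth derivative by 9–15%
at this window, order 6 by 0.3%, comfortably inside the 1% interior
accuracy the tests enforce. Only the interior where the full window fits
is returned; trimming (rather than NA-padding) keeps the result a valid
spectrum and avoids edge artifacts in peak reading.

## The synthetic-data generators

The generators are first-class, tested code: they define the ground-truth
world against which every estimator is validated.

* `generate_titration()` — mass-action binding (quadratic root, residual
  checked to 1e-10·P_t), static quenching `F = F0(1 − q·occupancy)`,
  van't Hoff temperature dependence `Ka(T) = exp(−ΔH/RT + ΔS/R)`
  (ΔS derived from `Ka_ref` at 298 K when not given), inner-filter
  attenuation from the ligand's molar absorptivities. Defaults are the
  study-like conditions: P_t = 0.1 µM, ladder 0–1 µM, 298/303/310 K,
  Ka(298) = 1.37e5 M⁻¹, ΔH = −17.8 kJ mol⁻¹.
* `generate_melt()` — Boltzmann sigmoid on a 37–81 °C, 1 °C grid. The
  plateau defaults (1.20 → 0.85) and steepness (1.5 °C) are typical of
  tryptophan-shift melts of folded globular proteins; no published values
  constrain them, so they were chosen once as realistic and are not
  revisited.
* `generate_oxidation()` — first-order decay with a protection factor;
  default 0.05 min⁻¹ over 30 min gives the ~78% signal loss typical of a
  strong radical challenge.
* `generate_activity_trace()` — linear A240 decrease clipped at zero;
  default 0.0436 A min⁻¹, i.e. 1 mM min⁻¹ at ε = 43.6, or 2 U in a 2 mL
  cuvette.

Noise is multiplicative Gaussian (σ_rel × signal, floored at zero) — a
desk-simple stand-in for photon statistics. The generators do **not**
model photobleaching, scattering, temperature-dependent quantum yield, or
dynamic quenching; a green recovery test therefore establishes estimator
correctness under the stated forward model, not robustness to instrument
artifacts absent from it.

## What recovery can and cannot achieve

Two information limits surfaced while validating, and the test design
follows them rather than pretending otherwise:

* **Ladder conditioning.** At Ka = 1.37e5 M⁻¹ a 0.1–1 µM ladder reaches
  only ~12% occupancy; the Klotz intercept (1/n) then lies far outside the
  data's 1/r range and is extrapolation-dominated, so small noise flips it
  negative. The demonstration pipeline therefore titrates across the
  transition (0–30 µM, occupancy to ~80%) and averages triplicates — the
  triplicate protocol being standard practice for such titrations — while
  the zero-noise closed loop at the low-occupancy conditions is verified
  separately.
* **van't Hoff leverage.** Three temperatures spanning 12 K amplify
  relative Ka errors into ΔH by roughly the ratio of R·T²/ΔT ≈ 75×:
  at 0.5% photometric noise, ΔH carries ~10% median uncertainty. The
  recovery tests bound ΔH/ΔS by 3× their OLS standard errors instead of a
  fixed percentage band; directly measured parameters (Ka per temperature,
  Tm, kinetic rates) are held to 5%.

## Numerical choices

* Peak reading is the grid maximum (no peak-shape fit), ties broken toward
  the lowest wavelength; off-grid intensity reads use linear
  interpolation — monotone, simple, testable.
* Temperatures are kelvin internally; file interfaces use °C. Energies are
  J mol⁻¹ internally, reported as kJ mol⁻¹ with 2 decimals.
* `nls` on noiseless synthetic data has zero residuals, which defeats the
  relative-offset convergence criterion; `scaleOffset = 1` restores it.
* Duplicate temperatures in a van't Hoff input are collapsed by
  geometric-mean Ka (arithmetic mean on the log scale) with a warning.
* Apparent fluorescence enhancement (F_c > F_0) is clipped to zero binding
  with a warning — noise robustness — whereas an implied bound ligand
  exceeding the total ligand is a hard data-inconsistency error.
* All generator randomness flows through a single integer seed per call;
  the demonstration pipeline derives its per-stage seeds from one master
  seed, so identical seeds give bit-identical reports (provenance,
  including input checksums and the package version, is embedded in every
  written report).

## Known limitations

* The partitioning estimator is exact only for q = 1, n = 1; cooperative
  (Hill) binding, multi-temperature global fits and fluorescence-lifetime
  analysis are out of scope.
* No ΔCp (curved van't Hoff) model; enthalpy is assumed
  temperature-independent across the narrow span analysed.
* Melt fitting assumes a single two-state transition with flat baselines.
* Densitometry enters as a numeric intensity table; image quantification
  is upstream of the package.
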