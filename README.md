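# fluorbind

Analysis of protein–ligand binding from steady-state spectroscopic
measurements, built around the classical fluorescence-quenching titration
workflow used to characterise drug binding to proteins such as catalase.

## What it does

Given a titration of a fluorescent protein (total concentration `P_t`) with
an absorbing ligand (total concentration `L_t`), the package:

1. **corrects the inner-filter effect**:
   `F_c = F_obs · 10^((A_em·d_em + A_ex·d_ex)/2)`;
2. **partitions ligand** under the static-quenching assumption:
   `L_b = ((F_0 − F_c)/F_0)·P_t`, `L_f = L_t − L_b`, `r = L_b/P_t`;
3. **fits the Klotz double-reciprocal plot**
   `1/r = 1/(n·K_a·L_f) + 1/n` by OLS, giving the association constant
   `K_a` and site number `n` (a direct nonlinear isotherm fit is provided
   as a cross-check estimator);
4. **fits the Stern–Volmer relation** `F_0/F = 1 + K_sv·[Q]`, and reports
   `k_q = K_sv/τ_0` (default τ₀ = 5 ns, the catalase lifetime) —
   `k_q ≫ 10^10 M⁻¹s⁻¹` flags static quenching;
5. **runs van't Hoff analysis** across temperatures,
   `ln K_a = −ΔH/(R·T) + ΔS/R`, and reports `ΔG = ΔH − T·ΔS` with the
   `−RT·ln K_a` cross-check.

Companion stages cover **thermal stability** (Boltzmann-sigmoid fit of
F330/F350 melt curves; Tm = inflection point), **oxidative protection**
(retained-fraction metrics and a normalised protection index from
fluorescence decay traces), **catalase activity** (A240 kinetics converted
through ε(H₂O₂) = 43.6 M⁻¹cm⁻¹ to enzyme units, plus percent-of-control
normalisation shared with zymogram densitometry), and **fourth-derivative
UV spectroscopy** (Savitzky–Golay, for resolving aromatic-residue bands).

Every data family has a seeded forward-model generator
(`generate_titration()`, `generate_melt()`, `generate_oxidation()`,
`generate_activity_trace()`) with known ground truth, so each estimator is
validated by closed-loop recovery.

## Worked example

```r
library(fluorbind)

truth <- binding_truth()        # Ka(298 K) = 1.37e5 M^-1, dH = -17.8 kJ/mol
tt <- generate_titration(truth) # noiseless titration at 298/303/310 K
run_binding_pipeline(tt)
```

```
Binding analysis report (klotz estimator)
 temperature_K     Ka n    Ksv        kq r2_binding r2_sv  dG_kJ dH_kJ dS_J_per_K
           298 137000 1 135400 2.707e+13          1     1 -29.30 -17.8       38.6
           303 121700 1 120400 2.408e+13          1     1 -29.50 -17.8       38.6
           310 103700 1 102800 2.055e+13          1     1 -29.77 -17.8       38.6
```

Each row is one temperature: the Klotz association constant `Ka` (M⁻¹) and
site number `n`, the Stern–Volmer constant `Ksv` (M⁻¹) and quenching rate
constant `kq` (M⁻¹s⁻¹; ~10¹³ here, i.e. far above the diffusion limit, so
the quenching is static), and the free-energy change per temperature with
the shared ΔH/ΔS from the van't Hoff fit — the generating truth is
recovered exactly at zero noise. Feeding published `Ka` values in directly
works the same way:

```r
vant_hoff_fit(c(298, 303, 310), c(1.37e5, 1.27e5, 1.04e5))
#> van't Hoff binding thermodynamics
#>   dH = -17.90 kJ/mol, dS = 38.40 J/mol/K  (R^2 = 0.9716)
#>   dG(298 K) = -29.34 kJ/mol  [-RT ln Ka: -29.30]
#>   ...
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates every synthetic data family from the given seed, runs all four
analysis stages end to end (`run_full_demo()`), prints the consolidated
recovered-vs-truth report, and writes the acceptance JSON to `--out`.

## Documentation

The methods vignette (`vignettes/binding-analysis.Rmd`) describes the
models, assumptions, generator defaults, numerical choices and known
limitations.
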