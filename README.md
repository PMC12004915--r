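# itcmicelle

Micellization thermodynamics from isothermal titration calorimetry (ITC)
demicellization experiments.

## The problem

Surfactant self-assembly is characterised by a handful of thermodynamic
quantities: the critical micelle concentration (CMC), the standard Gibbs
energy, enthalpy and entropy of micellization, the heat-capacity change
ΔC<sub>p,mic</sub>, and the compensation temperature T<sub>H</sub> at which
the enthalpy crosses zero. The demicellization ITC experiment measures all
of them in one design: a micellar stock at ~12× CMC is injected stepwise
into the calorimeter cell; micelles dissolve (releasing or absorbing the
demicellization enthalpy) until the cell crosses the CMC, producing a
sigmoidal heat-per-injection curve. This package is for experimentalists
and modellers who need that analysis chain as tested, scriptable code —
including a forward simulator so every stage can be validated by parameter
recovery on synthetic data — for example for salt/hydrotrope series on
zwitterionic surfactants such as dodecylphosphocholine (DPC) and
sulfobetaine (DPS) surfactants.

## The model

The enthalpogram q(C) (heat per mole of injectant vs cell concentration C)
is fitted by a Boltzmann sigmoid bridging two linear baselines,

    q(C) = (a3 + a4·C) + [(a1 + a2·C) − (a3 + a4·C)] / (1 + exp((C − a5)/a6))

The CMC is the extremum of the first derivative dq/dC of the fitted curve;
the demicellization enthalpy ΔH°demic is the baseline gap at the CMC, and
ΔH°mic = −ΔH°demic. Then, for surfactants with negligible counterion
association,

    ΔG°  = R·T·ln(cmc / c°)            (c° = 1 mol/L by default)
    ΔS°  = (ΔH°mic − ΔG°) / T
    ΔH°mic(T) = ΔCp,mic · (T − T_H)    (linear fit across temperatures)

The forward simulator supports a pseudophase model (monomer capped at the
CMC; step-like curves) and a mass-action n-mer equilibrium
nS ⇌ M<sub>n</sub>, with the monomer solving x + nKx<sup>n</sup> = C and K
calibrated so the nominal CMC is the transition midpoint. Cell
concentrations follow the overfilled-cell displacement model
C<sub>i</sub> = C<sub>syr</sub>·[1 − (1 − v/V₀)<sup>i</sup>]. Raw power
traces can be synthesised and re-integrated (`simulate_power_trace()`,
`integrate_peaks()`).

## Worked example

Simulate the standard titration (32 × 8 µL of 0.04 M stock into 1.4 mL at
298.15 K, 2% heat noise), fit it, and decompose:

```r
library(itcmicelle)
protocol <- titration_protocol()   # the defaults are exactly that protocol
model <- micellization_model("mass_action", cmc = 3.6e-3, dH_demic = 4000,
                             agg_number = 55, dilution_offset = -200)
e <- simulate_enthalpogram(protocol, model, noise_spec(0.02, seed = 7))
fit <- fit_sigmoid(e)
fit
#> Sigmoid enthalpogram fit
#>   converged : TRUE (rss = 2.253e+05)
#>   CMC       : 0.00356234 mol/L
#>   dH_demic  : 3297.12 J/mol

cmc    <- cmc_from_fit(fit)
dH_mic <- micellization_enthalpy(dH_from_fit(fit))
dG     <- gibbs_energy(cmc, 298.15)
round(c(cmc_mM = cmc * 1e3, dG_kJ = dG / 1e3, dH_mic_kJ = dH_mic / 1e3,
        minus_TdS_kJ = entropy_terms(dG, dH_mic, 298.15)$minus_TdS / 1e3), 3)
#>       cmc_mM        dG_kJ    dH_mic_kJ minus_TdS_kJ
#>        3.562      -13.974       -3.297      -10.677
```

The recovered CMC (3.56 mM) sits within ~1% of the generating 3.6 mM under
2% heat noise; ΔG° ≈ −13.97 kJ/mol follows from the CMC alone, and
−TΔS° ≈ −10.7 kJ/mol shows micellization here is entropy-driven. The
recovered |ΔH| is below the generating 4 kJ/mol because the fitted baseline
gap measures the plateau separation ΔH·(1 − cmc/C_syr), further reduced by
the post-transition tail of the mass-action model (see the vignette).

Across temperatures:

```r
s <- simulate_temperature_series(-400, 291, c(283.15, 298.15, 308.15))
heat_capacity(s)
#> Heat capacity of micellization (linear dH vs T)
#>   dCp : -400 J/mol/K (stderr 5.3e-13, n = 3)
#>   T_H : 291.00 K
```

Batch salt × temperature studies run from a YAML config via `run_study()` /
`render_report()`, or from the shell with the thin CLI in
`inst/cli/itcmicelle` (`simulate | integrate | fit | thermo | study`).

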