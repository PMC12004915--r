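---
title: "From titration heat traces to micellization thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From titration heat traces to micellization thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itcmicelle)
```

## The experiment and the model

In a demicellization experiment a concentrated surfactant stock — around
12 times its critical micelle concentration (CMC), hence almost entirely
micellar — is injected stepwise into the calorimeter cell. While the cell
concentration is below the CMC the injected micelles dissolve, and the
instrument records the associated heat; once the cell crosses the CMC the
micelles persist and only a small dilution heat remains. The integrated heat
per mole of injectant plotted against the cell surfactant concentration (the
*enthalpogram*) is therefore a sigmoid whose transition locates the CMC and
whose amplitude measures the demicellization enthalpy.

`itcmicelle` implements the full chain:

1. **Simulation** (`simulate_enthalpogram()`, `simulate_power_trace()`):
   a forward model of the titration under either a pseudophase or a
   mass-action description of micellization.
2. **Peak integration** (`integrate_peaks()`): raw power trace → per-injection
   molar heats.
3. **Sigmoid fitting** (`fit_sigmoid()`, `cmc_from_fit()`, `dH_from_fit()`):
   the normative enthalpogram model and the CMC/enthalpy extraction.
4. **Thermodynamics** (`gibbs_energy()`, `entropy_terms()`,
   `heat_capacity()`): the standard decomposition and its temperature
   dependence.
5. **Batch studies** (`run_study()`, `render_report()`): salt-by-temperature
   designs with consolidated tables.

## Concentration bookkeeping

The cell of a perfusion-type calorimeter is overfilled: each injection of
volume $v$ displaces an equal volume of cell content. The total surfactant
concentration after injection $i$ is therefore

$$C_i = C_\mathrm{syr}\,\left[1 - (1 - v/V_0)^i\right],$$

which increases strictly with $i$ and saturates at the syringe concentration
$C_\mathrm{syr}$. The naive additive-volume bookkeeping
$C_i = C_\mathrm{syr}\, i v/(V_0 + i v)$ is available behind a flag; it
agrees to well under 1% for a single injection but falls progressively
below the displacement value (about 8% by injection 32 of a standard run,
where the cumulative overfill is 18% of the cell), so the displacement form
is the default and the convention used throughout.

Moles injected are $C_\mathrm{syr} v$ per injection, with no displacement
correction on the injectant (second-order at $v/V_0 \approx 0.006$).

**Which concentration does a heat belong to?** The heat of injection $i$ is
generated while the cell moves from $C_{i-1}$ to $C_i$; it is an average of
the underlying heat curve over that interval. Pairing it with the interval
midpoint is second-order accurate, whereas pairing it with the
post-injection concentration — the convention most instrument software
prints — shifts the apparent transition right by half an injection step
(about 3% of the CMC under the standard 32-injection protocol, larger than
the accuracy the rest of the pipeline delivers). The package therefore
defaults to the midpoint (`conc_assignment = "mid"`) and retains `"post"`
as an explicit option for compatibility with instrument exports.

## The two micellization models

**Pseudophase**: micelles are a separate phase appearing sharply at the CMC;
monomer is $\min(C, \mathrm{cmc})$. Noise-free enthalpograms are step-like.

**Mass action**: an $n$-mer equilibrium $nS \rightleftharpoons M_n$ with
association constant $K$. The free monomer $x$ solves

$$x + nKx^n = C,$$

a strictly increasing function of $x$, so the root is unique;
`solve_monomer()` finds it on a log scale (the micellar term spans hundreds
of orders of magnitude across the transition at realistic aggregation
numbers, and $K$ itself would overflow double precision beyond
$n \approx 150$, so only $\log nK$ is ever formed). Transitions are smooth
and sharpen as $n$ grows.

**Calibrating $K$ from the CMC.** The $n$-mer model does not have a sharp
CMC, so a convention is needed to map a nominal CMC to $K$. The package
defines the CMC as the *transition midpoint*: the concentration at which the
marginal monomer fraction $dx/dC = 1/(1 + n^2 K x^{n-1})$ equals $1/2$, so
that half of further added surfactant enters micelles. This is the
half-amplitude point of the demicellization sigmoid in the
continuous-titration limit — precisely the quantity the fitted Boltzmann
centre estimates — and is the same midpoint convention used for melting
temperatures. It has the closed form $x_{1/2} = \mathrm{cmc}/(1 + 1/n)$,
$K = x_{1/2}^{1-n}/n^2$. With this convention the noise-free pipeline
(simulate → fit → derivative extremum) returns the nominal CMC to a fraction
of a percent at $n = 55$, so recovery tests genuinely exercise the fit
rather than a convention mismatch.

**Heat bookkeeping.** Per injection, a volume $v$ of cell content at the
pre-injection composition is expelled, $v$ of stock (partitioned as monomer
$= \mathrm{cmc}$, micellar $= C_\mathrm{syr} - \mathrm{cmc}$) is added, and
the cell re-equilibrates at $C_i$. The demicellized amount is the drop in
micellar material between the freshly mixed and re-equilibrated states, and

$$q_i = \Delta H_\mathrm{demic}\,
  \frac{\Delta n_{\mathrm{demic},i}}{C_\mathrm{syr} v}
  + q_\mathrm{dil} + \text{baseline terms}.$$

This bookkeeping conserves micellar mass exactly (delivered = retained +
expelled + demicellized), which the test suite asserts to $10^{-9}$
relative. Gaussian noise, when requested, is applied to the integrated
heats (the quantity the analysis consumes) with an explicit seed and
without touching the global RNG stream.

## Peak integration

Raw traces are rendered/consumed as differential power vs time with an
injection schedule. Each injection window runs to the next injection; the
local baseline under a peak is the linear interpolant between two *quiet
segments* — the last 10% of the preceding and of the current
inter-injection interval — which is well defined because 300 s spacing lets
the signal return to baseline. Heats are trapezoidal integrals of
(power − baseline). The quiet fraction is tunable (`quiet_fraction`); 10%
of a 300 s interval averages ~30 samples at 1 Hz. Integration is linear in
the trace and insensitive to a global linear drift by construction (the
quiet-segment means sit exactly on any linear drift). A `drop_first` flag
discards the first injection, common practice for an under-delivered first
volume, but is off by default.

## The sigmoid model and CMC extraction

The normative enthalpogram model is a Boltzmann sigmoid bridging two linear
baselines,

$$q(C) = (a_3 + a_4 C) +
  \frac{(a_1 + a_2 C) - (a_3 + a_4 C)}{1 + e^{(C - a_5)/a_6}},$$

with pre-transition baseline $a_1 + a_2 C$, post-transition baseline
$a_3 + a_4 C$, centre $a_5$ and width $a_6 > 0$. The CMC is the
concentration at which $|dq/dC|$ is extremal — the maximum or the minimum
of the first derivative, covering endothermic and exothermic runs alike —
and the demicellization enthalpy is the baseline gap at the CMC,
$(a_1 + a_2\,\mathrm{cmc}) - (a_3 + a_4\,\mathrm{cmc})$. The standard
micellization enthalpy is its negative, and the Gibbs energy follows from
the CMC alone (see below).

Numerical choices:

* **Optimizer**: bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on the
  residuals directly, tolerances $10^{-14}$; unit weights by default.
* **Initialisation**: centre at the steepest data slope, width 10% of the
  concentration span, baselines from straight lines through the first and
  last quarter of points; plus deterministic multi-start (two width
  variants and at least five jittered restarts from a fixed, documented
  seed). Best converged solution by residual sum of squares wins;
  non-convergence after all starts is an error, never a silent return.
* **Bounds**: $a_5$ within the data range; $a_6$ between one fifth of the
  median concentration step (below which the sigmoid degenerates to a step
  between samples and the parameters lose identifiability) and the full
  span.
* **Derivative extremum**: with equal baseline slopes the extremum is
  exactly $a_5$; otherwise the analytic $dq/dC$ is scanned on a 4001-point
  grid to bracket every local extremum, each is refined by golden-section
  optimisation, and ties are broken by the largest $|dq/dC|$. An extremum
  within one grid step of the data boundary sets a `boundary` flag
  (transition not bracketed) and warns.
* **Covariance**: $\hat\sigma^2 (J^\top W J)^{-1}$ from a central-difference
  Jacobian, equilibrated before inversion because the parameter scales span
  many orders of magnitude.

## Thermodynamic decomposition

With the standard concentration $c^\circ$ (1 mol L$^{-1}$ by default; a
mole-fraction convention $c^\circ = 55.5$ only shifts all values by a
constant and is available as an argument):

$$\Delta G^\circ = RT \ln(\mathrm{cmc}/c^\circ), \qquad
  \Delta S^\circ = (\Delta H^\circ - \Delta G^\circ)/T,$$

with $R = 8.314$ J mol$^{-1}$ K$^{-1}$. The counterion-free form of
$\Delta G^\circ$ is appropriate for zwitterionic surfactants, whose
counterion association is small. Every record enforces
$\Delta G = \Delta H + (-T\Delta S)$ to $10^{-9}$ relative.

Across temperatures the enthalpy is modelled as exactly linear,
$\Delta H(T) = \Delta C_p (T - T_H)$: `heat_capacity()` fits an ordinary
least-squares line, reports the slope as $\Delta C_{p,\mathrm{mic}}$ and
the root as the compensation temperature $T_H$ (undefined, not an error,
when the slope is zero; flagged `extrapolated` when more than 50 K outside
the measured range). Micellization is endothermic below $T_H$ and
exothermic above it when $\Delta C_p < 0$, the signature of the hydrophobic
effect.

## What the simulator does and does not emulate

The generator reproduces the standard protocol — 32 injections of 8 µL of
stock at ~12× CMC (0.04 M for the sulfobetaine, 0.02 M for the
phosphocholine) into a 1.4 mL cell every 300 s — with smooth mass-action
transitions, linear baselines, constant dilution offsets, Gaussian heat
noise and, for raw traces, Gaussian power pulses that integrate exactly to
each injection's heat on a linear instrument baseline.

It does **not** model instrument response deconvolution, feedback dynamics,
mixing kinetics, activity corrections at finite ionic strength (salts enter
as condition labels only), micelle polydispersity, or slow relaxation
between injections. Passing recovery tests therefore demonstrates the
correctness of the analysis chain under idealised, well-posed inputs — not
robustness to every instrumental artefact of real data.

Two behaviours of real (and simulated) mass-action data are worth knowing:

* Past the CMC the monomer keeps rising with marginal fraction $1/(1+u)$,
  and each injection carries a $(C_\mathrm{syr}-C)/C_\mathrm{syr} \sim 10×$
  micellar load, so enthalpograms have a power-law tail after the
  transition. At $n = 55$ part of this tail is absorbed into the fitted
  post-baseline slope, which biases the recovered baseline gap (the
  demicellization enthalpy) low by roughly 10% relative to the plateau gap
  $\Delta H (1 - \mathrm{cmc}/C_\mathrm{syr})$; the CMC position is much
  less affected. This is a property of the standard analysis itself, shared
  by the experimental procedure.
* For the same reason the mass-action enthalpogram approaches the
  pseudophase step only slowly in $n$: deviations just past the transition
  are still several percent of the amplitude at $n = 100$.

## Problem sizes and determinism

All tests and the acceptance script run on the study's native problem sizes:
32-injection titrations, three-temperature enthalpy series, 50–200-draw
property suites and 100-replicate noise ensembles — a few seconds in total.
Every stochastic step (noise, fit restarts, property draws) is driven by an
explicit seed, and identical seeds give bit-identical outputs, including
the CSV reports of `render_report()`, which print numbers with a fixed
format for that purpose.

## Worked example

```{r}
protocol <- titration_protocol()  # 32 x 8 uL, 0.04 M, 1.4 mL, 298.15 K
model <- micellization_model("mass_action", cmc = 3.6e-3, dH_demic = 4000,
                             agg_number = 55, dilution_offset = -200)
e <- simulate_enthalpogram(protocol, model, noise_spec(0.02, seed = 7))
fit <- fit_sigmoid(e)
cmc <- cmc_from_fit(fit)
dH_mic <- micellization_enthalpy(dH_from_fit(fit))
dG <- gibbs_energy(cmc, 298.15)
c(cmc_mM = cmc * 1e3, dG_kJ = dG / 1e3,
  minus_TdS_kJ = entropy_terms(dG, dH_mic, 298.15)$minus_TdS / 1e3)
```
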