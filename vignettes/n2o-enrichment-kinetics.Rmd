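---
title: "Gas kinetics of N2O-respiring enrichments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gas kinetics of N2O-respiring enrichments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2okin)
```

## The problem

Anaerobic digestates from biogas plants carry a small indigenous population
of N2O-respiring bacteria (NRB) — organisms that grow by reducing nitrous
oxide to N2 (2 e- per N2O). Incubating digestate anaerobically under an
N2O-supplemented He headspace selects for these organisms, and the
resulting NRB-enriched digestate acts as an N2O sink when used as
fertilizer. The evidence for what happens inside such a vial is almost
entirely *gas kinetics*: headspace concentrations of O2, N2, N2O, NO, CO2
and CH4 measured every few hours by a robotized sampler. `n2okin` turns
those measurements into the quantities of interest — true
production/consumption, respiratory electron flow, NRB growth parameters,
and the N2O emission index of amended soils — and ships a mechanistic
simulator that generates realistic vial data with known ground truth.

## Headspace accounting

Vials are stirred, so gas-liquid equilibrium is assumed instantaneous. For
a species with dimensionless Henry constant $K$ (liquid/gas concentration
ratio, $K_{cc}$), a total amount $n$ (umol) in a vial with headspace
$V_g$ and liquid $V_l$ (mL) splits as

$$C_g = \frac{n}{V_g + K V_l}, \qquad C_l = K\, C_g,$$

with $C_l$ directly in mM. The shipped defaults at 20 degC
(N2O 0.63, O2 0.033, N2 0.016, CH4 0.034, CO2 0.94 physical only,
NO 0.047) are standard literature values and user-overridable; CO2
carbonate speciation is deliberately not modelled (see Limitations).
A worked consequence: a 20 mL N2O injection at 1 atm and 20 degC is
831.4 umol, which in a 120 mL vial with 50 mL digestate equilibrates to
5.16 mM liquid N2O — the ~5 mM operating concentration of a standard
enrichment.

Each robot visit removes a fraction $f$ of the headspace and back-fills
with He. Measurements are modelled as taken immediately *before* the
dilution of the same visit. With the equilibrated total $A_j$ implied by
the measured headspace amount, the production over interval $j$ is

$$\Delta P_j = A_{j+1} - A'_j - I_j,$$

where $A'_j$ is $A_j$ after removing $f$ times the headspace share, and
$I_j$ is any injection during the interval (ideal-gas moles at the vial's
or the event's stated pressure/temperature). Liquid withdrawals shrink
$V_l$ and remove dissolved gas proportionally. The reconstruction is exact
— on simulator output with matching $f$ and equilibrium assumption the
recovered cumulative production agrees with truth to ~1e-12 relative, and
the test suite enforces 1e-6. The dilution fraction $f$ is an instrument
property that the analyst must supply; the default 0.01 is typical of
autosampler loops but should be replaced by the calibrated value.

Rates are per-interval finite differences assigned to interval midpoints,
so `rate * interval length` reproduces the cumulative increments exactly;
trapezoids are used wherever an integral is needed. An optional centered
running mean over intervals exists for noisy records (default off; see the
noise discussion below). A constant N2 leak baseline (estimated from blank
vials) can be subtracted before reconstruction.

## Electron flow and carbon mineralization

Respiratory electron flow is deduced from gas rates with fixed
stoichiometry: 4 e- per O2 consumed, 2 e- per N2 produced from N2O, and
5 e- per N for full denitrification NO3- -> 1/2 N2 (2 + 1 + 1 + 1 along
NO3- -> NO2- -> NO -> 1/2 N2O -> 1/2 N2). Nitrate is not a gas, so the
NO3- acceptor requires explicit liquid-phase bookkeeping and is otherwise
refused. Electrons routed to biomass synthesis are excluded: these are
respiratory budgets. C mineralization is the CO2 + CH4 production rate
(one C each); nitrogen recovery counts N atoms,
$(2\,\mathrm{N_2} + 2\,\mathrm{N_2O} + \mathrm{NO})/\mathrm{NO_3^-}_0$.

## The two-population growth model

The N2 production rate of an enrichment declines for ~50 h and then rises
exponentially. This is modelled as two NRB populations,

$$V_{N_2}(t) = v_0 e^{\mu t} + w_0 e^{-k t},$$

one growing exponentially from a very low initial abundance and one whose
activity is present initially but dies out. Because the rates span several
orders of magnitude, fitting uses a multiplicative error model: ordinary
least squares on $\log V_{N_2}$ with positivity enforced by optimizing
log-parameters (Levenberg-Marquardt via `minpack.lm`). Starting values
come from log-linear regressions on the two sides of the rate minimum;
degenerate records dispatch to reduced models (pure exponential — where
$\mu$ is exactly the closed-form log-linear slope — or decline-only, with
$\mu$ flagged unidentifiable). The identifiability guard is
covariance-based: $\mu$ is reported as poorly constrained whenever its
relative standard error exceeds 50%, which catches records truncated
before the growth phase dominates.

With a constant cell yield $Y$ (cells per fmol e-) the fit translates into
cells: during balanced growth the cell-specific electron flow is
$V_e = \mu / Y$, and the growing population's initial density is

$$N_0 = \frac{2 v_0 \times 10^9}{V_e}\ \text{cells mL}^{-1}.$$

The gas data fix $\mu$ and $v_0$ but not the absolute cell scale, so one
anchor is required: $V_e$ itself (e.g. the ~5 fmol e- cell^-1 h^-1
characteristic of these enrichments), $Y$, or an independent cell count
(e.g. ddPCR) at a known time. The exponential window ends at the first
time where the modelled growing population carries >= 90% of the total
rate *and* the observed curve has flattened (local slope of
$\log V_{N_2}$ below $\mu/2$); beyond it, density grows as
$dN/dt = Y \times$ (growing population's electron flow), integrated
trapezoidally — substrate limitation is represented by this switch, not by
adding a Monod term to the fit, which the rate data cannot constrain.

## The N2O index

For soil incubations the emission proxy is

$$I_{N_2O} = 100 \times
  \frac{\int_0^T \mathrm{N_2O}(t)\,dt}
       {\int_0^T [\mathrm{N_2O}(t) + \mathrm{N_2}(t)]\,dt},$$

on headspace molar amounts. The area-ratio form is used because the index
is defined over a period $0$–$T$; a point-in-time ratio would need no
period. Counting both gases as umol N (factor 2 each) cancels in the
ratio. $T$ is anchored where a given fraction of the initial NO3--N has
been recovered as gaseous N (N2 + N2O + NO): $T_{40}$ and $T_{100}$. The
recovery anchors include NO, but the index itself uses only N2O and N2.
Two deliberate choices: headspace-only amounts are the default (total
amounts sit behind no flag — pass totals to `n2o_index()` for a
sensitivity check), and an instantaneous-ratio variant is available via
`method = "instantaneous"`. Crossing times interpolate linearly, with a
1e-9 tolerance on the target fraction because kinetic tails approach
complete recovery asymptotically — an exact test against 1.0 would never
fire on noise-free data.

## The simulator

`simulate_enrichment()` integrates a deliberately small mechanistic model:
a fermenting consortium supplies electron equivalents to a single
substrate pool at rate `r_h`; the supply is product-inhibited
($r_h / (1 + (S/S_{cap})^8)$) so the pool saturates somewhat above
$S_{cap}$ when its consumers stall — the thermodynamic behaviour of
syntrophic fermentation, and what produces the observed transient
VFA/H2 accumulation while methanogenesis is inhibited. Methanogens
consume 8 e- per CH4 with Monod kinetics, reversibly inhibited by liquid
N2O ($K_I/(K_I + [\mathrm{N_2O}])$); NRB respire N2O with Michaelis
dependence on both N2O and substrate and grow with constant yield
($Y V_e^{max} = \mu^{max}$ enforced at construction); a declining
activity $w_0 e^{-kt}$ consumes N2O without growing. CO2 follows from the
substrate stoichiometry (acetate-like, 4 e- per C), which makes
cumulative CO2 + CH4 equal the substrate consumed in C units — the
conservation oracle used in the tests. The robot samples on a fixed
schedule (observation, then dilution, then a trigger check that re-injects
20 mL N2O when liquid N2O falls below 2 mM).

Default calibration (chosen once, from the observed features of mesophilic
digestate enrichments, and documented as calibration rather than ground
truth): $\mu^{max} = 0.1$ h^-1, $V_e^{max} = 5$ fmol e- cell^-1 h^-1,
$N_0 = 2.5 \times 10^3$ cells mL^-1, $w_0 = 0.014$ umol N2 mL^-1 h^-1
and $k = 0.03$ h^-1 (placing the rate minimum near 50 h),
`r_h` = 1.6 umol e- mL^-1 h^-1 (eight times the 0.2 umol CH4 mL^-1 h^-1
control methane rate), $K_I = 0.05$ mM (near-total inhibition at 5 mM,
matching the observed on/off behaviour; no quantitative constant is
published), N2O half-saturation 2 uM (Nos is a high-affinity enzyme), and
substrate half-saturation 0.05 umol e-eq mL^-1 (tens of uM acetate
equivalents). Under these defaults the simulation reproduces the study
conditions: density reaches ~1.6e8 cells mL^-1 at 110 h and ~3.6e9 at
215 h, the first N2O re-injection falls at ~117 h, and the full analysis
pipeline recovers $\mu^{max}$ within 1% (noise-free).

`simulate_soil()` is simpler: Michaelis O2 respiration, then a four-step
denitrification cascade gated by a steep Hill switch on liquid O2
(threshold 0.5 uM, exponent 4). The NO3- and NO2- steps use Michaelis
kinetics so the pools empty in finite time — with pure first-order decay
100% recovery is only approached asymptotically and $T_{100}$ would not
exist. The N2O -> N2 step is scaled by `nos_capacity`, the single knob
standing in for the soil's Nos synthesis capacity (pH effects enter only
through it). All N pools are tracked in umol N, so mass balance is exact
by construction.

### Numerical choices

Integration is fixed-step classical RK4 — chosen over adaptive schemes for
bit-reproducibility — with steps aligned exactly to the sampling schedule
and discrete events applied between steps. The enrichment default step is
0.005 h: once NRB demand exceeds supply, the substrate pool settles into a
quasi-steady state whose relaxation rate grows with cell density (up to
~300 h^-1 at the final density), and the step must resolve it; halving
the step changes every cumulative output by less than 1e-9 relative. The
soil default is 0.02 h (the Hill gate transition is the fastest scale).
Small negative gas pools (< 1e-6 umol, RK4 undershoot) are clamped to
zero; larger ones abort with an instability diagnostic. Observation noise
is multiplicative log-normal on the pre-dilution headspace amounts
(gas-chromatography-like, default sd 5%), seeded explicitly; outputs are a
pure function of (scenario, seed), and the RNG state of the session is
restored afterwards.

### What the simulator does and does not emulate

It emulates: the declining + growing two-population N2 kinetics,
reversible CH4 inhibition by N2O, substrate supply from a fermenting
consortium with transient intermediate accumulation, periodic He back-fill
dilution, trigger-fired N2O re-injection, and multiplicative measurement
noise. It does not emulate: gas-liquid mass-transfer kinetics (equilibrium
is instantaneous; defensible for stirred vials, not for static ones),
carbonate chemistry, pH dynamics, septum leakage physics (only a linear
N2 baseline), distinct VFA/H2 pools (a single electron-equivalent pool
stands for all intermediates), N2O-driven methane oxidation, or
multi-species community dynamics. Passing tests therefore demonstrate
correctness of the *accounting and inference machinery* under the model's
assumptions, not fidelity of any particular digestate.

## Noise and the rate pipeline

Rates are first differences of reconstructed cumulative amounts, so their
absolute noise scales with the *accumulated* amount while the signal is
only the per-interval increment. With 5% measurement noise the raw 3 h
rates in the valley of the two-population curve are noisy enough that a
direct log-space fit degrades badly. The parameter-recovery study
(`parameter_recovery_study()`) therefore smooths the interval rates with a
centered 5-interval running mean before fitting: smoothing a sum of
exponentials multiplies each component by a constant
($\sinh(\lambda \Delta)/(\lambda \Delta)$-type) factor — about +0.9% on
the growing amplitude at $\mu = 0.1$ and 15 h — so $\mu$ and $k$ are
essentially unbiased while the per-point noise drops by $\sqrt 5$. Under
the default conditions (5% noise, 100 replicates) the median relative
errors are ~4% for $\mu$, ~11% for $k$, and ~0.16 on
$\log_{10} N_0$. The fit window for enrichment records ends at 105 h,
before substrate limitation flattens the rate curve and the
two-population abstraction stops applying.

## Problem sizes

The shipped defaults — 215 h enrichments sampled every 3 h (72
observations), 160 h soil incubations sampled every 4 h, 100-replicate
recovery studies — match the incubation designs the package targets and
keep any single analysis under a few seconds on one core.

## Limitations

* CO2 accounting is physical solubility only; at digestate pH 7.6–8.2
  most dissolved inorganic carbon is carbonate, so dissolved CO2 — and
  hence C mineralization — is underestimated. Flagged, not corrected.
* NO3-/NO2- are liquid-phase book entries inferred from the gas-phase N
  budget, mirroring how denitrification progress is deduced from gases.
* Triplicate vials are analysed independently and summarized as
  mean ± sd; no hierarchical model, no Bayesian posterior.
* The statistical comparison of I_N2O between treatments (ANOVA + Tukey)
  is out of scope; the report exposes per-vial values for any external
  tool.
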