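---
title: "The gain–risk stomatal optimisation model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gain–risk stomatal optimisation model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profitmax)
```

## The model

`profitmax` simulates leaf gas exchange and plant water status by assuming
stomata behave as instantaneous profit maximisers: at every timestep the
plant selects the operating point that maximises a normalised carbon gain
minus a normalised hydraulic cost,

$$\mathrm{profit} = \frac{A(\Psi_\mathrm{leaf})}{A_\mathrm{max}}
 - \frac{k_{i\max} - k(\Psi_\mathrm{leaf})}{k_{i\max} - k_\mathrm{crit}},$$

both terms in $[0,1]$. The hydraulic backbone is a cumulative-Weibull
vulnerability curve for whole-plant (soil-to-canopy) conductance per unit
leaf area,

$$k(\Psi) = k_\mathrm{max}\, e^{-(|\Psi|/b)^c},$$

with sensitivity $b$ (MPa), shape $c$ (–) and a fixed
$k_\mathrm{max} = 1.5$ mmol m$^{-2}$ s$^{-1}$ MPa$^{-1}$ for every species
(species-level measurements of $k_\mathrm{max}$ are unavailable; the
sensitivity engine exposes it as an override precisely because this is the
model's least-constrained constant). $k_{i\max} = k(\Psi_\mathrm{soil,w})$ is
the conductance the plant could realise at the current root-zone potential,
and $k_\mathrm{crit} = 0.05\,k_\mathrm{max}$ defines hydraulic failure;
percent loss of conductivity is $\mathrm{PLC} = 100\,(1 - k/k_\mathrm{max})$.

Rather than co-optimising stomatal conductance and intercellular CO₂, the
search runs over a uniform grid of $n = 1000$ candidate intercellular CO₂
values between the photorespiratory compensation point $\Gamma^*$ and
leaf-surface CO₂ $C_s$ (a spacing of roughly 0.35 µmol mol⁻¹ at ambient
CO₂). Each candidate maps to an assimilation rate via the Farquhar model, a
stomatal conductance via Fick's law $g_{sc} = A/(C_s - C_i)$ (water vapour:
$g_{sw} = 1.57\,g_{sc}$), a transpiration rate
$E = g_{sw}\,\mathrm{VPD}/P_\mathrm{atm}$, and a leaf water potential from
the steady-state supply function

$$E = k(\Psi_\mathrm{leaf})\,(\Psi_\mathrm{soil,w} - \Psi_\mathrm{leaf}).$$

Candidates whose transpiration exceeds the supply maximum $E_\mathrm{crit}$,
or whose conductance falls below $k_\mathrm{crit}$, are infeasible (both
gates are individually switchable in `optimiser_settings()`, since either
alone defines a defensible failure boundary). If no candidate achieves
positive profit — at night, or when the soil itself is beyond the critical
potential — the stomata close: $g_{sc} = 0$, $E = 0$,
$\Psi_\mathrm{leaf} = \Psi_\mathrm{soil,w}$, $A = -R_d$. Cavitation carries
no memory between steps: $k$ depends only on the current potential, i.e.
full recovery after rain is assumed.

### Assumptions worth stating plainly

* One water potential represents the whole pathway: xylem and leaf
  potentials are not separated.
* No cuticular conductance: a closed leaf loses no water.
* No non-stomatal downregulation of photosynthetic capacity under drought.
* Big-leaf canopy: mean absorbed PAR per unit leaf area follows Beer's law
  with extinction coefficient 0.5, in place of a sunlit/shaded two-leaf
  scheme. This affects absolute fluxes, not the optimiser's logic.
* Leaf temperature defaults to air temperature ("isothermal"); an iterative
  leaf energy balance (Newton iteration, 5-iteration cap, 0.01 °C tolerance)
  is available because the VPD seen by the leaf is sensitive to this choice.

## Numerical choices

**Root-finding.** The supply function is inverted by bracketed bisection on
the ascending branch, between the potential of the supply maximum (found by
golden-section search) and the soil potential; the less-negative root is the
physically stable one. The default tolerance (10⁻⁸ MPa in the simulator's
inner solve) keeps the steady-state residual
$|E - k(\Psi)(\Psi_\mathrm{soil,w}-\Psi)|$ below 10⁻⁶ mmol m⁻² s⁻¹.

**Tie-breaking.** Among equal-profit candidates the least-negative
$\Psi_\mathrm{leaf}$ (hydraulically safest) wins, making output
deterministic.

**Negative assimilation.** Candidates with $A \le 0$ are retained with zero
carbon gain and zero conductance; they can never win while any candidate has
positive profit.

**Biochemistry.** The Farquhar implementation uses a single frozen constant
table (`PHOTOSYN_CONSTANTS`): Bernacchi-type Arrhenius responses for
$K_c, K_o, \Gamma^*, R_d$ and peaked Arrhenius for $V_{c\max}$ and
$J_{\max}$; $J_{\max,25} = 1.67\,V_{c\max,25}$,
$R_{d,25} = 0.015\,V_{c\max,25}$; electron transport from a non-rectangular
hyperbola (curvature 0.7, quantum yield 0.26); no TPU limitation. Only
$V_{c\max,25}$ is species-specific. These ratios are declared package
defaults, not species measurements.

## The trait registry

`load_species_registry()` packages hydraulic and photosynthetic traits for
15 canopy-dominant eucalypts. The Weibull parameters $(b, c)$ are
authoritative — the curve consumes nothing else — while the tabulated
P12/P50/P88 thresholds are stored as metadata. Inverting the curve
reproduces P12 and P50 within 0.01 MPa (the table's printed resolution) for
every species; P88 is deliberately *not* validated, because for several
species the tabulated P88 is not Weibull-consistent with $(b, c)$ (e.g.
*E. camaldulensis*: the curve implies −4.87 MPa against a tabulated −4.15).
`fit_bc_from_pxx()` therefore inverts the parameterisation from P12 and P50
only. Species without a specific $V_{c\max,25}$ receive the cross-species
mean 86.88 µmol m⁻² s⁻¹.

## Soil water store

Six layers to 4.6 m depth (0.1, 0.25, 0.65, 1.0, 1.3, 1.3 m), vertically
uniform texture by default, Campbell retention
$\Psi_s = \psi_e(\theta/\theta_\mathrm{sat})^{-b}$ and conductivity
$K = K_\mathrm{sat}(\theta/\theta_\mathrm{sat})^{2b+3}$. The root-zone
potential seen by the optimiser is the conductance-weighted mean: weights
proportional to root fraction × layer conductivity, so uptake shifts from
the root-dense surface to deeper, wetter layers as the profile dries. Root
fractions decay exponentially with depth (e-folding 0.5 m, configurable).

A full Richards solver is deliberately replaced by a tipping-bucket cascade:
extraction is distributed by the uptake weights, infiltration fills layers
from the top (saturation excess becomes runoff), and each layer passes
$\min(K(\theta), \text{water above field capacity})$ downward with free
drainage at the bottom. The optimiser consumes only
$\Psi_\mathrm{soil,w}$, so the store needs to be mass-conservative and
directionally correct rather than a PDE; mass balance is exact to numerical
precision at every step. Soil evaporation is omitted — water leaves only by
transpiration, runoff and drainage — which biases the store wet in open
canopies; simulated droughts are therefore conservative in that respect.
The profile initialises at field capacity (the Campbell curve at −0.01 MPa),
i.e. drained to equilibrium.

## Synthetic forcing and what it does not emulate

`generate_forcing()` produces regular 3-hourly weather: clear-sky shortwave
from solar geometry scaled by a daily transmissivity (cloudier on rain
days); temperature as seasonal + diurnal harmonics with AR(1) daily
anomalies; vapour pressure from a bounded relative-humidity process, capped
so RH never exceeds 1; rainfall as Bernoulli rain days (default frequency
0.25) with gamma-distributed depths (shape 0.75) tuned to the target mean
annual precipitation; constant pressure and CO₂ (400 µmol mol⁻¹). A
"drought block" suppresses rain-day frequency by a configurable factor over
chosen years. Everything is reproducible from one seed.

This emulates the statistical texture of sub-daily station weather, not any
particular observed sequence: no synoptic rain systems, no heatwave–drought
correlation, no trends. Passing tests on this forcing demonstrate the
model's internal contracts (orderings, conservation, determinism) — they do
not validate the model against observed fluxes or mortality.

The scenario test fixture uses a subhumid site (mean annual precipitation
900 mm, LAI 1.5 — representative woodland values for the wetter part of
these species' ranges) with a 30% rainfall deficit in simulation years 2–3,
matching the severity scale of a strong observed meteorological drought.
Under these conditions the control run reaches partial hydraulic stress
(maximum PLC well below failure), which is the regime where the scenario
contrasts are informative; a substantially harsher fixture drives every
scenario to the failure boundary, where orderings degenerate to ties.

## Scenarios, sensitivity and diagnostics

`run_scenarios()` produces the control, a uniform 20% precipitation
reduction (`precip_scale = 0.8`), and the reduced precipitation combined
with doubled CO₂. `sensitivity_suite()` perturbs, one at a time: the
critical-conductance fraction (doubled), $k_\mathrm{max}$ (halved), LAI
(+40%), and LAI +40% with doubled CO₂. `summarise_run()` reports the
minimum leaf water potential, maximum PLC, and calendar-month mean leaf
water potentials with counts of months below the species' P50 (all steps by
default; a daylight-only switch exists because the appropriate aggregation
is genuinely ambiguous — night steps sit at the soil potential and dilute
the signal). `range_summary()` aggregates many sites: per-species
distributions of minimum potential, the proportion of occupied sites with
any monthly mean below P50, and per-site equal-weight means of maximum PLC
across the species present.

Expansive simulations in the test-suite use three simulated years at a
single site — enough for spin-up, a wet year and a two-year drought — and
the spin-up policy repeats the first forcing year until root-zone storage
changes by less than 0.1 mm between cycles (at most 10 cycles).

## The Standardised Precipitation Index

`spi()` implements the gamma-fit construction: rolling `window`-month sums
(default 6), a gamma distribution fitted to the baseline sums by maximum
likelihood (`MASS::fitdistr`) with the Thom moment approximation as a
fallback, zero-precipitation sums handled by the mixture CDF
$H(x) = q + (1-q)G(x)$, and the probability mapped through the standard
normal quantile. By construction SPI over the baseline has mean ≈ 0 and
SD ≈ 1, and is invariant to rescaling the whole series (gamma is a scale
family) — both properties are tested.

## Known limitations

* The optimiser retains marginally open stomata at very negative leaf
  potentials (small profit persists as long as carbon gain slightly exceeds
  cost). This is a documented property of the scheme, surfaced in the
  diagnostics, not patched away; raising `kcrit_fraction` strengthens
  stomatal control.
* Absolute fluxes inherit the big-leaf and isothermal simplifications;
  comparisons should focus on contrasts between runs, which share those
  simplifications.
* No groundwater access: riparian species (notably *E. camaldulensis*) will
  look more drought-exposed than they are.
* Prescribed LAI: no drought defoliation, no CO₂-driven leaf-area growth;
  the LAI sensitivity experiments bracket this uncertainty instead.
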