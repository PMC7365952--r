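---
title: "A lumped-parameter model of microbial heat and dry matter loss in aerated corn stover storage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of microbial heat and dry matter loss in aerated corn stover storage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoverheat)
```

## The problem

Corn stover — the stalks, leaves and cobs left after grain harvest — is a
cellulosic biofuel feedstock that is typically stored for months between
harvest and conversion. During storage, aerobic microbial communities
respire the carbohydrate fraction, releasing CO~2~, water and heat. The
resulting *dry matter loss* (DML) erodes conversion yields, and the
self-heating interacts with the microbes' own temperature response:
respiration warms the pile, warming accelerates respiration up to an
optimum, and beyond it activity collapses. `stoverheat` implements a
lumped-parameter (single thermal node) dynamical model of this coupled
system at the scale of an instrumented laboratory storage reactor (~100 L,
~7 kg dry matter, controlled aeration, a temperature-controlled water
jacket, off-gas CO~2~ monitoring and daily condensate collection), together
with the calibration and validation workflow used to confront the model
with such reactors, and a synthetic-data generator so the full loop is
testable without access to any experimental campaign.

## The model

### Bi-phasic substrate kinetics

The degradable substrate is split into pools, one per growth phase.
Storage reactors of this type show *diauxic* (bi-phasic) behaviour — a
second respiration burst after an intermediate lag, classically explained
by sequential consumption of two carbon sources — so the default
configuration carries two pools. Each pool degrades by first-order
kinetics on its remaining mass, modulated by two dimensionless
environmental factors:

$$\frac{dS_i}{dt} = k_{d,i}\, f_T(T)\, f_M(M)\, (S_{0,i} - S_i),
\qquad t \ge t_{\mathrm{lag},i},$$

where $S_i$ is the cumulative mass degraded by phase $i$ (g), $S_{0,i}$
its pool size, and $k_{d,i}$ its specific degradation rate (s^-1^). A
phase is inert before its lag time. The total degradable pool is expressed
as a fraction of loading dry matter (`s0_fraction`, default 0.05,
consistent with the ~5% dry matter losses these reactors exhibit) and the
calibrated split between the two phases is 50.1% / 49.9% with an 11.2-day
lag for the second phase.

The temperature factor is the cardinal temperature model with inflection
(CTMI), parameterized by a minimum, optimum and maximum temperature:

$$f_T(T) = \frac{(T - T_{max})(T - T_{min})^2}
{(T_{opt}-T_{min})\left[(T_{opt}-T_{min})(T-T_{opt}) -
(T_{opt}-T_{max})(T_{opt}+T_{min}-2T)\right]}$$

The raw rational expression is negative or undefined outside
$[T_{min}, T_{max}]$, so `temperature_factor()` clamps it to 0 there and
clips to $[0,1]$ inside, standard CTMI practice. One subtlety: the CTMI
shape is smooth and monotone below the optimum only when the optimum lies
in the upper half of the cardinal range
($T_{opt}-T_{min} > T_{max}-T_{opt}$); outside that region the expression
has a pole below the optimum and the clip merely keeps the factor bounded.
Every parameter set reported for this system satisfies the condition, and
the property tests sample their random triples accordingly (with a
separate boundedness check for ill-shaped triples). The moisture factor is a
Monod half-saturation form on wet-basis moisture content,
$f_M = M / (0.25 + M)$, with the 0.25 half-saturation constant taken from
dry-matter-loss experiments across the 20–50% moisture range. Moisture
follows a prescribed linear drying schedule between the measured initial
and final contents; it is *not* a dynamic state coupled to evaporation,
because the reactors' drying trajectories are well approximated as linear
and treating them as inputs keeps the state vector small.

CO~2~ release and microbial heat are strictly proportional to substrate
degraded: $CO_2 = y_{CO_2} S$ and $Q_m = y_m S$ cumulatively, with
$y_{CO_2} = 1.44$ g/g (experimentally determined, close to but
deliberately not replaced by the glucose stoichiometric 264/180 ≈ 1.47)
and $y_m = 9.7$ J/g (calibrated). Both by-products are reconstructed
algebraically from the substrate states rather than integrated as extra
ODE states — the proportionality is then exact at every output time, which
the tests assert to machine precision.

### The thermal node

A single energy balance governs the biomass temperature $T$:

$$C_{th}\frac{dT}{dt} = Q_m + Q_k + Q_h + E$$

with all flows signed relative to the biomass node (positive = warming):

* **Microbial heat** $Q_m = y_m \sum_i dS_i/dt$ (W).
* **Conduction to the water jacket**
  $Q_k = (K/L)\,A\,(T_{jacket} - T)$, with calibrated conductivity
  $K = 10.1$ W/m/K, heat-flux area $A = 0.6$ m^2^ and characteristic
  length $L = 0.08$ m.
* **Convection to ambient air** $Q_h = h\,A\,(T_{amb} - T)$, with $h$
  estimated from the turbulent flat-plate correlation
  $Nu = 0.0296\,Re^{0.8} Pr^{1/3}$ at fixed ~300 K air film properties.
  The air velocity is the volumetric airflow divided by a configurable
  cross-section (default 0.07 m^2^); at these airflows the correlation
  gives $h$ far below the experimentally reported 2.2 W/m^2^/K, so
  `thermal_params(h_conv_override =)` lets users pin $h$ directly. Either
  way the term is small relative to conduction.
* **Evaporation** $E = -h_{vap}\,\dot m_w$ with $h_{vap} = 2257$ kJ/kg.
  When no measured condensate series is supplied, the water removal rate
  is the constant rate implied by the linear drying schedule
  (`default_evaporation_rate()`); a measured series of daily condensate
  masses is converted to piecewise-constant rates.

The capacitance is the wet biomass plus the stainless-steel reactor mass,
$C_{th} = m_{wet}\,c_{wet}(T, M) \cdot 1000 + \rho_{ss} V_{ss} c_{ss}$,
with $c_{wet}$ from a moist-wood correlation on absolute temperature. Two
details deserve a note. First, the temperature unit of the specific-heat
correlations is not self-evident; in kelvin the dry correlation gives
~1.25 kJ/kg/K at room temperature, inside the 1.2–1.5 kJ/kg/K literature
range for dry wood (and the 20%-moisture value lands in the 1.7–2.3
range), while in Celsius it gives a physically impossible ~0.2, so the
package evaluates them in kelvin. Second, the literal density-times-volume
capacitance basis (832–954 kg/m^3^ bulk density times the 0.074 m^3^
vessel) implies ~65 kg of biomass where only ~10 kg wet matter was
loaded; the default basis is therefore the wet loaded mass, with
`capacitance_mode = "density_volume"` retained for literal reproduction
of the density-based definition.

### The water jacket boundary condition

Each reactor is surrounded by a circulating water jacket whose controller
tracks the internal temperature with a −0.5 K offset once the internal
temperature exceeds 20 °C; below that threshold the jacket idles at its
floor (20 °C). `jacket_temperature()` implements this rule literally, and
`simulate_reactor()` uses it whenever no measured jacket series is
supplied. A measured series, when available, always takes precedence —
this matters, because under the calibrated heat yield of 9.7 J/g the
*total* microbial heat over a storage campaign is a few kJ against a
capacitance of ~56 kJ/K: microbial heat alone cannot drive the node from
13 °C to the ~40 °C actually observed in such reactors. In the closed
loop the simulated node instead settles just below the controller
threshold. The experimental thermal trajectories are, in effect, driven
by the jacket (which in turn was slaved to the measured biomass
temperature); simulating them faithfully therefore requires the jacket
series as an input, exactly as the calibration workflow uses it.

## The simulator

The state vector is $[T, S_1, \dots, S_n]$. Integration uses the adaptive
Dormand–Prince 4(5) pair (deSolve's `ode45`) with relative tolerance
10^-6^ and absolute tolerance 10^-8^ by default, a 1-hour maximum step
(so interpolated forcings are always resolved), and dense output onto a
5-minute grid matching the thermocouple logging cadence. Integration is
restarted at each phase's lag time so the stepper never straddles that
discontinuity. Observed jacket temperatures are interpolated piecewise
linearly and condensate volumes as piecewise-constant rates, both with
constant extrapolation beyond the last sample.

Two numerical properties are enforced by test rather than assumed: the
adaptive solution agrees with a 1-second fixed-step classical RK4
integration to within 10^-5^ relative on a 5-day bi-phasic scenario, and
a trapezoidal audit of the outputs balances the integrated net heat flow
against the capacitance-weighted temperature change to within 0.1% of the
total heat turnover (on a 60-second output grid; the audit is
grid-limited by the initial exponential transient, whose time constant
$C_{th} L / (K A) \approx 12$ min must be resolved by several output
intervals).

`solver_options(fixed_step =)` switches to classical RK4 on a fixed grid.
This is deliberately *not* the default for forward simulation, but it is
the default inside calibration (600 s), for a reason described below.

## Calibration

`calibrate_reactor()` estimates named parameters (per-phase cardinal
temperatures, degradation rates, lag, pool split, yields, conductivity,
area, stainless volume, pool fraction) by weighted nonlinear least
squares against observed temperature and substrate series, the latter
usually derived from off-gas CO~2~ via `substrate_from_offgas()`
(baseline subtraction, ideal-gas conversion at 44.01 g/mol, trapezoidal
integration, division by $y_{CO_2}$). Residuals from both channels are
concatenated with per-channel weights (default: inverse standard
deviation of each observed series, user-overridable — the channels' units
are incommensurable and no principled common scale exists without
replicate-level uncertainty estimates, which these instruments do not
report).

The optimizer is Levenberg–Marquardt (`minpack.lm::nls.lm`) with the
parameter tolerance 10^-6^. Classic LM is unconstrained, so box bounds
(e.g. $T_{opt} \in [35, 55]$ °C) are honoured by running LM in a
transformed space mapped bijectively onto each box: identity for
unbounded parameters, a log map for half-open intervals, a scaled
logistic for closed ones. Four further numerical choices matter in
practice, and all are visible (and overridable) in the function
signature:

1. **Fixed-grid residuals.** The residual function integrates on a fixed
   600-second RK4 grid instead of the adaptive stepper. Adaptive step
   selection makes the discretization error a *discontinuous* function of
   the parameters; for parameters whose true effect on the observables is
   small, finite-difference sensitivities computed through an adaptive
   solver measure step-selection noise rather than physics. On a fixed
   grid the error is smooth in the parameters and differences out.
2. **Explicit finite-difference Jacobian.** A forward difference with a
   fixed step of 0.01 in the transformed space (i.e. ~1% on the natural
   scale) replaces the optimizer's machine-epsilon-scaled default, which
   falls below integration noise.
3. **Identity trust-region scaling.** The bound transforms already place
   every parameter on a comparable O(1) scale; minpack's column-norm
   auto-scaling would undo this and leave weakly identified directions
   effectively unpenalized.
4. **Weak ridge damping** (`prior_sd`, default 10 in transformed space).
   Directions the data do not constrain at all otherwise drift without
   limit once the LM damping shrinks. The default width contributes
   curvature 10^-2^ — far below that of identified parameters here
   (order 10–100) and far above that of unidentified ones (order
   10^-8^) — so identified estimates are essentially unaffected while
   unidentified ones stay at their baseline. Set `prior_sd = NULL` for
   pure least squares.

### What is and is not identifiable

Under the calibrated parameter regime, the heat yield $y_m$ is
*structurally unidentifiable* from temperature and substrate series: its
effect on the simulated temperature is of order 10^-4^ K, four orders of
magnitude below RTD noise. The package does not pretend otherwise — with
the default ridge the estimate simply stays at its baseline, and with
`prior_sd = NULL` it wanders along an essentially flat cost valley, which
is the honest behaviour of unregularized least squares on an unidentified
direction. The degradation rate and optimum temperature, by contrast, are
well identified *provided the thermal trajectory sweeps a range of
temperatures*: noiseless self-consistency runs recover them to better
than 0.1%, and the seeded noisy recovery study (20 replicates, 0.2 °C
temperature noise, 1% substrate noise) recovers $k_d$ within ~2% and
$T_{opt}$ within ~0.4 °C. On a near-isothermal trajectory $k_d$ and
$T_{opt}$ would be confounded through their product — one reason the
synthetic generator's default scenario drives the reactor through a
13 → 40 → 20 °C excursion.

Validation uses two error metrics: the mean absolute temperature error
(note: this quantity is conventionally labelled a "mean absolute
*relative* error" in the composting literature even though no
normalization is applied; `mean_absolute_error()` implements the
unnormalized formula literally and keeps the honest name), and the
relative error of the predicted dry matter loss at quasi-steady state,
defined here as the final observed time point.

## The synthetic-data generator

`generate_dataset()` produces observation sets with known ground truth on
realistic measurement grids: biomass temperature every 5 minutes
(thermocouple cadence), CO~2~-derived substrate hourly (gas chromatograph
cadence), condensate daily. Noise is additive, independent and Gaussian
per channel (the instruments' error structure is not reported in any more
detail; this is the simplest defensible model), with defaults of 0.2 °C
for temperature and 1% of the final value for substrate; noisy masses are
clipped at zero. Every stochastic output is reproducible bit-for-bit from
the seed, which the test suite asserts.

The default jacket mode, `"driven"`, synthesizes a smooth jacket program
— the controller floor of 20 °C plus a gamma pulse peaking at 40 °C near
day 8 — and supplies it to the simulator as a measured series, emulating
the thermal trajectory of an instrumented campaign (initial warm-up,
self-heating phase, slow decay) for the reason given above: a closed-loop
jacket cannot produce that excursion under the calibrated heat yield. The
peak value and timing are configurable; `jacket_mode = "controller"`
selects the closed-loop model instead, under which the node settles just
below the 20 °C activation threshold.

What the generator deliberately does **not** emulate: gas-chromatograph
drift, sensor dropout, the spatial thermocouple array (the model is
single-node by design), moisture-evaporation feedback, or oxygen
limitation. Tests passing against synthetic data therefore demonstrate
the internal consistency of the model, the integrator and the estimation
machinery — not that the model captures every process in a real stack.

## Problem sizes in the test suite

The shipped tests run the forward model on 2–5-day horizons with hourly
or 5-minute output, the noiseless calibration on a 12-day horizon, and
the noisy recovery study on the full 34.1-day benchmark configuration
with 20 seeded replicates (hourly grids for both channels during
fitting). These sizes were chosen so each check exercises the relevant
dynamics — lag onset, thermal excursion, pool exhaustion — at the
smallest scale that does so.

## Known limitations

* The model is a single thermal node; spatial gradients (which real
  reactors show, with faster diffusion near the top flange) are outside
  its scope, and the calibrated $K$, $A$ and $V_{ss}$ absorb those
  effects rather than resolve them.
* $y_m$ is carried as a calibratable parameter for completeness but is
  unidentifiable from the available observables (see above); its
  calibrated literature value is itself three orders of magnitude below
  calorimetric values for glucose in soil, which suggests it compensates
  for structure missing from the energy balance.
* The bi-phasic pool split and lag calibrated under low airflow do not
  transfer to high-airflow regimes, where degradation reaches
  quasi-steady state too quickly for the two-phase structure to resolve;
  validation on such reactors effectively exercises a single phase.
* Air properties are fixed at ~300 K film values; the convective term is
  small enough here that this is immaterial, but the correlation-based
  $h$ should not be trusted for geometries where convection dominates.
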