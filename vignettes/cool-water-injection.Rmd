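---
title: "Modelling the feasibility of cool-water injection on coral reefs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the feasibility of cool-water injection on coral reefs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefcool)
```

## The question

During marine heatwaves, pumping cooler water from a nearby deep channel
onto a reef flat is one of the few direct interventions that could reduce
coral thermal stress locally. Whether it is worth attempting depends on
three quantities this package computes:

1. **Where would injected water linger?** Water residence over a reef is
   measured with the *reef age* tracer: reefs whose overlying water is
   replaced every tidal phase are poor candidates, because injected cool
   water would be advected off almost immediately.
2. **How much reef area actually cools, and by how much?** Paired
   control/injection simulations give a per-cell mean temperature
   reduction, summarized as an area-versus-reduction histogram and as
   cooled areas above thresholds, convertible to a reduction in Degree
   Heating Weeks (DHW).
3. **What does the pumping cost?** A complete pipe-flow energy model
   (friction, momentum and lift losses, pump efficiency, energy tariff,
   capital cost) prices the intervention.

Everything runs on synthetic reef and flow fields generated by the
package itself, so the full pipeline is testable end to end without any
ocean-model output.

## The reef-age tracer

Reef age $\tau$ (days) is the time a water parcel has spent over the reef.
It obeys the same conservative advection–diffusion equation as any passive
tracer, plus unit accumulation over the reef:

$$\frac{\partial \tau}{\partial t} + \mathbf{u}\cdot\nabla\tau
  = \nabla\cdot(K\nabla\tau) + \Phi, \qquad
  \Phi = \begin{cases}1\ \mathrm{d\,d^{-1}} & \text{over the reef}\\
  0 & \text{open ocean,}\end{cases}$$

where $\mathbf{u}$ is the depth-averaged velocity and $K$ the horizontal
eddy diffusivity. The reef is defined as cells with bottom depth shallower
than 10 m; the *footprint* over which cooled area is tallied uses depth
< 20 m. We implement the diffusion term in its Fickian (divergence of
$K\nabla\tau$) form: it is the only form that conserves the tracer and
matches the age-tracer literature. Water entering through open boundaries
carries age zero; outflow is zero-gradient.

In a sealed all-reef basin $\tau(t) = t$ exactly; in a steady channel with
speed $u$ crossing a reef strip of length $L$, the steady exit age is
$L/u$. Both limits are exercised in the test suite, the second to within
5 % (it is in fact exact for the upwind discretization at steady state).

## Numerics

The solver is a finite-volume scheme on a regular masked grid with static
depth (no wetting/drying) and a single depth-averaged layer, so "seabed
temperature" and depth-averaged temperature coincide and the footprint
analysis is areal.

* **Flow = streamfunction.** Face transports are corner differences of a
  transport streamfunction, so the discrete divergence of every cell is a
  telescoping sum that vanishes to round-off. Conservation tests can then
  demand machine-precision budgets (the suite asserts total-tracer drift
  below $10^{-12}$ relative per step) without attributing residuals to the
  flow. The price is that we prescribe flow rather than solving momentum:
  tides are a spatially uniform rotating ellipse (velocity amplitudes
  times a 10 m reference depth give transports) modulated by a spring–neap
  envelope $1 + m\cos(2\pi t/T_{sn})$, diverted around land by flattening
  the streamfunction to a constant over each connected land region.
  Defaults: $T_{tide} = 12.42$ h (semi-diurnal), $T_{sn} = 14.77$ d,
  $m = 0.5$ (spring/neap amplitude ratio 3).
* **Upwind advection.** First-order upwind is monotone and conservative:
  temperatures can never leave the convex hull of initial, boundary and
  source values, so the *sign* of a control-minus-injection difference is
  never a numerical artifact. Its numerical diffusion smears plume edges,
  which biases footprint areas at high thresholds low and at low
  thresholds high; at the 50 m, footprint-scale statistics targeted here
  that trade-off is acceptable, and the 1-D refinement test confirms
  first-order convergence.
* **Explicit Euler, auto-capped step.** Operator order is advection →
  diffusion → source. The step is chosen from the envelope maximum of the
  transports so the Courant number stays below 1 (times a 0.8 safety
  factor) at every instant; a user-supplied step that violates the limit
  is refused with the required value in the error.
* **Injection as in-cell mixing.** A site with flux $Q$ and source
  temperature $T_{inj}$ relaxes its cell toward $T_{inj}$ at rate
  $Q/V_{cell}$ — the flux replaces resident water; no volume or momentum
  is added. The term is integrated exactly over each step
  ($T \mapsto T_{inj} + (T - T_{inj})e^{-Q\,\Delta t/V}$), which is
  unconditionally monotone and reproduces the closed-basin exponential
  flushing solution $T(t) = T_{inj} + (T_a - T_{inj})e^{-Qt/V_b}$ to
  machine precision on a single-cell basin. Schedules are either
  continuous or a daily clock window (e.g. 11:00–14:00); clock time is
  simulation time modulo 24 h from 00:00.
* **Diffusivity.** Neither model system we emulate documents its $K$; it
  is a free parameter, default 5 m$^2$ s$^{-1}$, a mid-range value for
  reef-scale horizontal eddy diffusivity. Diffusive face conductances use
  the mean $K$ and the minimum depth of the two neighbours, and vanish
  across land and domain edges.

## The synthetic reef

`make_island_reef()` draws the study setting: a circular island, a shallow
(default 3 m) annular reef flat inside the reef mask, a 15 m lagoon ring
(footprint but not reef), 30 m open ocean, and a 40 m channel strip south
of the island — the cool-water source in the scenario narrative. Mild
seeded bathymetric roughness (sd 0.2 m) is clamped clear of the 10/20 m
thresholds so masks stay exactly the drawn annuli and every geometric test
can count cells. What the generator does *not* emulate: realistic reef
geometry, vertical structure (the real systems resolve several sigma
layers), wind-driven and baroclinic flow, surface heat fluxes, and
wetting/drying of the flat. Passing tests therefore demonstrate the
correctness of the machinery and the qualitative behaviour of the
intervention (plume dilution, spring–neap sensitivity, rate monotonicity),
not site-specific hectare numbers, which require real bathymetry and
hindcast boundary forcing.

## Footprint statistics

The attributed cooling is the per-cell time mean of control minus injected
temperature over one spring–neap cycle (a shorter window warns: it would
bias the mean toward spring or neap flushing). Footprint cells are binned
into half-open 0.05 °C reduction bins — the width implied by the reported
thresholds (0.05, 0.15, 0.25 °C) — with areas in hectares; thresholds must
sit on bin edges and "at least" is implemented as $\geq$ the edge, the
convention under which the published bin sum (39 + 25 + 22 + 9 + 2 = 97 ha
at ≥ 0.15 °C) reproduces. Cells that warmed go to a single "< 0" bin and
never count toward threshold areas. Bins with ≤ 1 ha are flagged
non-displayed but retained. A cooling $\Delta T$ sustained for $d$ days
removes $\Delta T \times d / 7$ DHW.

Reef-age trajectories reduce to pooled statistics over all shallow cells
sampled every 3 h (mean, median, quartiles by the linear-interpolation
convention, range, shallow area), and reefs rank by descending mean age
with median then label as tie-breaks. Only depth-averaged values exist
here, so "surface" and bulk age coincide.

## Pipe energy and cost model

Per pipe (flow $V = V_{total}/n$, diameter $D$, length $L$, roughness
$\epsilon$): velocity $U = V/(\pi D^2/4)$, Reynolds number
$Re = \rho U D / \mu$, Haaland friction factor

$$\frac{1}{\sqrt{f}} = -1.8\log_{10}\!\left[\left(\frac{\epsilon/D}{3.75}\right)^{1.11}
   + \frac{6.9}{Re}\right],$$

pressure drop $\Delta p = f\rho U^2 L / (2D)$, and powers
$P_f = \Delta p\, V$, $P_m = \tfrac12 \rho V U^2$,
$P_l = gV(\rho - \rho_w)h$, $P_c = c_p \rho V_{total}\,\Delta T$, with
site totals $n$ times the per-pipe values and $P_T = P_f + P_m + P_l$.
Design notes:

* The square-root (standard Haaland) form is used; a printed variant with
  $1/f$ on the left is selectable (`form = "as_printed"`) but produces
  factors an order of magnitude too large and is not a valid correlation.
  The 3.75 constant (vs the textbook 3.7) is kept; at
  $\epsilon/D = 0.002$ the difference is below the reporting precision.
  Agreement with an iterative Colebrook solution is within 1.5 % across
  $Re \in [10^4, 10^8]$, $\epsilon/D \in [10^{-5}, 0.05]$.
* $\rho = 1022.72$ kg m$^{-3}$ (salinity 35, 27 °C source water),
  $\mu = 1.08\times10^{-3}$ kg s$^{-1}$ m$^{-1}$,
  $c_p = 4.186$ J g$^{-1}$ °C$^{-1}$ (converted to J kg$^{-1}$
  internally). The ambient density $\rho_w$ entering the lift term has no
  canonical published value; the default 1022.40 kg m$^{-3}$ corresponds
  to the same salinity at 28 °C, consistent with source water about 1 °C
  cooler than ambient. $P_l$ is therefore reported but, at ~1–3 kW, is
  negligible against $P_f$ either way.
* The published cooling loads are consistent with $\rho \approx 1025$
  rather than 1022.72; `cooling_density` makes either choice explicit.
  $P_c$ is a comparison quantity only — the source water is naturally
  cool — and is never added to the pumping total.
* Operating cost is $P_T \times$ hours $/\ \phi \times$ tariff $\times$
  sites, with pump efficiency $\phi = 0.8$ and a deliberately conservative
  remote-site tariff of 1 per kWh; capital cost is linear at 5,000 per
  metre of laid 1 m pipe.

```{r energy}
site_powers(pipe_system(V_total = 5, n_pipes = 4))
operating_cost(465, efficiency = 0.80, price_per_kWh = 1, hours = 24)
```

## The demo scenario

`demo_config()` fixes the study conditions exercised by the test suite: an
80 × 80 grid of 50 m cells (4 × 4 km), a tidal ellipse of 0.08/0.03
m s$^{-1}$ amplitude at the 10 m reference depth — giving spring currents
of 0.3–0.4 m s$^{-1}$ over the 3 m reef flat, typical of tidally flushed
reef flats — with a 0.005 m s$^{-1}$ residual drift, ambient 28 °C,
27 °C source water injected continuously at two southern reef-flat sites,
one full 14.77 d spring–neap cycle sampled 3-hourly, and pipes sized so
per-pipe flow is ≈ 1.25 m$^3$ s$^{-1}$ (2 → 2, 5 → 4, 10 → 8 pipes).
These sizes keep a full three-rate sweep (2, 5, 10 m$^3$ s$^{-1}$, control
run shared) to a few minutes on one CPU while still resolving the plume
over several cells. Cooled areas grow monotonically with rate, the
scaled-down analogue of the published 117-ha-at-2 versus
571-ha-at-10 m$^3$ s$^{-1}$ pattern.

```{r scenario, eval = FALSE}
b2 <- run_scenario(demo_config(rate = 2))
b5 <- run_scenario(demo_config(rate = 5), control = b2$runs$control)
b10 <- run_scenario(demo_config(rate = 10), control = b2$runs$control)
compare_scenarios(list(b2, b5, b10), threshold = 0.05)
```

## Known limitations

* Prescribed barotropic flow: no momentum response to the injection, no
  buoyant plume near-field; the mixing-source contract is ours, not a
  hydrodynamic result.
* First-order accuracy: footprint areas near sharp plume edges carry
  $O(\Delta x)$ uncertainty.
* Single layer: stratified trapping of cool water in the bottom layer —
  which would help the intervention — cannot be represented.
* No surface heat flux: the control stays at ambient, so the attributed
  cooling isolates advection/dilution only.
* The hectare values published for the real island (117/3/571/111 ha of
  1334 ha) are not reproducible here by design; they depend on real
  bathymetry and hindcast forcing.
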