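# reefcool

Tools to assess the feasibility of **cool-water injection** as a local
intervention against coral bleaching: where on a reef would injected cool
water linger, how much reef area does it actually cool, and what does the
pumping cost?

The package is aimed at reef modellers and intervention analysts. It
implements three connected pieces:

1. **Reef-age residence tracer.** "Reef age" τ (days) measures how long a
   water parcel has resided over the reef (cells with depth < 10 m). It
   satisfies the conservative advection–diffusion equation with unit
   accumulation over the reef,

   ∂τ/∂t + **u**·∇τ = ∇·(K∇τ) + Φ,  Φ = 1 d d⁻¹ over the reef, 0 elsewhere,

   solved with a conservative finite-volume scheme (first-order upwind
   advection, explicit diffusion) on streamfunction-derived non-divergent
   transports, so tracer budgets close to machine precision. Reefs where
   mean age is long (water resides over many tidal cycles) are the
   candidates where injected cool water would not be immediately advected
   away.

2. **Control-vs-injection footprint.** Paired temperature simulations —
   identical except for point sources mixing water at the source
   temperature into their cell at rate Q — give a per-cell mean
   temperature reduction over a spring–neap cycle, reduced to an
   area-vs-reduction histogram (0.05 °C bins, hectares, over the depth
   < 20 m footprint), threshold areas, and a Degree Heating Week
   reduction ΔT × days / 7.

3. **Pipe energy and cost model.** For V m³ s⁻¹ per pipe of diameter D:
   U = V/(πD²/4), Re = ρUD/μ, Haaland friction factor
   1/√f = −1.8 log₁₀[((ε/D)/3.75)^1.11 + 6.9/Re], Δp = fρU²L/(2D), and
   the powers P_f = ΔpV, P_m = ½ρVU², P_l = gV(ρ−ρ_w)h,
   P_c = c_p ρ V ΔT, with P_T = P_f + P_m + P_l, pump efficiency,
   operating tariff and capital cost.

A synthetic generator (island + annular reef flat + lagoon + deep channel
bathymetry; spring–neap modulated elliptic tides; ambient/source thermal
forcing) provides the study conditions, so the entire pipeline runs and is
tested without any ocean-model output.

## Worked example

Energy for the reference design — 5 m³ s⁻¹ to one site through four 1 m
pipes, 3 km long, 2 mm roughness:

```r
library(reefcool)
site_powers(pipe_system(V_total = 5, n_pipes = 4))
#> <energy_report> 5 m^3/s through 4 x 1 m pipe(s), L = 3000 m
#>   U = 1.59 m/s | Re = 1.51e+06 | f = 0.02349
#>   friction loss P_f                 456 kW
#>   momentum loss P_m                   6 kW
#>   lift loss P_l                       1 kW
#>   total pumping P_T                 464 kW
#>   cooling load P_c (dT = 1)       21406 kW
```

Friction dominates the pumping budget, yet pumping naturally cool channel
water needs ~50× less power than chilling the same flow on site (P_c).
At 80 % pump efficiency and 1 per kWh, `operating_cost(465)` gives
13,950 per site-day; `capital_cost(3000)` prices the pipe itself at 15 M.

An end-to-end scenario sweep on the synthetic island (continuous 27 °C
injection into 28 °C ambient at two reef-flat sites, one 14.77 d
spring–neap cycle, ~2 min/scenario on one CPU):

```r
b2  <- run_scenario(demo_config(rate = 2))
b5  <- run_scenario(demo_config(rate = 5),  control = b2$runs$control)
b10 <- run_scenario(demo_config(rate = 10), control = b2$runs$control)
compare_scenarios(list(b2, b5, b10), threshold = 0.05)
#>   rate_m3s area_ha   P_T_kW daily_cost_per_site season_cost_all_sites
#> 1        2     0.0 118.8968            3566.904               1284086
#> 2        5     0.5 463.5609           13906.827               5006458
#> 3       10    10.5 927.1218           27813.654              10012915
```

The area cooled by ≥ 0.05 °C grows monotonically — and faster than
linearly — with the injection rate, while the 90-day, 4-site energy bill
reaches ~10 M at 10 m³ s⁻¹: the qualitative trade-off at the heart of the
feasibility question. A sustained 0.15 °C reduction over a 90-day summer
(`dhw_reduction(0.15, 90)`) removes 1.93 DHW.

See `vignettes/cool-water-injection.Rmd` for the model formulation,
numerical choices and limitations.

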