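#' Describe a cool-water pipe system for one site
#'
#' A site is supplied through `n_pipes` identical submerged pipes sharing
#' the total flow equally, so the per-pipe flow is `V_total / n_pipes`.
#' Defaults are the reference design: 1 m diameter, 3 km long pipes drawing
#' from 40 m deep channel water with 2 mm wall roughness.
#'
#' @param V_total total volumetric flow delivered to the site \[m^3 s^-1\].
#' @param n_pipes number of identical pipes.
#' @param diameter pipe inner diameter D \[m\].
#' @param length pipe length L \[m\].
#' @param lift_height depth of the cool source water h \[m\]; the water is
#'   raised this far against its buoyancy deficit (both pipe ends are
#'   submerged, so lift works against the ambient density difference, not
#'   the atmosphere).
#' @param roughness pipe wall roughness epsilon \[m\].
#' @return Object of class `pipe_system`.
#' @export
pipe_system <- function(V_total, n_pipes = 1L, diameter = 1, length = 3000,
                        lift_height = 40, roughness = 0.002) {
  stopifnot(V_total >= 0, n_pipes >= 1, diameter > 0, length > 0,
            lift_height >= 0, roughness >= 0)
  structure(list(V_total = V_total, n_pipes = as.integer(n_pipes),
                 V_pipe = V_total / n_pipes,
                 diameter = diameter, length = length,
                 lift_height = lift_height, roughness = roughness),
            class = "pipe_system")
}

#' Physical constants for the pumping calculations
#'
#' @param density density of the pumped (source) seawater \[kg m^-3\];
#'   default 1022.72, seawater at salinity 35 and 27 deg C.
#' @param ambient_density density of the ambient water the pipe discharges
#'   into \[kg m^-3\]; default 1022.40, seawater at salinity 35 and 28 deg C
#'   (the ambient reef water is about 1 deg C warmer than the source).
#' @param viscosity dynamic viscosity mu \[kg s^-1 m^-1\].
#' @param specific_heat specific heat capacity of seawater \[J g^-1 degC^-1\]
#'   (converted to J kg^-1 degC^-1 internally).
#' @param gravity g \[m s^-2\].
#' @param pump_efficiency phi in (0, 1\].
#' @param energy_price price per kWh \[currency\].
#' @return Object of class `fluid_constants`.
#' @export
fluid_constants <- function(density = 1022.72, ambient_density = 1022.40,
                            viscosity = 1.08e-3, specific_heat = 4.186,
                            gravity = 9.81, pump_efficiency = 0.80,
                            energy_price = 1) {
  stopifnot(density > 0, ambient_density > 0, viscosity > 0,
            specific_heat > 0, gravity > 0,
            pump_efficiency > 0, pump_efficiency <= 1, energy_price >= 0)
  structure(list(density = density, ambient_density = ambient_density,
                 viscosity = viscosity, specific_heat = specific_heat,
                 gravity = gravity, pump_efficiency = pump_efficiency,
                 energy_price = energy_price),
            class = "fluid_constants")
}

#' Per-pipe flow velocity
#'
#' `U = (V_total / n) / (pi D^2 / 4)`.
#'
#' @param system a [pipe_system()].
#' @return velocity U \[m s^-1\].
#' @examples
#' pipe_velocity(pipe_system(2, 1))      # 2.55 m/s
#' pipe_velocity(pipe_system(5, 4))      # 1.59 m/s
#' @export
pipe_velocity <- function(system) {
  system$V_pipe / (pi * system$diameter^2 / 4)
}

#' Pipe Reynolds number
#'
#' `Re = rho U D / mu`, with a `"regime"` attribute flagging laminar flow
#' (Re < 4000), outside the validity of the rough-pipe friction factor.
#'
#' @param system a [pipe_system()].
#' @param fluids a [fluid_constants()].
#' @return Reynolds number (dimensionless) with attribute `regime`.
#' @export
reynolds <- function(system, fluids = fluid_constants()) {
  re <- fluids$density * pipe_velocity(system) * system$diameter /
    fluids$viscosity
  attr(re, "regime") <- if (re < 4000) "laminar" else "turbulent"
  re
}

#' Darcy friction factor for rough turbulent pipe flow
#'
#' The explicit Haaland approximation to the Colebrook-White relation:
#' \deqn{1/\sqrt{f} = -1.8 \log_{10}\left[\left(\frac{\epsilon/D}{3.75}\right)^{1.11}
#'   + \frac{6.9}{Re}\right].}
#' An alternative form with `1/f` on the left-hand side
#' (`form = "as_printed"`) is provided for comparison; it is not a valid
#' friction correlation (it yields f an order of magnitude too large) and
#' only the square-root form reproduces measured turbulent pipe losses.
#'
#' @param system a [pipe_system()] (supplies the relative roughness).
#' @param Re Reynolds number; must be turbulent (> 4000).
#' @param form `"haaland"` (default) or `"as_printed"`.
#' @return friction factor f (dimensionless).
#' @examples
#' s <- pipe_system(2, 1)
#' friction_factor(s, reynolds(s))   # ~ 0.0235
#' @export
friction_factor <- function(system, Re, form = c("haaland", "as_printed")) {
  form <- match.arg(form)
  if (Re <= 4000)
    stop(sprintf("Re = %.3g is not turbulent (<= 4000): friction factor out of regime", Re))
  rel <- system$roughness / system$diameter
  arg <- -1.8 * log10((rel / 3.75)^1.11 + 6.9 / as.numeric(Re))
  switch(form, haaland = arg^-2, as_printed = 1 / arg)
}

#' Full pumping-power and cooling-load report for one site
#'
#' Computes, per pipe and summed over the site's `n` pipes:
#' \itemize{
#'   \item friction power `P_f = dp V` with pressure drop
#'     `dp = f rho U^2 L / (2 D)`;
#'   \item momentum power `P_m = 0.5 rho V U^2` (accelerating the flow from
#'     rest);
#'   \item lift power `P_l = g V (rho - rho_ambient) h` (raising the denser
#'     source water against its buoyancy deficit);
#'   \item total pumping power `P_T = P_f + P_m + P_l`;
#'   \item cooling load `P_c = c_p rho V_total dT`, the thermodynamic power
#'     a chiller would need to cool the same flow by `dT` — reported for
#'     comparison only (the source water is naturally cool) and never added
#'     to the pumping total.
#' }
#' A zero-flow system returns an all-zero report (no friction regime).
#'
#' @param system a [pipe_system()].
#' @param fluids a [fluid_constants()].
#' @param dT_cool temperature reduction used for the cooling load \[deg C\].
#' @param cooling_density optional density \[kg m^-3\] used only in `P_c`
#'   (defaults to `fluids$density`).
#' @return Object of class `energy_report` with `U` \[m s^-1\], `Re`, `f`,
#'   `dp` \[Pa\] and site powers `P_f`, `P_m`, `P_l`, `P_T`, `P_c` \[kW\].
#' @examples
#' site_powers(pipe_system(5, 4))   # the 5 m^3/s, four-pipe reference case
#' @export
site_powers <- function(system, fluids = fluid_constants(), dT_cool = 1,
                        cooling_density = NULL) {
  U <- pipe_velocity(system)
  n <- system$n_pipes
  V <- system$V_pipe
  rho <- fluids$density
  if (is.null(cooling_density)) cooling_density <- rho
  cp <- fluids$specific_heat * 1000   # J g^-1 -> J kg^-1
  if (U == 0) {
    rep <- list(U = 0, Re = 0, f = NA_real_, dp = 0,
                P_f = 0, P_m = 0, P_l = 0, P_T = 0, P_c = 0)
  } else {
    Re <- reynolds(system, fluids)
    f <- friction_factor(system, Re)
    dp <- f * rho * U^2 * system$length / (2 * system$diameter)
    P_f <- dp * V * n / 1000
    P_m <- 0.5 * rho * V * U^2 * n / 1000
    P_l <- fluids$gravity * V * (rho - fluids$ambient_density) *
      system$lift_height * n / 1000
    rep <- list(U = U, Re = as.numeric(Re), f = f, dp = dp,
                P_f = P_f, P_m = P_m, P_l = P_l, P_T = P_f + P_m + P_l,
                P_c = cp * cooling_density * system$V_total * dT_cool / 1000)
  }
  structure(c(list(system = system, fluids = fluids, dT_cool = dT_cool), rep),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  s <- x$system
  cat(sprintf("<energy_report> %g m^3/s through %d x %g m pipe(s), L = %g m\n",
              s$V_total, s$n_pipes, s$diameter, s$length))
  cat(sprintf("  U = %.2f m/s | Re = %.3g | f = %.4g\n", x$U, x$Re, x$f))
  cat(sprintf("  %-28s %8.0f kW\n", "friction loss P_f", x$P_f))
  cat(sprintf("  %-28s %8.0f kW\n", "momentum loss P_m", x$P_m))
  cat(sprintf("  %-28s %8.0f kW\n", "lift loss P_l", x$P_l))
  cat(sprintf("  %-28s %8.0f kW\n", "total pumping P_T", x$P_T))
  cat(sprintf("  %-28s %8.0f kW\n",
              sprintf("cooling load P_c (dT = %g)", x$dT_cool), x$P_c))
  invisible(x)
}

#' Operating cost of pumping
#'
#' `cost = power * hours / efficiency * price * n_sites`: the electrical
#' energy drawn (pump shaft power divided by pump efficiency) at the given
#' tariff. The reference case, 465 kW for 24 h at 80% efficiency and 1 per
#' kWh, costs 13,950 per site-day.
#'
#' @param total_power_kW pumping power at the shaft \[kW\] (e.g. `P_T`).
#' @param efficiency pump efficiency in (0, 1\].
#' @param price_per_kWh energy tariff.
#' @param hours operating hours.
#' @param n_sites number of identical sites.
#' @return cost in the tariff's currency.
#' @examples
#' operating_cost(465)                       # 13950 per site-day
#' operating_cost(465, n_sites = 4)          # 55800 per day for 4 sites
#' operating_cost(465, hours = 24 * 90, n_sites = 4)  # ~5M for a summer
#' @export
operating_cost <- function(total_power_kW, efficiency = 0.80,
                           price_per_kWh = 1, hours = 24, n_sites = 1) {
  stopifnot(total_power_kW >= 0, efficiency > 0, efficiency <= 1,
            price_per_kWh >= 0, hours >= 0, n_sites >= 1)
  total_power_kW * hours / efficiency * price_per_kWh * n_sites
}

#' Capital cost of laying pipe
#'
#' Linear in pipe length at a per-metre rate (default 5,000 per metre of
#' 1 m diameter pipe laid in the marine environment).
#'
#' @param pipe_length_m total pipe length \[m\].
#' @param rate_per_m capital rate per metre.
#' @return cost.
#' @examples
#' capital_cost(3000)   # 15M for a 3 km pipe
#' @export
capital_cost <- function(pipe_length_m, rate_per_m = 5000) {
  stopifnot(pipe_length_m >= 0, rate_per_m >= 0)
  pipe_length_m * rate_per_m
}
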