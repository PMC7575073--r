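#' Solver settings for the finite-volume tracer engine
#'
#' The engine uses first-order upwind advection, explicit centered diffusion
#' and forward-Euler time stepping (point injections are integrated exactly,
#' see [run_injection()]). Stability requires the cell Courant number
#' (summed face transports times dt over cell volume) to stay below 1 and
#' the diffusion number below 1/2; `cfl_safety` scales the automatically
#' chosen step below those limits. If `dt` is given and violates the limits
#' for a particular grid/flow pair, the run refuses to start and reports the
#' required step.
#'
#' @param dt time step \[s\], or `NULL` to choose the largest stable step
#'   automatically (then rounded down so steps tile the sample interval).
#' @param cfl_safety safety factor in (0, 1] applied to the stability limit.
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(dt = NULL, cfl_safety = 0.8) {
  stopifnot(is.null(dt) || dt > 0, cfl_safety > 0, cfl_safety <= 1)
  structure(list(dt = dt, cfl_safety = cfl_safety), class = "solver_config")
}

#' Largest stable time step for a grid/flow pair
#'
#' Uses the envelope maximum of the tidal transports (worst spring tide), so
#' a step chosen here is stable at every instant of the simulation.
#'
#' @param grid a [reef_grid()].
#' @param flow a `flow_series` on the same grid.
#' @param cfl_safety safety factor applied to the combined advective +
#'   diffusive limit.
#' @return time step \[s\].
#' @export
stable_dt <- function(grid, flow, cfl_safety = 0.8) {
  nx <- grid$nx; ny <- grid$ny
  fxmax <- sqrt(flow$Fx_cos^2 + flow$Fx_sin^2) * (1 + flow$sn_mod) +
    abs(flow$Fx_res)
  fymax <- sqrt(flow$Fy_cos^2 + flow$Fy_sin^2) * (1 + flow$sn_mod) +
    abs(flow$Fy_res)
  adv <- fxmax[1:nx, , drop = FALSE] + fxmax[2:(nx + 1), , drop = FALSE] +
    fymax[, 1:ny, drop = FALSE] + fymax[, 2:(ny + 1), drop = FALSE]
  # conductances as in the core: min-depth, mean-K faces, doubled per cell
  hx <- pmin(grid$depth[1:(nx - 1), , drop = FALSE],
             grid$depth[2:nx, , drop = FALSE])
  kx <- 0.5 * (flow$K[1:(nx - 1), , drop = FALSE] +
                 flow$K[2:nx, , drop = FALSE])
  hy <- pmin(grid$depth[, 1:(ny - 1), drop = FALSE],
             grid$depth[, 2:ny, drop = FALSE])
  ky <- 0.5 * (flow$K[, 1:(ny - 1), drop = FALSE] +
                 flow$K[, 2:ny, drop = FALSE])
  dif <- matrix(0, nx, ny)
  cx <- kx * hx * grid$dy / grid$dx
  dif[1:(nx - 1), ] <- dif[1:(nx - 1), ] + cx
  dif[2:nx, ] <- dif[2:nx, ] + cx
  cy <- ky * hy * grid$dx / grid$dy
  dif[, 1:(ny - 1)] <- dif[, 1:(ny - 1)] + cy
  dif[, 2:ny] <- dif[, 2:ny] + cy
  vol <- grid$cell_area * grid$depth
  wet <- !grid$land_mask
  denom <- adv[wet] + 2 * dif[wet]
  if (!any(denom > 0)) return(Inf)
  cfl_safety * min(vol[wet][denom > 0] / denom[denom > 0])
}

#' Construct a tracer state
#'
#' A snapshot of a tracer field at one instant: reef age \[d\],
#' temperature \[deg C\], or a generic passive tracer. Land cells are `NA`.
#'
#' @param values `nx x ny` matrix (or scalar, recycled over wet cells).
#' @param grid the [reef_grid()] the state lives on.
#' @param time time stamp \[s\].
#' @param kind one of `"age"`, `"temperature"`, `"passive"`.
#' @return Object of class `tracer_state`.
#' @export
tracer_state <- function(values, grid, time = 0,
                         kind = c("passive", "age", "temperature")) {
  kind <- match.arg(kind)
  if (length(values) == 1) values <- matrix(values, grid$nx, grid$ny)
  stopifnot(all(dim(values) == c(grid$nx, grid$ny)))
  values[grid$land_mask] <- NA_real_
  structure(list(values = values, time = time, kind = kind),
            class = "tracer_state")
}

#' @export
print.tracer_state <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<tracer_state:%s> t = %.4g s | range [%.4g, %.4g]\n",
              x$kind, x$time, min(v), max(v)))
  invisible(x)
}

# shared driver around the compiled core
run_tracer <- function(grid, flow, config, init, t0, duration,
                       sample_interval, kind,
                       boundary_mean = 0, boundary_amp = 0,
                       boundary_peak_hour = 15,
                       source_rate = NULL, sites = list()) {
  stopifnot(inherits(grid, "reef_grid"), inherits(flow, "flow_series"),
            inherits(config, "solver_config"),
            duration > 0, sample_interval > 0)
  if (flow$nx != grid$nx || flow$ny != grid$ny)
    stop("flow and grid dimensions differ")
  dt_max <- stable_dt(grid, flow, config$cfl_safety)
  dt <- config$dt
  if (is.null(dt)) {
    dt <- min(dt_max, sample_interval)
  } else if (dt > dt_max * (1 + 1e-9)) {
    stop(sprintf("time step %g s violates the stability limit; requires dt <= %g s",
                 dt, dt_max))
  }
  nsub <- max(1L, as.integer(ceiling(sample_interval / dt - 1e-9)))
  dt_eff <- sample_interval / nsub
  nsamples <- as.integer(ceiling(duration / sample_interval - 1e-9))
  if (is.null(source_rate)) source_rate <- matrix(0, grid$nx, grid$ny)
  if (length(init) == 1) init <- matrix(init, grid$nx, grid$ny)

  nsite <- length(sites)
  si <- sj <- integer(nsite); sq <- st <- lo <- hi <- numeric(nsite)
  for (k in seq_len(nsite)) {
    s <- sites[[k]]
    si[k] <- s$i - 1L; sj[k] <- s$j - 1L
    sq[k] <- s$flux; st[k] <- s$source_temp
    lo[k] <- s$window[1]; hi[k] <- s$window[2]
  }

  out <- run_tracer_core(grid$depth, grid$dx, grid$dy,
                         flow$Fx_cos, flow$Fx_sin, flow$Fx_res,
                         flow$Fy_cos, flow$Fy_sin, flow$Fy_res,
                         flow$omega, flow$sn_omega, flow$sn_mod,
                         flow$K, init,
                         t0, dt_eff, nsub, nsamples,
                         boundary_mean, boundary_amp, boundary_peak_hour,
                         source_rate,
                         si, sj, sq, st, lo, hi)
  structure(list(values = out$values, times = out$times, kind = kind,
                 dt = dt_eff, nx = grid$nx, ny = grid$ny),
            class = "tracer_trajectory")
}

#' @export
print.tracer_trajectory <- function(x, ...) {
  cat(sprintf("<tracer_trajectory:%s> %d x %d cells, %d samples, t in [%g, %g] s (dt = %.3g s)\n",
              x$kind, x$nx, x$ny, length(x$times),
              min(x$times), max(x$times), x$dt))
  invisible(x)
}

#' Extract one snapshot from a trajectory as a tracer state
#' @param traj a `tracer_trajectory`.
#' @param index sample index (default: last).
#' @param grid the grid the trajectory was run on.
#' @return A [tracer_state()].
#' @export
state_at <- function(traj, grid, index = length(traj$times)) {
  tracer_state(traj$values[, , index], grid, time = traj$times[index],
               kind = if (traj$kind %in% c("age", "temperature")) traj$kind else "passive")
}

#' Advance a tracer state by one time step
#'
#' Applies a single conservative finite-volume update (upwind advection,
#' explicit diffusion, then source increment) at the state's time stamp.
#' Open-boundary inflow carries `boundary_value`; outflow is zero-gradient.
#' Refuses to step, reporting the required step, if `config$dt` violates
#' the stability limits for this flow.
#'
#' @param state a [tracer_state()].
#' @param grid the [reef_grid()].
#' @param flow a `flow_series`.
#' @param config a [solver_config()]; `dt = NULL` uses the stable step.
#' @param source_field optional `nx x ny` tendency \[tracer s^-1\].
#' @param boundary_value inflow value at open domain edges.
#' @return The advanced [tracer_state()].
#' @export
step <- function(state, grid, flow, config = solver_config(),
                 source_field = NULL, boundary_value = 0) {
  dt <- config$dt
  if (is.null(dt)) dt <- stable_dt(grid, flow, config$cfl_safety)
  traj <- run_tracer(grid, flow, solver_config(dt, config$cfl_safety),
                     init = state$values, t0 = state$time,
                     duration = dt, sample_interval = dt, kind = state$kind,
                     boundary_mean = boundary_value,
                     source_rate = source_field)
  tracer_state(traj$values[, , 2], grid, time = traj$times[2],
               kind = state$kind)
}

#' Integrate a passive tracer
#'
#' General entry point used by the specialized drivers: integrates an
#' arbitrary initial field with an optional constant source tendency.
#'
#' @inheritParams step
#' @param init initial field (`nx x ny` matrix or scalar).
#' @param t0 start time \[s\].
#' @param duration integration length \[s\].
#' @param sample_interval spacing of recorded snapshots \[s\].
#' @param source_rate optional `nx x ny` constant tendency \[tracer s^-1\].
#' @return A `tracer_trajectory` (`values` is `nx x ny x nsamples+1`,
#'   including the initial state).
#' @export
run_passive <- function(grid, flow, config = solver_config(), init = 0,
                        t0 = 0, duration, sample_interval = 3 * 3600,
                        boundary_value = 0, source_rate = NULL) {
  run_tracer(grid, flow, config, init, t0, duration, sample_interval,
             kind = "passive", boundary_mean = boundary_value,
             source_rate = source_rate)
}

#' Integrate the reef-age tracer
#'
#' Reef age tau measures the time (days) a water parcel has spent over the
#' reef. It obeys the conservative advection-diffusion equation of any
#' passive tracer with an accumulation source of 1 d per day over reef
#' cells (depth < 10 m) and zero over open ocean; water entering through
#' the open boundaries carries age zero.
#'
#' @inheritParams run_passive
#' @param duration integration length \[s\]; age starts at 0 everywhere.
#' @param sample_interval snapshot spacing \[s\] (default 3 h, the spacing
#'   used by [age_statistics()]).
#' @return A `tracer_trajectory` with `kind = "age"`, values in days.
#' @examples
#' g <- make_island_reef(48, 48, dx = 50, island_radius = 5,
#'                       reef_flat_width = 6)
#' fl <- make_tidal_flow(g, ellipse_major = 0.15, ellipse_minor = 0.05)
#' ages <- run_age(g, fl, duration = 2 * 86400)
#' @export
run_age <- function(grid, flow, config = solver_config(), duration,
                    sample_interval = 3 * 3600) {
  if (!any(grid$reef_mask))
    warning("grid has no reef cells (depth < 10 m); age stays zero")
  src <- matrix(0, grid$nx, grid$ny)
  src[grid$reef_mask] <- 1 / 86400   # 1 d per day, in d/s
  run_tracer(grid, flow, config, init = 0, t0 = 0, duration,
             sample_interval, kind = "age",
             boundary_mean = 0, source_rate = src)
}

#' Define a cool-water injection site
#'
#' An injection delivers a volume flux `Q` of water at `source_temp` into
#' one bottom cell. It is modelled as in-cell mixing: the flux replaces
#' resident water, relaxing the cell temperature toward the source at rate
#' `Q / cell volume` while the schedule is active. The free surface is not
#' perturbed.
#'
#' @param i,j cell indices of the site (must be wet).
#' @param flux volumetric flux Q \[m^3 s^-1\].
#' @param source_temp temperature of the injected water \[deg C\]; if `NULL`
#'   the forcing's `source_temp` is used at run time.
#' @param schedule `"continuous"`, or a daily clock window `c(start, end)`
#'   in hours within \[0, 24\) (e.g. `c(11, 14)` for an injection active
#'   11:00-14:00 each day).
#' @return Object of class `injection_site`.
#' @export
injection_site <- function(i, j, flux, source_temp = NULL,
                           schedule = "continuous") {
  stopifnot(flux >= 0)
  if (identical(schedule, "continuous")) {
    window <- c(0, 24)
  } else {
    stopifnot(is.numeric(schedule), length(schedule) == 2,
              schedule[1] >= 0, schedule[1] < 24,
              schedule[2] > schedule[1], schedule[2] <= 24)
    window <- schedule
  }
  structure(list(i = as.integer(i), j = as.integer(j), flux = flux,
                 source_temp = source_temp, window = window),
            class = "injection_site")
}

#' Run paired control and injection temperature simulations
#'
#' Runs two simulations from identical initial and boundary ambient
#' temperature: a control without intervention, and one with cool water
#' injected at the given sites. The difference between the pair is the
#' attributed effect of the intervention (see [mean_reduction_field()]).
#'
#' @inheritParams run_passive
#' @param forcing a [make_forcing()] object supplying ambient and source
#'   temperatures.
#' @param sites list of [injection_site()]s; all must lie on wet cells.
#' @param duration integration length \[s\]; for footprint statistics it
#'   should cover at least one spring-neap cycle.
#' @param control optional precomputed control trajectory from an earlier
#'   call with the same grid/flow/forcing (reused, e.g. when sweeping
#'   injection rates).
#' @return List of class `injection_run` with elements `control` and
#'   `injected`, each a `tracer_trajectory` of temperature.
#' @export
run_injection <- function(grid, flow, config = solver_config(), forcing,
                          sites, duration, sample_interval = 3 * 3600,
                          control = NULL) {
  stopifnot(inherits(forcing, "forcing_series"))
  sites <- lapply(sites, function(s) {
    stopifnot(inherits(s, "injection_site"))
    if (s$i < 1 || s$i > grid$nx || s$j < 1 || s$j > grid$ny)
      stop("injection site outside the grid")
    if (grid$land_mask[s$i, s$j])
      stop(sprintf("injection site (%d, %d) is on land", s$i, s$j))
    if (is.null(s$source_temp)) s$source_temp <- forcing$source_temp
    s
  })
  run1 <- function(ss) run_tracer(
    grid, flow, config, init = forcing$mean_temp, t0 = 0, duration,
    sample_interval, kind = "temperature",
    boundary_mean = forcing$mean_temp, boundary_amp = forcing$diurnal_amp,
    boundary_peak_hour = forcing$peak_hour, sites = ss)
  if (is.null(control)) control <- run1(list())
  structure(list(control = control, injected = run1(sites)),
            class = "injection_run")
}
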