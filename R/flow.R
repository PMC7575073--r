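#' Build a flow series from transport streamfunctions
#'
#' The solver takes depth-integrated volume transports across cell faces
#' \[m^3 s^-1\]. Deriving them from a streamfunction on cell corners makes
#' the discrete divergence of every wet cell vanish identically (telescoping
#' sum), so finite-volume tracer conservation is exact by construction.
#'
#' The time dependence is a rotating tidal signal with a spring-neap
#' amplitude envelope plus a steady residual:
#' \deqn{\psi(t) = e(t)\,[\psi_c \cos\omega t + \psi_s \sin\omega t] + \psi_r,
#'       \quad e(t) = 1 + m \cos(2\pi t / T_{sn}),}
#' where \eqn{\omega = 2\pi/T_{tide}} and `m` is the spring-neap modulation
#' fraction. Face transports are the corner differences of \eqn{\psi}.
#'
#' Every streamfunction is flattened to a constant over each connected land
#' region (all four corners of every land cell), which forces zero transport
#' across all land faces while leaving the far field untouched.
#'
#' @param grid a [reef_grid()].
#' @param psi_cos,psi_sin,psi_res streamfunction corner matrices,
#'   `(nx+1) x (ny+1)` \[m^3 s^-1\]; scalars are recycled. `psi_cos`/`psi_sin`
#'   rotate at the tidal frequency under the spring-neap envelope; `psi_res`
#'   is steady.
#' @param tidal_period tidal period \[s\] (default semi-diurnal M2, 12.42 h).
#' @param springneap_period spring-neap envelope period \[s\]
#'   (default 14.77 d).
#' @param springneap_mod modulation fraction `m` in \[0, 1); the spring/neap
#'   amplitude ratio is `(1 + m)/(1 - m)`.
#' @param diffusivity horizontal eddy diffusivity K, scalar or per-cell
#'   matrix \[m^2 s^-1\].
#' @param times optional vector of times \[s\] recorded with the series
#'   (metadata for sampling; transports can be evaluated at any time with
#'   [flow_at()]).
#' @return An object of class `flow_series` holding the face-transport basis
#'   (`Fx_*` are `(nx+1) x ny`, `Fy_*` are `nx x (ny+1)`), the temporal
#'   parameters, the per-cell diffusivity and the water-column depth.
#' @seealso [make_tidal_flow()] for the elliptic-tide convenience wrapper.
#' @export
flow_from_streamfunction <- function(grid, psi_cos = 0, psi_sin = 0,
                                     psi_res = 0,
                                     tidal_period = 12.42 * 3600,
                                     springneap_period = 14.77 * 86400,
                                     springneap_mod = 0,
                                     diffusivity = 0, times = NULL) {
  stopifnot(inherits(grid, "reef_grid"), tidal_period > 0,
            springneap_period > 0,
            springneap_mod >= 0, springneap_mod < 1)
  if (!is.null(times) && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  nx <- grid$nx; ny <- grid$ny
  as_corner <- function(p) {
    if (length(p) == 1) p <- matrix(p, nx + 1, ny + 1)
    stopifnot(nrow(p) == nx + 1, ncol(p) == ny + 1)
    flatten_over_land(p, grid$land_mask)
  }
  psis <- lapply(list(psi_cos, psi_sin, psi_res), as_corner)
  faces <- lapply(psis, function(p) list(
    # Fx[i,j]: transport in +x across the face between cells (i-1,j) and (i,j)
    Fx = p[, 2:(ny + 1), drop = FALSE] - p[, 1:ny, drop = FALSE],
    Fy = -(p[2:(nx + 1), , drop = FALSE] - p[1:nx, , drop = FALSE])
  ))
  K <- if (length(diffusivity) == 1) matrix(diffusivity, nx, ny) else diffusivity
  stopifnot(all(dim(K) == c(nx, ny)), all(K >= 0))
  structure(list(
    nx = nx, ny = ny,
    Fx_cos = faces[[1]]$Fx, Fy_cos = faces[[1]]$Fy,
    Fx_sin = faces[[2]]$Fx, Fy_sin = faces[[2]]$Fy,
    Fx_res = faces[[3]]$Fx, Fy_res = faces[[3]]$Fy,
    omega = 2 * pi / tidal_period,
    sn_omega = 2 * pi / springneap_period,
    sn_mod = springneap_mod,
    tidal_period = tidal_period,
    springneap_period = springneap_period,
    K = K, depth = grid$depth, times = times
  ), class = "flow_series")
}

# Set the streamfunction to a single constant over each connected land
# region (4-connectivity): all faces bordering land then difference two
# equal corner values and vanish exactly.
flatten_over_land <- function(psi, land) {
  nx <- nrow(land); ny <- ncol(land)
  if (!any(land)) return(psi)
  comp <- matrix(0L, nx, ny)
  ncomp <- 0L
  for (start in which(land)) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    comp[start] <- ncomp
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      i <- (cell - 1L) %% nx + 1L; j <- (cell - 1L) %/% nx + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] >= 1 && nb[1] <= nx && nb[2] >= 1 && nb[2] <= ny &&
            land[nb[1], nb[2]] && comp[nb[1], nb[2]] == 0L) {
          comp[nb[1], nb[2]] <- ncomp
          queue <- c(queue, (nb[2] - 1L) * nx + nb[1])
        }
      }
    }
  }
  for (k in seq_len(ncomp)) {
    cells <- which(comp == k, arr.ind = TRUE)
    corner_idx <- unique(rbind(cells, cells + rep(c(1L, 0L), each = nrow(cells)),
                               cells + rep(c(0L, 1L), each = nrow(cells)),
                               cells + 1L))
    idx <- (corner_idx[, 2] - 1L) * nrow(psi) + corner_idx[, 1]
    psi[idx] <- mean(psi[idx])
  }
  psi
}

#' Generate a spring-neap modulated elliptic tidal flow
#'
#' Convenience wrapper around [flow_from_streamfunction()] producing a
#' spatially uniform, elliptically rotating depth-integrated tide (plus an
#' optional steady residual drift) diverted around any land in the grid.
#' Velocity amplitudes are converted to transports with a reference depth,
#' so a cell of depth `h` sees a velocity of roughly
#' `amplitude * reference_depth / h`.
#'
#' @param grid a [reef_grid()].
#' @param ellipse_major,ellipse_minor velocity amplitudes of the tidal
#'   ellipse semi-axes \[m s^-1\].
#' @param orientation angle of the major axis from the x axis \[radians\].
#' @param residual steady residual velocity `c(u, v)` \[m s^-1\].
#' @param reference_depth depth used to convert velocity amplitudes to
#'   depth-integrated transports \[m\].
#' @inheritParams flow_from_streamfunction
#' @return A `flow_series`.
#' @examples
#' g <- make_island_reef(48, 48, dx = 50, island_radius = 5,
#'                       reef_flat_width = 6)
#' fl <- make_tidal_flow(g, ellipse_major = 0.15, ellipse_minor = 0.05)
#' f0 <- flow_at(fl, 3 * 3600)
#' max(abs(flow_divergence(fl, 3 * 3600)))  # ~ 0 by construction
#' @export
make_tidal_flow <- function(grid, ellipse_major, ellipse_minor = 0,
                            orientation = 0,
                            tidal_period = 12.42 * 3600,
                            springneap_period = 14.77 * 86400,
                            springneap_mod = 0.5,
                            residual = c(0, 0),
                            reference_depth = 10,
                            diffusivity = 5, times = NULL) {
  stopifnot(ellipse_major >= 0, ellipse_minor >= 0, reference_depth > 0)
  xc <- (0:grid$nx) * grid$dx
  yc <- (0:grid$ny) * grid$dy
  # uniform transport (U, V) has streamfunction psi = U*y - V*x
  psi_uv <- function(U, V)
    outer(rep(U, grid$nx + 1), yc) - outer(xc, rep(V, grid$ny + 1))
  qM <- ellipse_major * reference_depth
  qm <- ellipse_minor * reference_depth
  flow_from_streamfunction(
    grid,
    psi_cos = psi_uv(qM * cos(orientation), qM * sin(orientation)),
    psi_sin = psi_uv(-qm * sin(orientation), qm * cos(orientation)),
    psi_res = psi_uv(residual[1] * reference_depth,
                     residual[2] * reference_depth),
    tidal_period = tidal_period,
    springneap_period = springneap_period,
    springneap_mod = springneap_mod,
    diffusivity = diffusivity, times = times
  )
}

#' Evaluate face transports at a given time
#'
#' @param flow a `flow_series`.
#' @param t time \[s\].
#' @return List with `Fx` (`(nx+1) x ny`) and `Fy` (`nx x (ny+1)`) face
#'   transports \[m^3 s^-1\].
#' @export
flow_at <- function(flow, t) {
  env <- 1 + flow$sn_mod * cos(flow$sn_omega * t)
  cc <- env * cos(flow$omega * t)
  cs <- env * sin(flow$omega * t)
  list(Fx = flow$Fx_cos * cc + flow$Fx_sin * cs + flow$Fx_res,
       Fy = flow$Fy_cos * cc + flow$Fy_sin * cs + flow$Fy_res)
}

#' Discrete divergence of the face transports
#'
#' Net volume outflow per cell \[m^3 s^-1\]; identically zero (to round-off)
#' for any streamfunction-derived flow.
#'
#' @inheritParams flow_at
#' @return `nx x ny` matrix.
#' @export
flow_divergence <- function(flow, t) {
  f <- flow_at(flow, t)
  nx <- flow$nx; ny <- flow$ny
  (f$Fx[2:(nx + 1), , drop = FALSE] - f$Fx[1:nx, , drop = FALSE]) +
    (f$Fy[, 2:(ny + 1), drop = FALSE] - f$Fy[, 1:ny, drop = FALSE])
}

#' @export
print.flow_series <- function(x, ...) {
  amp <- sqrt(x$Fx_cos^2 + x$Fx_sin^2)
  cat(sprintf(
    "<flow_series> %d x %d cells | tide %.2f h, spring-neap %.2f d (mod %.2f)\n",
    x$nx, x$ny, x$tidal_period / 3600, x$springneap_period / 86400, x$sn_mod))
  cat(sprintf("  max tidal face transport %.3g m^3/s, K in [%.3g, %.3g] m^2/s\n",
              max(amp), min(x$K), max(x$K)))
  invisible(x)
}

#' Ambient temperature forcing for injection runs
#'
#' Describes the thermal environment of a paired control/injection
#' experiment: the ambient temperature used as initial condition and
#' open-boundary inflow value (optionally with a diurnal cycle peaking
#' mid-afternoon), and the temperature of the injected source water. The
#' study setting is source water drawn from a deep channel about 1 degree C
#' cooler than the ambient reef-flat water.
#'
#' @param mean_temp ambient mean temperature \[deg C\].
#' @param diurnal_amp amplitude of the diurnal ambient cycle \[deg C\]
#'   (0 = constant ambient).
#' @param source_temp temperature of the injected water \[deg C\]; must not
#'   exceed `mean_temp` (a cooling intervention).
#' @param peak_hour clock hour at which the diurnal cycle peaks.
#' @return Object of class `forcing_series`.
#' @examples
#' f <- make_forcing(mean_temp = 28, source_temp = 27)
#' f$mean_temp - f$source_temp  # 1 degree cooling contrast
#' @export
make_forcing <- function(mean_temp = 28, diurnal_amp = 0, source_temp = 27,
                         peak_hour = 15) {
  stopifnot(mean_temp > 0, mean_temp < 40, source_temp > 0, source_temp < 40,
            diurnal_amp >= 0)
  if (source_temp > mean_temp)
    stop("source_temp must not exceed mean_temp for a cooling scenario")
  structure(list(mean_temp = mean_temp, diurnal_amp = diurnal_amp,
                 source_temp = source_temp, peak_hour = peak_hour),
            class = "forcing_series")
}

#' Ambient boundary temperature at a given time
#' @param forcing a `forcing_series`.
#' @param t time \[s\] (clock time is `t` modulo 24 h from 00:00).
#' @return temperature \[deg C\].
#' @export
ambient_at <- function(forcing, t) {
  forcing$mean_temp + forcing$diurnal_amp *
    cos(2 * pi * ((t / 3600) %% 24 - forcing$peak_hour) / 24)
}
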