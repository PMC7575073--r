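# shared fixtures: all built in code at test time

# flat-bottomed grid (depth 5 m is inside the reef mask by design)
uniform_grid <- function(nx, ny = 3, dx = 10, depth = 5) {
  reef_grid(matrix(depth, nx, ny), dx = dx)
}

# steady uniform eastward flow with depth-integrated transport q [m^2/s]
channel_flow <- function(grid, q, K = 0) {
  psi <- outer(rep(q, grid$nx + 1), (0:grid$ny) * grid$dy)
  flow_from_streamfunction(grid, psi_res = psi, diffusivity = K)
}

# tidally oscillating closed gyre: streamfunction vanishes on the domain
# edge, so no volume crosses the open boundaries
gyre_flow <- function(grid, amplitude, K = 0, tidal_period = 12.42 * 3600,
                      springneap_mod = 0) {
  psi <- amplitude * outer(sin(pi * (0:grid$nx) / grid$nx),
                           sin(pi * (0:grid$ny) / grid$ny))
  flow_from_streamfunction(grid, psi_cos = psi, tidal_period = tidal_period,
                           springneap_mod = springneap_mod, diffusivity = K)
}

# volume-weighted tracer total of sample k
total_tracer <- function(traj, grid, k) {
  v <- traj$values[, , k]
  sum(v[!grid$land_mask] * grid$depth[!grid$land_mask]) * grid$cell_area
}

# iterative Colebrook-White solution, the independent friction-factor oracle
colebrook_factor <- function(Re, rel_roughness) {
  x <- 8 # 1/sqrt(f)
  for (i in 1:100) x <- -2 * log10(rel_roughness / 3.7 + 2.51 * x / Re)
  x^-2
}

max_abs_divergence <- function(flow, times) {
  max(vapply(times, function(t) max(abs(flow_divergence(flow, t))), 0))
}

# minimal hand-built age trajectory (for statistics-only tests)
manual_trajectory <- function(values_by_sample, times, nx, ny) {
  structure(list(
    values = array(unlist(values_by_sample), c(nx, ny, length(times))),
    times = times, kind = "age", dt = if (length(times) > 1) diff(times)[1] else 1,
    nx = nx, ny = ny), class = "tracer_trajectory")
}
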