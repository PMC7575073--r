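test_that("zero flow, zero diffusion and zero source leave the state unchanged", {
  g <- uniform_grid(12)
  fl <- flow_from_streamfunction(g)
  set.seed(1)
  init <- matrix(runif(12 * 3), 12, 3)
  s0 <- tracer_state(init, g)
  s1 <- step(s0, g, fl, solver_config(dt = 100))
  expect_equal(s1$values, s0$values)
  expect_equal(s1$time, 100)
})

test_that("a uniform tracer stays uniform under non-divergent closed flow", {
  g <- uniform_grid(24, 8)
  fl <- gyre_flow(g, amplitude = 40, K = 1)
  tr <- run_passive(g, fl, init = 3.7, duration = 12 * 3600,
                    sample_interval = 12 * 3600)
  expect_equal(max(abs(tr$values[, , 2] - 3.7)), 0, tolerance = 1e-12)
})

test_that("an advected top-hat moves at the flow speed and converges with dx", {
  u <- 0.2; h <- 5; t_end <- 2000
  err <- c()
  for (dx in c(40, 20, 10)) {
    nx <- 1200 / dx
    g <- reef_grid(matrix(h, nx, 3), dx = dx)
    fl <- channel_flow(g, q = u * h)
    init <- matrix(0, nx, 3)
    lo <- 200; hi <- 300  # top-hat between x = 200 and 300 m
    init[g$x > lo & g$x <= hi, ] <- 1
    tr <- run_passive(g, fl, init = init, duration = t_end,
                      sample_interval = t_end)
    prof <- tr$values[, 2, 2]
    centroid <- sum(g$x * prof) / sum(prof)
    centroid0 <- sum(g$x * init[, 2]) / sum(init[, 2])
    expect_lt(abs((centroid - centroid0) - u * t_end), dx)
    exact <- as.numeric(g$x > lo + u * t_end & g$x <= hi + u * t_end)
    err <- c(err, sum(abs(prof - exact)) * dx)
  }
  expect_true(all(diff(err) < 0))  # refinement reduces the L1 error
})

test_that("stepping refuses an unstable time step and reports the limit", {
  g <- uniform_grid(20)
  fl <- channel_flow(g, q = 2)
  dt_ok <- stable_dt(g, fl)
  expect_error(run_passive(g, fl, solver_config(dt = 10 * dt_ok),
                           init = 0, duration = 1000, sample_interval = 1000),
               "requires dt")
  expect_silent(run_passive(g, fl, solver_config(dt = 0.9 * dt_ok),
                            init = 0, duration = 1000, sample_interval = 1000))
})

test_that("age equals elapsed time exactly in a sealed all-reef basin", {
  g <- uniform_grid(10, 10, depth = 5)  # all cells < 10 m: all reef
  fl <- flow_from_streamfunction(g)     # no flow, no diffusion: sealed
  tr <- run_age(g, fl, config = solver_config(dt = 900),
                duration = 2 * 86400, sample_interval = 6 * 3600)
  for (k in seq_along(tr$times))
    expect_equal(max(abs(tr$values[, , k] - tr$times[k] / 86400)), 0,
                 tolerance = 1e-12)
})

test_that("age never exceeds elapsed time and never goes negative", {
  g <- make_island_reef(40, 40, dx = 50, island_radius = 5,
                        reef_flat_width = 5)
  fl <- make_tidal_flow(g, 0.2, 0.05, residual = c(0.02, 0))
  tr <- run_age(g, fl, duration = 2 * 86400)
  for (k in seq_along(tr$times)) {
    v <- tr$values[, , k]
    v <- v[is.finite(v)]
    expect_gte(min(v), 0)
    expect_lte(max(v), tr$times[k] / 86400 + 1e-12)
  }
})

test_that("steady-channel age at the strip exit equals length over speed", {
  # 1000 m reef strip, u = 0.1 m/s inside the strip, K = 0:
  # steady age at the exit is L/u = 1e4 s = 0.1157 d
  dep <- matrix(12, 150, 3); dep[51:150, ] <- 5
  g <- reef_grid(dep, dx = 10)
  fl <- channel_flow(g, q = 0.5)  # u = q/h = 0.1 m/s over the strip
  tr <- run_age(g, fl, duration = 8e4, sample_interval = 2e4)
  exit_age <- tr$values[150, 2, length(tr$times)]
  expect_equal(exit_age, 1000 / 0.1 / 86400, tolerance = 0.05)
})

test_that("cells upstream of the reef stay at age zero", {
  dep <- matrix(12, 150, 3); dep[51:150, ] <- 5
  g <- reef_grid(dep, dx = 10)
  fl <- channel_flow(g, q = 0.5)
  tr <- run_age(g, fl, duration = 8e4, sample_interval = 4e4)
  expect_equal(max(abs(tr$values[1:40, , length(tr$times)])), 0)
})

test_that("paired runs are identical when the injection cannot act", {
  g <- uniform_grid(10, 10, depth = 8)
  fl <- gyre_flow(g, amplitude = 20, K = 2)
  f_equal <- make_forcing(mean_temp = 28, source_temp = 28)
  r1 <- run_injection(g, fl, forcing = f_equal,
                      sites = list(injection_site(5, 5, 1)),
                      duration = 86400, sample_interval = 6 * 3600)
  expect_equal(r1$injected$values, r1$control$values)

  f_cool <- make_forcing(28, source_temp = 27)
  r2 <- run_injection(g, fl, forcing = f_cool,
                      sites = list(injection_site(5, 5, 0)),  # Q = 0
                      duration = 86400, sample_interval = 6 * 3600)
  expect_equal(r2$injected$values, r2$control$values)
})

test_that("closed stagnant basin follows the exponential flushing solution", {
  d <- matrix(0, 3, 3); d[2, 2] <- 10
  g <- reef_grid(d, dx = 10)       # one wet cell, V = 1000 m^3
  fl <- flow_from_streamfunction(g)
  f <- make_forcing(28, source_temp = 27)
  r <- run_injection(g, fl, forcing = f,
                     sites = list(injection_site(2, 2, 0.02)),
                     duration = 1e5, sample_interval = 1e4)
  got <- r$injected$values[2, 2, ]
  expect_equal(got, 27 + exp(-0.02 * r$injected$times / 1000),
               tolerance = 0.01)

  # well-mixed multi-cell basin: mixing much faster than flushing
  g2 <- uniform_grid(3, 3, depth = 10)
  fl2 <- flow_from_streamfunction(g2, diffusivity = 50)
  Vb <- sum(g2$depth) * g2$cell_area
  r2 <- run_injection(g2, fl2, forcing = f,
                      sites = list(injection_site(2, 2, 0.2)),
                      duration = 9e4, sample_interval = 9e3)
  mean_T <- apply(r2$injected$values, 3, mean)
  expect_equal(mean_T, 27 + exp(-0.2 * r2$injected$times / Vb),
               tolerance = 0.01)
})

test_that("temperatures stay inside the ambient-source convex hull", {
  g <- make_island_reef(40, 40, dx = 50, island_radius = 5,
                        reef_flat_width = 5)
  fl <- make_tidal_flow(g, 0.2, 0.05)
  f <- make_forcing(28, diurnal_amp = 0.5, source_temp = 27)
  wet <- which(!g$land_mask, arr.ind = TRUE)
  site <- wet[which.min((wet[, 1] - 20)^2 + (wet[, 2] - 15)^2), ]
  r <- run_injection(g, fl, forcing = f,
                     sites = list(injection_site(site[1], site[2], 5)),
                     duration = 2 * 86400, sample_interval = 6 * 3600)
  v <- r$injected$values[is.finite(r$injected$values)]
  expect_gte(min(v), 27)
  expect_lte(max(v), 28.5)  # ambient mean + diurnal amplitude
})

test_that("the closed-basin heat deficit grows as the mixing source dictates", {
  # per step, V_site (T_new - T_old) = (T_old - T_inj)(e^{-Q dt/V} - 1) V:
  # over a sample interval the domain-integrated deficit must match the
  # injected heat exactly (no other sink in a closed stagnant domain)
  g <- uniform_grid(4, 4, depth = 10)
  fl <- flow_from_streamfunction(g, diffusivity = 10)
  f <- make_forcing(28, source_temp = 27)
  r <- run_injection(g, fl, forcing = f,
                     sites = list(injection_site(2, 3, 0.1)),
                     duration = 4e4, sample_interval = 4e3)
  deficit <- apply(r$injected$values, 3, function(m)
    sum((28 - m) * g$depth) * g$cell_area)
  expect_true(all(diff(deficit) > 0))
  # mixing (K) is much faster than flushing, so the integrated deficit
  # follows the well-mixed exponential budget
  Vb <- sum(g$depth) * g$cell_area
  expect_equal(deficit / Vb, 1 - exp(-0.1 * r$injected$times / Vb),
               tolerance = 0.01)
})

test_that("a daily injection window only acts between its clock hours", {
  d <- matrix(0, 3, 3); d[2, 2] <- 10
  g <- reef_grid(d, dx = 10)
  fl <- flow_from_streamfunction(g)
  f <- make_forcing(28, source_temp = 27)
  r <- run_injection(g, fl, forcing = f,
                     sites = list(injection_site(2, 2, 0.01,
                                                 schedule = c(11, 14))),
                     duration = 86400, sample_interval = 3600)
  Tcell <- r$injected$values[2, 2, ]
  hours <- r$injected$times / 3600
  expect_equal(Tcell[hours <= 11], rep(28, sum(hours <= 11)))  # idle before
  expect_lt(Tcell[hours == 14], 28)                            # acted during
  expect_equal(Tcell[hours == 24], Tcell[hours == 14])         # idle after
})

test_that("injection sites on land or off-grid are rejected", {
  g <- make_island_reef(40, 40, dx = 50, island_radius = 5,
                        reef_flat_width = 5)
  fl <- make_tidal_flow(g, 0.1)
  f <- make_forcing(28, source_temp = 27)
  land <- which(g$land_mask, arr.ind = TRUE)[1, ]
  expect_error(run_injection(g, fl, forcing = f, duration = 3600,
                             sites = list(injection_site(land[1], land[2], 1))),
               "land")
  expect_error(run_injection(g, fl, forcing = f, duration = 3600,
                             sites = list(injection_site(1000, 1, 1))),
               "outside")
})
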