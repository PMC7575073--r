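test_that("all-ocean parameters give empty reef and footprint masks", {
  g <- make_island_reef(32, 32, dx = 50, island_radius = 0,
                        reef_flat_width = 5, ocean_depth = 30,
                        channel_depth = 40)
  expect_false(any(g$reef_mask))
  expect_false(any(g$footprint_mask))
  expect_false(any(g$land_mask))
})

test_that("reef-flat area matches a brute-force annulus cell count", {
  nx <- ny <- 64; dx <- 40
  ir <- 10; fw <- 5
  g <- make_island_reef(nx, ny, dx, island_radius = ir, reef_flat_width = fw,
                        lagoon_width = 4, channel_offset = 2)
  # oracle: count cells whose centre lies in the annulus drawn by the
  # generator (same centre convention, direct distance test)
  ci <- 0.5 * nx; cj <- 0.62 * ny
  r <- sqrt(outer((seq_len(nx) - ci)^2, (seq_len(ny) - cj)^2, `+`))
  annulus <- r > ir & r <= ir + fw
  expect_identical(sum(g$reef_mask), sum(annulus))
  expect_equal(sum(g$reef_mask) * dx^2, sum(annulus) * dx^2)
})

test_that("deep channel lies outside the footprint and at full depth", {
  g <- make_island_reef(48, 48, dx = 50, island_radius = 5,
                        reef_flat_width = 6, channel_depth = 40,
                        channel_width = 3, channel_offset = 4)
  ch <- g$depth == 40
  expect_true(any(ch))
  expect_equal(min(g$depth[ch]), 40)
  expect_false(any(g$footprint_mask[ch]))
})

test_that("masks nest and exclude land for a range of island geometries", {
  cases <- expand.grid(ir = c(0, 4, 8), fw = c(3, 6), seed = c(1, 7))
  for (k in seq_len(nrow(cases))) {
    g <- make_island_reef(64, 64, dx = 50, island_radius = cases$ir[k],
                          reef_flat_width = cases$fw[k], seed = cases$seed[k])
    expect_true(all(g$footprint_mask[g$reef_mask]))
    expect_false(any(g$land_mask & g$reef_mask))
    expect_false(any(g$land_mask & g$footprint_mask))
    expect_true(all(g$depth >= 0))
  }
})

test_that("identical seeds reproduce bit-identical grids and flows", {
  make <- function() {
    g <- make_island_reef(48, 48, dx = 50, island_radius = 6,
                          reef_flat_width = 6, seed = 42)
    list(g = g, f = make_tidal_flow(g, 0.2, 0.07, orientation = 0.5))
  }
  a <- make(); b <- make()
  expect_identical(a$g$depth, b$g$depth)
  expect_identical(flow_at(a$f, 9999), flow_at(b$f, 9999))
})

test_that("domain too small for the island is a parameter error", {
  expect_error(make_island_reef(20, 20, dx = 50, island_radius = 8,
                                reef_flat_width = 8),
               "too small")
})

test_that("zero tidal and residual forcing gives zero transports always", {
  g <- make_island_reef(32, 32, dx = 50, island_radius = 4,
                        reef_flat_width = 4)
  fl <- make_tidal_flow(g, ellipse_major = 0, ellipse_minor = 0,
                        residual = c(0, 0))
  for (t in c(0, 3600, 1e5)) {
    f <- flow_at(fl, t)
    expect_identical(max(abs(f$Fx)), 0)
    expect_identical(max(abs(f$Fy)), 0)
  }
})

test_that("discrete divergence vanishes for arbitrary tidal flows", {
  g <- make_island_reef(48, 48, dx = 50, island_radius = 6,
                        reef_flat_width = 6)
  fl <- make_tidal_flow(g, 0.3, 0.1, orientation = 1.1,
                        residual = c(0.03, -0.02), springneap_mod = 0.4)
  scale <- max(abs(flow_at(fl, 0)$Fx))
  tt <- seq(0, 20 * 86400, length.out = 17)
  expect_lt(max_abs_divergence(fl, tt) / scale, 1e-12)
})

test_that("transports are zero across every land face", {
  g <- make_island_reef(48, 48, dx = 50, island_radius = 6,
                        reef_flat_width = 6)
  fl <- make_tidal_flow(g, 0.25, 0.1, orientation = 0.8, residual = c(0.02, 0))
  f <- flow_at(fl, 4321)
  land <- g$land_mask
  for (j in seq_len(g$ny)) for (i in seq_len(g$nx)) {
    if (!land[i, j]) next
    expect_identical(f$Fx[i, j], 0)     # west face
    expect_identical(f$Fx[i + 1, j], 0) # east face
    expect_identical(f$Fy[i, j], 0)     # south face
    expect_identical(f$Fy[i, j + 1], 0) # north face
  }
})

test_that("spring-neap envelope modulates tidal amplitude by (1+m)/(1-m)", {
  g <- uniform_grid(16)
  fl <- make_tidal_flow(g, ellipse_major = 0.2, springneap_mod = 0.5,
                        springneap_period = 14.77 * 86400)
  # amplitude of the tidal transport at spring (t = 0) vs neap (half period)
  amp_at <- function(t) {
    env <- 1 + fl$sn_mod * cos(fl$sn_omega * t)
    env * max(sqrt(fl$Fx_cos^2 + fl$Fx_sin^2))
  }
  expect_equal(amp_at(0) / amp_at(14.77 * 86400 / 2), 3, tolerance = 1e-12)
})

test_that("forcing validates the cooling contrast and diurnal cycle", {
  f <- make_forcing(mean_temp = 28, source_temp = 27)
  expect_equal(f$mean_temp - f$source_temp, 1)
  expect_error(make_forcing(mean_temp = 27, source_temp = 28), "cooling")
  const <- make_forcing(28, diurnal_amp = 0, source_temp = 27)
  expect_equal(ambient_at(const, seq(0, 86400, by = 3600)),
               rep(28, 25))
  diur <- make_forcing(28, diurnal_amp = 1, source_temp = 27, peak_hour = 15)
  expect_equal(ambient_at(diur, 15 * 3600), 29)
  expect_equal(ambient_at(diur, 3 * 3600), 27)
})
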