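#' Construct a reef grid from a bathymetry matrix
#'
#' A `reef_grid` is the spatial container every other stage works on: a
#' regular finite-volume grid of rectangular cells with a static bottom depth
#' per cell. Depth is positive down and a depth of exactly 0 marks dry land.
#' Two nested habitat masks are derived from depth following the analysis
#' conventions: the *reef* mask (source region of the reef-age tracer) holds
#' cells with 0 < depth < 10 m, and the *footprint* mask (over which cooled
#' area is tallied) holds cells with 0 < depth < 20 m.
#'
#' @param depth numeric matrix `nx` by `ny` of bottom depths in metres,
#'   positive down; 0 = land. Row index increases eastward (x), column index
#'   northward (y).
#' @param dx,dy cell sizes in metres (`dy` defaults to `dx`).
#' @return An object of class `reef_grid`: a list with `nx`, `ny`, `dx`,
#'   `dy`, `depth`, `cell_area` (m^2), logical masks `reef_mask`,
#'   `footprint_mask`, `land_mask`, and cell-centre coordinates `x`, `y` (m).
#' @examples
#' g <- reef_grid(matrix(c(0, 5, 15, 30), 2, 2), dx = 100)
#' g$reef_mask      # only the 5 m cell
#' g$footprint_mask # the 5 m and 15 m cells
#' @export
reef_grid <- function(depth, dx, dy = dx) {
  stopifnot(is.matrix(depth), dx > 0, dy > 0)
  if (!all(is.finite(depth)) || any(depth < 0))
    stop("depth must be finite and >= 0 (0 = land)")
  structure(list(
    nx = nrow(depth), ny = ncol(depth), dx = dx, dy = dy,
    depth = depth,
    cell_area = dx * dy,
    land_mask = depth == 0,
    reef_mask = depth > 0 & depth < 10,
    footprint_mask = depth > 0 & depth < 20,
    x = (seq_len(nrow(depth)) - 0.5) * dx,
    y = (seq_len(ncol(depth)) - 0.5) * dy
  ), class = "reef_grid")
}

#' @export
print.reef_grid <- function(x, ...) {
  cat(sprintf("<reef_grid> %d x %d cells, dx = %g m, dy = %g m\n",
              x$nx, x$ny, x$dx, x$dy))
  cat(sprintf("  land %d | reef (<10 m) %d | footprint (<20 m) %d cells\n",
              sum(x$land_mask), sum(x$reef_mask), sum(x$footprint_mask)))
  cat(sprintf("  reef area %.3f km^2, footprint area %.1f ha\n",
              sum(x$reef_mask) * x$cell_area / 1e6,
              sum(x$footprint_mask) * x$cell_area / 1e4))
  invisible(x)
}

#' Generate an idealized island reef bathymetry
#'
#' Builds the synthetic setting the feasibility analysis assumes: a circular
#' island (land core) fringed by a shallow annular reef flat, a deeper lagoon
#' ring grading into open ocean, and a deep channel strip to the south of the
#' island holding the cool source water. Geometric parameters are in cell
#' units so masks can be checked by direct cell counting.
#'
#' With `island_radius = 0` no island is drawn at all (land core, reef flat
#' and lagoon rings are skipped) and the grid is uniform open ocean apart
#' from the channel.
#'
#' Mild seeded Gaussian roughness (`depth_noise`, metres, sd) is added to the
#' reef flat and lagoon rings so fields are not perfectly symmetric; it is
#' clamped well clear of the 10 m and 20 m mask thresholds, so the masks
#' remain exactly the drawn annuli. The generator is deterministic for a
#' fixed seed.
#'
#' @param nx,ny grid dimensions in cells.
#' @param dx cell size \[m\] (cells are square).
#' @param island_radius radius of the land core \[cells\]; 0 = no island.
#' @param reef_flat_width width of the shallow reef-flat annulus \[cells\].
#' @param reef_flat_depth depth of the reef flat \[m\]; must be < 10 so the
#'   flat lies inside the reef mask.
#' @param lagoon_width,lagoon_depth width \[cells\] and depth \[m\] of the
#'   ring between reef flat and open ocean; the 15 m default places it inside
#'   the footprint but outside the reef mask.
#' @param channel_depth depth of the channel strip \[m\] (default 40, the
#'   deep cool-water source).
#' @param channel_width width of the channel strip \[cells\].
#' @param channel_offset distance of the channel strip from the southern
#'   domain edge \[cells\]; default ~12% of `ny`.
#' @param ocean_depth open-ocean depth \[m\]; must be >= 20 so the open ocean
#'   stays outside the footprint mask.
#' @param centre island centre as fractions of the domain (x, y).
#' @param depth_noise sd \[m\] of seeded roughness on reef flat and lagoon.
#' @param seed integer seed controlling the roughness.
#' @return A [reef_grid()].
#' @examples
#' g <- make_island_reef(64, 64, dx = 50, island_radius = 6,
#'                       reef_flat_width = 8)
#' print(g)
#' @export
make_island_reef <- function(nx, ny, dx,
                             island_radius, reef_flat_width,
                             reef_flat_depth = 3,
                             lagoon_width = 6, lagoon_depth = 15,
                             channel_depth = 40, channel_width = 3,
                             channel_offset = max(2L, round(0.12 * ny)),
                             ocean_depth = 30,
                             centre = c(0.5, 0.62),
                             depth_noise = 0.2, seed = 1L) {
  stopifnot(nx >= 2, ny >= 2, dx > 0)
  if (reef_flat_depth <= 0 || reef_flat_depth >= 10)
    stop("reef_flat_depth must lie in (0, 10) m")
  if (ocean_depth < 20)
    stop("ocean_depth must be >= 20 m so open ocean is outside the footprint")
  depth <- matrix(ocean_depth, nx, ny)

  # channel strip (full width, overwritten later by the island if they touch)
  j_ch <- channel_offset + seq_len(channel_width)
  j_ch <- j_ch[j_ch >= 1 & j_ch <= ny]
  depth[, j_ch] <- channel_depth

  if (island_radius > 0) {
    ci <- centre[1] * nx
    cj <- centre[2] * ny
    r_tot <- island_radius + reef_flat_width + lagoon_width
    r_fit <- island_radius + reef_flat_width   # lagoon ring may clip the edge
    if (ci - r_fit < 1 || ci + r_fit > nx || cj - r_fit < 1 || cj + r_fit > ny)
      stop("domain too small to contain the island and its reef flat")
    r <- sqrt(outer((seq_len(nx) - ci)^2, (seq_len(ny) - cj)^2, `+`))
    depth[r <= r_tot] <- lagoon_depth
    depth[r <= island_radius + reef_flat_width] <- reef_flat_depth
    depth[r <= island_radius] <- 0

    # seeded roughness, clamped clear of the 10/20 m mask thresholds
    if (depth_noise > 0) {
      set.seed(as.integer(seed))
      noise <- matrix(rnorm(nx * ny, sd = depth_noise), nx, ny)
      flat <- depth == reef_flat_depth & r <= island_radius + reef_flat_width
      lag  <- depth == lagoon_depth & r <= r_tot
      depth[flat] <- pmin(pmax(depth[flat] + noise[flat], 0.5), 9.5)
      depth[lag]  <- pmin(pmax(depth[lag] + noise[lag], 10.5), 19.5)
    }
  }
  reef_grid(depth, dx)
}
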