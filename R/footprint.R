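#' Time-mean temperature reduction attributed to an injection
#'
#' Per-cell time mean of control minus injected temperature over the
#' averaging window; positive values are cooling. The window should span a
#' full spring-neap cycle so the mean is not biased toward spring or neap
#' flushing (a shorter window raises a warning).
#'
#' @param control,injected `tracer_trajectory` objects from the same paired
#'   run (an `injection_run` can be passed as `control` with
#'   `injected` missing).
#' @param window time window `c(start, end)` \[s\]; default the whole
#'   trajectory.
#' @param springneap_period spring-neap period \[s\] used for the window
#'   length check.
#' @return `nx x ny` matrix of mean temperature reduction \[deg C\]
#'   (`NA` on land).
#' @export
mean_reduction_field <- function(control, injected = NULL, window = NULL,
                                 springneap_period = 14.77 * 86400) {
  if (inherits(control, "injection_run")) {
    injected <- control$injected
    control <- control$control
  }
  stopifnot(inherits(control, "tracer_trajectory"),
            inherits(injected, "tracer_trajectory"))
  if (length(control$times) != length(injected$times) ||
      max(abs(control$times - injected$times)) > 1e-6)
    stop("control and injected trajectories have misaligned time axes")
  times <- control$times
  if (is.null(window)) window <- range(times)
  if (diff(window) < springneap_period * (1 - 1e-9))
    warning("averaging window is shorter than a spring-neap cycle")
  idx <- which(times >= window[1] - 1e-6 & times <= window[2] + 1e-6)
  if (!length(idx)) stop("no samples inside the window")
  d <- control$values[, , idx, drop = FALSE] -
    injected$values[, , idx, drop = FALSE]
  apply(d, c(1, 2), mean)
}

#' Histogram of reef area by temperature reduction
#'
#' Bins the footprint cells (depth < 20 m) of a mean-reduction field into
#' half-open cooling bins `[lo, hi)` of width `bin_width` and tallies the
#' area (hectares) per bin — the area-vs-reduction histogram used to report
#' an injection's cooling footprint. Cells that warmed (negative reduction)
#' are collected in a single `< 0` bin and excluded from threshold areas.
#' Bins with area at or below `cutoff` are flagged as not displayed but
#' retained.
#'
#' @param delta_t mean reduction field \[deg C\] from
#'   [mean_reduction_field()].
#' @param grid the [reef_grid()].
#' @param bin_width bin width \[deg C\] (default 0.05).
#' @param cutoff display cutoff \[ha\] (default 1).
#' @return Object of class `cooling_footprint`: `bins` (data.frame with
#'   `lo`, `hi`, `area_ha`, `displayed`), `negative_area_ha`,
#'   `total_footprint_ha`, `bin_width`, `cutoff`.
#' @export
footprint_histogram <- function(delta_t, grid, bin_width = 0.05, cutoff = 1) {
  stopifnot(all(dim(delta_t) == c(grid$nx, grid$ny)), bin_width > 0)
  vals <- delta_t[grid$footprint_mask]
  vals <- vals[is.finite(vals)]
  area_ha <- grid$cell_area / 1e4
  nbin <- max(1L, as.integer(ceiling(max(vals, 0) / bin_width + 1e-9)))
  lo <- (seq_len(nbin) - 1) * bin_width
  pos <- vals >= 0
  # half-open bins [lo, hi): bin index floor(v / width)
  bidx <- pmin(floor(vals[pos] / bin_width), nbin - 1) + 1
  area <- vapply(seq_len(nbin), function(b) sum(bidx == b) * area_ha, 0)
  structure(list(
    bins = data.frame(lo = lo, hi = lo + bin_width, area_ha = area,
                      displayed = area > cutoff),
    negative_area_ha = sum(!pos) * area_ha,
    total_footprint_ha = sum(grid$footprint_mask) * area_ha,
    bin_width = bin_width, cutoff = cutoff
  ), class = "cooling_footprint")
}

#' @export
print.cooling_footprint <- function(x, ...) {
  cat(sprintf("<cooling_footprint> %.0f ha footprint, %.2f deg C bins (display cutoff %g ha)\n",
              x$total_footprint_ha, x$bin_width, x$cutoff))
  shown <- x$bins[x$bins$displayed & x$bins$area_ha > 0, ]
  if (nrow(shown)) {
    for (r in seq_len(nrow(shown)))
      cat(sprintf("  [%.2f, %.2f) degC : %8.1f ha\n",
                  shown$lo[r], shown$hi[r], shown$area_ha[r]))
  } else cat("  (no bin above the display cutoff)\n")
  if (x$negative_area_ha > 0)
    cat(sprintf("  < 0 degC (warming): %.1f ha\n", x$negative_area_ha))
  invisible(x)
}

#' Plot a cooling footprint histogram
#' @param x a `cooling_footprint`.
#' @param all_bins plot bins below the display cutoff too?
#' @param ... passed to [graphics::barplot()].
#' @export
plot.cooling_footprint <- function(x, all_bins = FALSE, ...) {
  b <- x$bins
  if (!all_bins) b$area_ha[!b$displayed] <- 0
  graphics::barplot(b$area_ha, names.arg = sprintf("%.2f", b$lo),
                    xlab = "temperature reduction [deg C]",
                    ylab = "reef area [ha]", ...)
  invisible(x)
}

#' Cooled area at or above a reduction threshold
#'
#' Sum of footprint bin areas whose lower edge is at or above `threshold`.
#' The threshold must align with a bin edge; no interpolation inside bins is
#' attempted.
#'
#' @param footprint a [footprint_histogram()] result.
#' @param threshold temperature reduction \[deg C\].
#' @return area \[ha\].
#' @examples
#' # a field cooled uniformly by 0.12 degC over 10 ha scores fully at 0.10
#' g <- reef_grid(matrix(15, 10, 10), dx = 100)  # 1 ha cells, all footprint
#' f <- footprint_histogram(matrix(0.12, 10, 10), g)
#' area_at_threshold(f, 0.10)
#' @export
area_at_threshold <- function(footprint, threshold) {
  stopifnot(inherits(footprint, "cooling_footprint"), threshold >= 0)
  k <- threshold / footprint$bin_width
  if (abs(k - round(k)) > 1e-8)
    stop(sprintf("threshold %g is not aligned with a %g-wide bin edge",
                 threshold, footprint$bin_width))
  sum(footprint$bins$area_ha[footprint$bins$lo >= threshold - 1e-12])
}

#' Degree Heating Week reduction of a sustained cooling
#'
#' Degree Heating Weeks accumulate thermal stress as degC-weeks; a cooling
#' of `delta_t` sustained for `days` days removes `delta_t * days / 7` DHW.
#'
#' @param delta_t sustained temperature reduction \[deg C\].
#' @param days duration \[d\].
#' @return Object of class `dhw_reduction` with the reduction in
#'   \[degC-weeks\].
#' @examples
#' dhw_reduction(0.15, 90)  # a summer of 0.15 degC cooling ~ 1.93 DHW
#' @export
dhw_reduction <- function(delta_t, days) {
  stopifnot(delta_t >= 0, days >= 0)
  structure(list(delta_t = delta_t, days = days, dhw = delta_t * days / 7),
            class = "dhw_reduction")
}

#' @export
print.dhw_reduction <- function(x, ...) {
  cat(sprintf("<dhw_reduction> %.3g degC over %g d = %.3g DHW\n",
              x$delta_t, x$days, x$dhw))
  invisible(x)
}

#' Export a cooling footprint as CSV
#' @param footprint a `cooling_footprint`.
#' @param path output CSV path (columns lo, hi, area_ha, displayed).
#' @return the bins data.frame, invisibly.
#' @export
export_footprint_csv <- function(footprint, path) {
  write.csv(footprint$bins, path, row.names = FALSE)
  invisible(footprint$bins)
}
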