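#' Residence-time statistics of a reef-age trajectory
#'
#' Pools the age of every shallow cell (depth < 10 m) at every 3-hourly
#' sample in the window and summarizes the pooled distribution: mean,
#' median, first and third quartiles and range, plus the shallow area.
#' These are the statistics used to compare and rank reefs by how long
#' water resides over them.
#'
#' Quartiles use the linear-interpolation convention (`quantile` type 7).
#'
#' @param states a `tracer_trajectory` from [run_age()].
#' @param grid the [reef_grid()] the trajectory was run on.
#' @param sample_interval pooling interval \[s\] (default 3 h); the
#'   trajectory must be sampled at least this often.
#' @param window time window `c(start, end)` \[s\]; default the whole
#'   trajectory.
#' @param label reef name carried into the summary.
#' @return Object of class `age_summary`: label, `shallow_area_km2`, and
#'   `mean`, `median`, `q1`, `q3`, `min`, `max` of age \[d\], with the
#'   number of pooled values in `n`.
#' @export
age_statistics <- function(states, grid, sample_interval = 3 * 3600,
                           window = NULL, label = "reef") {
  stopifnot(inherits(states, "tracer_trajectory"))
  if (!any(grid$reef_mask))
    stop("no shallow cells (depth < 10 m): cannot compute reef-age statistics")
  times <- states$times
  if (is.null(window)) window <- range(times)
  in_win <- times >= window[1] - 1e-6 & times <= window[2] + 1e-6
  if (!any(in_win)) stop("no samples inside the window")
  tw <- times[in_win]
  if (length(tw) > 1 && max(diff(tw)) > sample_interval * (1 + 1e-9))
    stop("trajectory is sampled more coarsely than sample_interval")
  # take samples on the sample_interval lattice anchored at the window start
  keep <- abs((tw - tw[1]) %% sample_interval) < 1e-6 |
    abs((tw - tw[1]) %% sample_interval - sample_interval) < 1e-6
  idx <- which(in_win)[keep]
  vals <- states$values[, , idx, drop = FALSE]
  pooled <- as.vector(vals[rep(grid$reef_mask, length(idx))])
  pooled <- pooled[is.finite(pooled)]
  q <- unname(quantile(pooled, c(0.25, 0.5, 0.75), type = 7))
  structure(list(label = label,
                 shallow_area_km2 = sum(grid$reef_mask) * grid$cell_area / 1e6,
                 mean = mean(pooled), median = q[2], q1 = q[1], q3 = q[3],
                 min = min(pooled), max = max(pooled),
                 n = length(pooled)),
            class = "age_summary")
}

#' @export
print.age_summary <- function(x, ...) {
  cat(sprintf("<age_summary> %s (%.3f km^2 shallow)\n", x$label,
              x$shallow_area_km2))
  cat(sprintf("  age [d]: min %.3g | q1 %.3g | median %.3g | mean %.3g | q3 %.3g | max %.3g (n = %d)\n",
              x$min, x$q1, x$median, x$mean, x$q3, x$max, x$n))
  invisible(x)
}

#' Rank reefs by residence time
#'
#' Orders reef summaries by decreasing mean age — the criterion for picking
#' reefs where injected cool water would linger longest — with ties broken
#' by decreasing median, then alphabetically by label.
#'
#' @param summaries list of [age_statistics()] results (a single
#'   `age_summary` is accepted).
#' @return `data.frame` with one row per reef, best candidate first.
#' @export
rank_reefs <- function(summaries) {
  if (inherits(summaries, "age_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1)
  df <- do.call(rbind, lapply(summaries, function(s) data.frame(
    label = s$label, shallow_area_km2 = s$shallow_area_km2,
    mean = s$mean, median = s$median, q1 = s$q1, q3 = s$q3,
    min = s$min, max = s$max, stringsAsFactors = FALSE)))
  df <- df[order(-df$mean, -df$median, df$label), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Export age summaries
#'
#' Writes the ranked table as CSV and, optionally, JSON.
#'
#' @param summaries list of `age_summary` objects.
#' @param csv,json output paths (either may be `NULL`).
#' @return The ranked `data.frame`, invisibly.
#' @export
export_age_summaries <- function(summaries, csv = NULL, json = NULL) {
  df <- rank_reefs(summaries)
  if (!is.null(csv)) write.csv(df, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(df, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  invisible(df)
}
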