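#' Remove low-accuracy fixes by dilution of precision
#'
#' Collar fixes with DOP at or above the threshold (default 8, strict `>=`)
#' are removed and their slots become gaps, to be reconstructed by
#' [interpolate_gaps()]. Fixes without a DOP value are kept.
#'
#' @param ts A `trackset`.
#' @param max_dop Removal threshold; a fix is dropped when `dop >= max_dop`.
#' @return The filtered `trackset`; removal counts (total and per component)
#'   are in `ts$log$dop_filter`.
#' @export
filter_by_dop <- function(ts, max_dop = 8) {
  stopifnot(inherits(ts, "trackset"), is.finite(max_dop), max_dop > 0)
  f <- ts$fixes
  drop <- !is.na(f$dop) & !is.na(f$lon) & f$dop >= max_dop
  per_comp <- tapply(drop, f$component_id, sum)[ts$components]
  f$lon[drop] <- NA_real_
  f$lat[drop] <- NA_real_
  f$elev_m[drop] <- NA_real_
  ts$fixes <- f
  n_obs <- sum(!is.na(f$lon)) + sum(drop)
  ts$log$dop_filter <- list(
    max_dop = max_dop, removed = sum(drop),
    removed_by_component = as.list(per_comp),
    fraction_removed = if (n_obs > 0) sum(drop) / n_obs else 0
  )
  if (n_obs > 0 && sum(drop) == n_obs)
    warning("DOP filter removed every fix", call. = FALSE)
  ts
}

#' Reconstruct interior gaps with piecewise cubic splines
#'
#' Each component's longitude, latitude and elevation are fitted with a
#' piecewise cubic spline against the true fix timestamps (so the overnight
#' span is represented at its real length) and evaluated at the empty grid
#' slots. Only interior gaps are filled; leading and trailing gaps are left
#' empty. Gaps whose bracketing observed fixes lie more than one calendar
#' day apart are not reconstructed (a spline has no information at that
#' range) and are reported instead.
#'
#' @param ts A `trackset` (typically after [filter_by_dop()]).
#' @return The `trackset` with interior gaps filled; counts in
#'   `ts$log$interpolate`. Reconstructed rows are marked in the logical
#'   column `interpolated`.
#' @export
interpolate_gaps <- function(ts) {
  stopifnot(inherits(ts, "trackset"))
  f <- ts$fixes
  if (is.null(f$interpolated)) f$interpolated <- FALSE
  filled <- 0L; skipped_long <- 0L; edge <- 0L
  for (comp in ts$components) {
    rows <- which(f$component_id == comp)
    rows <- rows[order(f$slot[rows])]
    obs <- rows[!is.na(f$lon[rows])]
    if (length(obs) < 4)
      stop("component ", comp, " has fewer than 4 valid fixes; ",
           "cannot fit a cubic spline", call. = FALSE)
    gap <- rows[is.na(f$lon[rows])]
    if (!length(gap)) next
    t_obs <- as.numeric(f$timestamp[obs])
    interior <- gap[f$slot[gap] > min(f$slot[obs]) &
                      f$slot[gap] < max(f$slot[obs])]
    edge <- edge + (length(gap) - length(interior))
    if (!length(interior)) next
    # bracketing observed fixes; skip gaps spanning > 1 calendar day
    d_obs <- as.Date(f$timestamp[obs])
    prev_i <- findInterval(f$slot[interior], f$slot[obs])
    span_ok <- as.integer(d_obs[prev_i + 1] - d_obs[prev_i]) <= 1
    skipped_long <- skipped_long + sum(!span_ok)
    fill <- interior[span_ok]
    if (!length(fill)) next
    t_fill <- as.numeric(f$timestamp[fill])
    for (v in c("lon", "lat", "elev_m")) {
      y <- f[[v]][obs]
      if (all(is.na(y))) next
      f[[v]][fill] <- stats::spline(t_obs, y, xout = t_fill,
                                    method = "fmm")$y
    }
    f$interpolated[fill] <- TRUE
    filled <- filled + length(fill)
  }
  ts$fixes <- f
  ts$log$interpolate <- list(filled = filled, skipped_long_gaps = skipped_long,
                             edge_gaps_left = edge)
  ts
}

# running mean with symmetric window shrink at the series ends
run_mean_shrink <- function(x, window) {
  n <- length(x)
  h <- (window - 1) / 2
  i <- seq_len(n)
  half <- pmin(i - 1, n - i, h)
  cs <- cumsum(x)
  lo <- i - half
  hi <- i + half
  (cs[hi] - c(0, cs[-n])[lo]) / (hi - lo + 1)
}

#' Smooth tracks with a centred moving average
#'
#' Each smoothed position is the coordinate-wise arithmetic mean of `window`
#' consecutive fixes centred on the slot; near the series ends the window
#' shrinks symmetrically, so constant and (interior) linear trajectories are
#' left unchanged. Smoothing is applied independently to each maximal run of
#' consecutive located slots.
#'
#' @param ts A `trackset` with interior gaps already reconstructed.
#' @param window Odd window length >= 1 (default 15 fixes).
#' @return The smoothed `trackset`.
#' @export
smooth_track <- function(ts, window = 15) {
  stopifnot(inherits(ts, "trackset"))
  if (!is.finite(window) || window < 1 || window %% 2 == 0)
    stop("window must be an odd integer >= 1", call. = FALSE)
  f <- ts$fixes
  for (comp in ts$components) {
    rows <- which(f$component_id == comp)
    rows <- rows[order(f$slot[rows])]
    ok <- !is.na(f$lon[rows])
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (r in which(runs$values)) {
      seg <- rows[starts[r]:ends[r]]
      if (length(seg) < 2) next
      for (v in c("lon", "lat", "elev_m")) {
        y <- f[[v]][seg]
        if (anyNA(y)) next
        f[[v]][seg] <- run_mean_shrink(y, window)
      }
    }
  }
  ts$fixes <- f
  ts$log$smooth <- list(window = window)
  ts
}

#' Run the full preprocessing chain
#'
#' Applies, in order: [filter_by_dop()], [interpolate_gaps()],
#' [smooth_track()], [align_tracks()]. The order is asserted by the
#' accumulated log.
#'
#' @param ts A `trackset` of raw fixes.
#' @param max_dop DOP removal threshold (default 8).
#' @param window Smoothing window (default 15).
#' @return The preprocessed, aligned `trackset`.
#' @export
preprocess_trackset <- function(ts, max_dop = 8, window = 15) {
  ts <- filter_by_dop(ts, max_dop)
  ts <- interpolate_gaps(ts)
  ts <- smooth_track(ts, window)
  align_tracks(ts)
}
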