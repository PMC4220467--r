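#' Diurnal sampling grid for collar fixes
#'
#' Collars record on a fixed diurnal schedule: `slots_per_day` fixes at
#' `interval_h`-hour spacing starting at `start_hour` local time (default
#' 8 fixes, every 2 h from 05:00 to 19:00). The overnight span is part of
#' the grid design, not missing data. Slots are numbered 1..n consecutively
#' across days.
#'
#' @param start_date Date (or string coercible to Date) of the first day.
#' @param n_days Number of sampling days (>= 1).
#' @param slots_per_day Fixes per day (default 8).
#' @param start_hour First fix hour of day (default 5).
#' @param interval_h Hours between fixes within a day (default 2).
#' @return An object of class `time_grid`.
#' @export
time_grid <- function(start_date, n_days, slots_per_day = 8,
                      start_hour = 5, interval_h = 2) {
  start_date <- as.Date(start_date)
  stopifnot(is.finite(n_days), n_days >= 1, slots_per_day >= 1,
            interval_h > 0, start_hour >= 0)
  if (start_hour + (slots_per_day - 1) * interval_h >= 24)
    stop("daily schedule exceeds 24 h", call. = FALSE)
  structure(
    list(start_date = start_date, n_days = as.integer(n_days),
         slots_per_day = as.integer(slots_per_day),
         start_hour = start_hour, interval_h = interval_h),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time_grid: %d days from %s, %d slots/day every %g h from %02d:00 (%d slots)\n",
              x$n_days, format(x$start_date), x$slots_per_day,
              x$interval_h, as.integer(x$start_hour), n_slots(x)))
  invisible(x)
}

#' Total number of slots in a grid
#' @param grid A `time_grid`.
#' @export
n_slots <- function(grid) grid$n_days * grid$slots_per_day

#' Timestamps of grid slots
#'
#' @param grid A `time_grid`.
#' @param slots Slot indices (default all).
#' @return POSIXct vector (UTC-stored naive local clock).
#' @export
slot_times <- function(grid, slots = seq_len(n_slots(grid))) {
  stopifnot(all(slots >= 1), all(slots <= n_slots(grid)))
  day <- (slots - 1) %/% grid$slots_per_day
  k <- (slots - 1) %% grid$slots_per_day
  as.POSIXct(as.numeric(as.POSIXct(grid$start_date, tz = "UTC")) +
               day * 86400 + (grid$start_hour + k * grid$interval_h) * 3600,
             origin = "1970-01-01", tz = "UTC")
}

#' Map timestamps to grid slot indices
#'
#' @param grid A `time_grid`.
#' @param times POSIXct timestamps (same naive-local convention as the grid).
#' @return Integer slot indices; `NA` for off-grid timestamps.
#' @export
slot_of_time <- function(grid, times) {
  t0 <- as.numeric(as.POSIXct(grid$start_date, tz = "UTC"))
  dt <- as.numeric(times) - t0
  day <- dt %/% 86400
  sec_in_day <- dt - day * 86400
  k <- (sec_in_day / 3600 - grid$start_hour) / grid$interval_h
  ok <- !is.na(dt) & day >= 0 & day < grid$n_days &
    abs(k - round(k)) < 1e-9 & round(k) >= 0 &
    round(k) < grid$slots_per_day
  out <- rep(NA_integer_, length(times))
  out[ok] <- as.integer(day[ok] * grid$slots_per_day + round(k[ok]) + 1)
  out
}
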