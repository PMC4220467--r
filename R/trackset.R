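#' Track sets: grid-aligned positions of several social components
#'
#' A `trackset` holds one grid-aligned track per social component. Internally
#' it is a long data frame with one row per component x slot (gaps carry `NA`
#' coordinates), the shared [time_grid()], the component identifiers, and a
#' `log` list accumulating preprocessing record counts.
#'
#' @param fixes Data frame with columns `component_id`, and either `slot` or
#'   `timestamp`, plus `lon`, `lat`, and optionally `elev_m`, `dop`.
#' @param grid A [time_grid()].
#' @param components Optional character vector fixing component order;
#'   defaults to sorted unique ids in `fixes`.
#' @return An object of class `trackset`.
#' @export
trackset <- function(fixes, grid, components = NULL) {
  stopifnot(inherits(grid, "time_grid"), is.data.frame(fixes))
  need <- c("component_id", "lon", "lat")
  if (!all(need %in% names(fixes)))
    stop("fixes must have columns component_id, lon, lat", call. = FALSE)
  fixes$component_id <- as.character(fixes$component_id)
  if (is.null(fixes$slot)) {
    if (is.null(fixes$timestamp))
      stop("fixes need a slot or timestamp column", call. = FALSE)
    fixes$slot <- slot_of_time(grid, fixes$timestamp)
    if (anyNA(fixes$slot))
      stop("off-grid timestamps in fixes; run validate_fixes() for details",
           call. = FALSE)
  }
  if (is.null(fixes$elev_m)) fixes$elev_m <- NA_real_
  if (is.null(fixes$dop)) fixes$dop <- NA_real_
  if (is.null(components)) components <- sort(unique(fixes$component_id))
  if (length(components) < 2)
    stop("a trackset needs at least 2 components", call. = FALSE)
  ns <- n_slots(grid)
  key <- paste(fixes$component_id, fixes$slot)
  if (anyDuplicated(key))
    stop("duplicate component/slot rows in fixes", call. = FALSE)

  # complete to the full grid, NA coordinates at empty slots
  full <- data.frame(
    component_id = rep(components, each = ns),
    slot = rep(seq_len(ns), length(components)),
    stringsAsFactors = FALSE
  )
  idx <- match(paste(full$component_id, full$slot), key)
  full$timestamp <- slot_times(grid, full$slot)
  full$lon <- fixes$lon[idx]
  full$lat <- fixes$lat[idx]
  full$elev_m <- fixes$elev_m[idx]
  full$dop <- fixes$dop[idx]
  ok <- !is.na(full$lon)
  if (any(ok)) check_lonlat(full$lon[ok], full$lat[ok])

  structure(
    list(fixes = full, grid = grid, components = components,
         slots = seq_len(ns), log = list()),
    class = "trackset"
  )
}

#' @export
print.trackset <- function(x, ...) {
  cat(sprintf("trackset: %d components (%s), %d/%d grid slots retained\n",
              length(x$components), paste(x$components, collapse = ", "),
              length(x$slots), n_slots(x$grid)))
  miss <- sum(is.na(x$fixes$lon[x$fixes$slot %in% x$slots]))
  cat(sprintf("  empty component-slots: %d; log stages: %s\n", miss,
              if (length(x$log)) paste(names(x$log), collapse = " -> ")
              else "(none)"))
  invisible(x)
}

# positions as slot x component matrices over the retained slots
position_matrices <- function(ts, what = c("lon", "lat", "elev_m")) {
  f <- ts$fixes[ts$fixes$slot %in% ts$slots, ]
  ord <- order(match(f$component_id, ts$components), f$slot)
  f <- f[ord, ]
  ns <- length(ts$slots)
  out <- lapply(what, function(v) {
    matrix(f[[v]], nrow = ns, ncol = length(ts$components),
           dimnames = list(NULL, ts$components))
  })
  names(out) <- what
  out
}

#' Restrict a trackset to slots where every component has a fix
#'
#' All association and affinity mathematics needs a complete panel: every
#' component located at every retained slot. Slots where any component is
#' missing (after interpolation) are dropped for all components; the number
#' of dropped slots is recorded in the trackset log.
#'
#' @param ts A `trackset`.
#' @return The aligned `trackset`.
#' @export
align_tracks <- function(ts) {
  stopifnot(inherits(ts, "trackset"))
  pm <- position_matrices(ts, "lon")$lon
  keep <- ts$slots[rowSums(is.na(pm)) == 0]
  if (length(keep) == 0)
    stop("no slot has all components located; cannot align", call. = FALSE)
  dropped <- length(ts$slots) - length(keep)
  ts$slots <- keep
  ts$log$align <- list(slots_kept = length(keep), slots_dropped = dropped)
  ts
}

#' Read and write delimited fix tables
#'
#' The pipeline's interchange format: comma-separated text with header
#' `component_id, timestamp, lon, lat, elev_m, dop`, timestamps in ISO-8601
#' (`YYYY-MM-DDTHH:MM:SS`), local naive clock.
#'
#' @param path File path.
#' @return `read_fixes`: a data frame of fixes.
#' @export
read_fixes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("component_id", "timestamp", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("fix table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$timestamp <- parse_iso_time(df$timestamp)
  if (anyNA(df$timestamp))
    stop("unparseable timestamps in ", path, call. = FALSE)
  if (is.null(df$elev_m)) df$elev_m <- NA_real_
  if (is.null(df$dop)) df$dop <- NA_real_
  df
}

parse_iso_time <- function(x) {
  # strptime yields NA (not an error) on malformed entries
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  alt <- is.na(out)
  if (any(alt))
    out[alt] <- as.POSIXct(strptime(x[alt], "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  out
}

#' @rdname read_fixes
#' @param fixes A data frame of fixes or a `trackset` (recorded slots only).
#' @export
write_fixes <- function(fixes, path) {
  if (inherits(fixes, "trackset")) {
    f <- fixes$fixes
    fixes <- f[f$slot %in% fixes$slots & !is.na(f$lon), ]
  }
  out <- data.frame(
    component_id = fixes$component_id,
    timestamp = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lon = sprintf("%.8f", fixes$lon),
    lat = sprintf("%.8f", fixes$lat),
    elev_m = ifelse(is.na(fixes$elev_m), "", sprintf("%.2f", fixes$elev_m)),
    dop = ifelse(is.na(fixes$dop), "", sprintf("%.3f", fixes$dop)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read GPX 1.1 track files
#'
#' Reads every `<trkpt>` of every `<trk>`; the track name becomes the
#' component id, `<ele>` the elevation and `<hdop>` (if present) the DOP.
#'
#' @param path Path to a GPX 1.1 file.
#' @return A fix data frame as from [read_fixes()].
#' @export
read_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  trks <- xml2::xml_find_all(doc, ".//trk")
  if (length(trks) == 0) stop("no <trk> elements in ", path, call. = FALSE)
  rows <- lapply(seq_along(trks), function(i) {
    trk <- trks[[i]]
    nm <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
    if (is.na(nm) || nm == "") nm <- paste0("track", i)
    pts <- xml2::xml_find_all(trk, ".//trkpt")
    ele <- as.numeric(xml2::xml_text(xml2::xml_find_first(pts, "./ele")))
    hdop <- as.numeric(xml2::xml_text(xml2::xml_find_first(pts, "./hdop")))
    tim <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
    data.frame(
      component_id = nm,
      timestamp = as.POSIXct(tim, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                            "%Y-%m-%dT%H:%M:%S")),
      lon = as.numeric(xml2::xml_attr(pts, "lon")),
      lat = as.numeric(xml2::xml_attr(pts, "lat")),
      elev_m = ele, dop = hdop, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a trackset as GPX 1.1
#'
#' One `<trk>` per component; DOP stored as `<hdop>`.
#'
#' @param ts A `trackset`.
#' @param path Output file.
#' @export
write_gpx <- function(ts, path) {
  stopifnot(inherits(ts, "trackset"))
  f <- ts$fixes[ts$fixes$slot %in% ts$slots & !is.na(ts$fixes$lon), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<gpx version="1.1" creator="telemsoc" xmlns="http://www.topografix.com/GPX/1/1">'),
             con)
  for (comp in ts$components) {
    g <- f[f$component_id == comp, ]
    writeLines(sprintf("  <trk><name>%s</name><trkseg>", comp), con)
    writeLines(sprintf(
      '    <trkpt lat="%.8f" lon="%.8f"><ele>%.2f</ele><time>%s</time>%s</trkpt>',
      g$lat, g$lon, ifelse(is.na(g$elev_m), 0, g$elev_m),
      format(g$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      ifelse(is.na(g$dop), "", sprintf("<hdop>%.3f</hdop>", g$dop))), con)
    writeLines("  </trkseg></trk>", con)
  }
  writeLines("</gpx>", con)
  invisible(path)
}

#' Validate a raw fix table
#'
#' Schema and sanity checks before any computation: required columns,
#' parseable timestamps, coordinate ranges, DOP positivity, duplicated
#' component/slot records and (when a grid is supplied) off-grid timestamps.
#' Fatal issues make the table unusable; warnings are informational.
#'
#' @param path Path to a delimited fix table.
#' @param grid Optional [time_grid()] to check timestamps against.
#' @return A list of class `fix_report` with data frames `fatal` and
#'   `warnings` (columns `line`, `issue`) and the number of rows read.
#' @export
validate_fixes <- function(path, grid = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  fatal <- list(); warn <- list()
  note <- function(store, line, issue)
    c(store, list(data.frame(line = line, issue = issue,
                             stringsAsFactors = FALSE)))
  need <- c("component_id", "timestamp", "lon", "lat")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    fatal <- note(fatal, 0L, paste("missing columns:",
                                   paste(missing_cols, collapse = ", ")))
  } else {
    line <- seq_len(nrow(raw)) + 1L  # header is line 1
    tt <- suppressWarnings(parse_iso_time(raw$timestamp))
    bad <- which(is.na(tt))
    for (i in bad) fatal <- note(fatal, line[i], "unparseable timestamp")
    bad <- which(!is.finite(raw$lat) | raw$lat < -90 | raw$lat > 90)
    for (i in bad)
      fatal <- note(fatal, line[i], sprintf("latitude out of range: %s",
                                            raw$lat[i]))
    bad <- which(!is.finite(raw$lon) | raw$lon < -180 | raw$lon > 180)
    for (i in bad)
      fatal <- note(fatal, line[i], sprintf("longitude out of range: %s",
                                            raw$lon[i]))
    if (!is.null(raw$dop)) {
      bad <- which(!is.na(raw$dop) & raw$dop <= 0)
      for (i in bad)
        fatal <- note(fatal, line[i], sprintf("nonpositive DOP: %s",
                                              raw$dop[i]))
    }
    key <- paste(raw$component_id, raw$timestamp)
    dup <- which(duplicated(key))
    for (i in dup)
      fatal <- note(fatal, line[i],
                    sprintf("duplicate slot for component %s at %s",
                            raw$component_id[i], raw$timestamp[i]))
    if (!is.null(grid)) {
      off <- which(!is.na(tt) & is.na(slot_of_time(grid, tt)))
      for (i in off)
        warn <- note(warn, line[i], sprintf("off-grid timestamp: %s",
                                            raw$timestamp[i]))
    }
  }
  empty <- data.frame(line = integer(), issue = character(),
                      stringsAsFactors = FALSE)
  structure(list(
    fatal = if (length(fatal)) do.call(rbind, fatal) else empty,
    warnings = if (length(warn)) do.call(rbind, warn) else empty,
    n_rows = nrow(raw)
  ), class = "fix_report")
}

#' @export
print.fix_report <- function(x, ...) {
  cat(sprintf("fix_report: %d rows, %d fatal issue(s), %d warning(s)\n",
              x$n_rows, nrow(x$fatal), nrow(x$warnings)))
  if (nrow(x$fatal)) print(utils::head(x$fatal, 10))
  invisible(x)
}
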