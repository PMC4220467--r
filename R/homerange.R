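#' Kernel utilization distribution of one component
#'
#' Bivariate Gaussian kernel density of a component's fixes on a local
#' planar grid (equirectangular projection at the component's mean
#' latitude, kilometres). The default bandwidth is the per-dimension
#' reference rule [stats::bw.nrd0()] (Silverman's rule of thumb), applied as
#' the kernel standard deviation; the grid extends at least `pad_bw`
#' bandwidths beyond the data hull and the density is renormalised to
#' integrate to 1.
#'
#' @param ts A `trackset`, or a data frame of fixes with `lon`, `lat`.
#' @param component Component id (required when `ts` is a trackset).
#' @param bandwidth Kernel s.d. in km (scalar or per-dimension pair), or
#'   `"reference"` for the reference rule.
#' @param grid_n Grid points per axis (default 200).
#' @param pad_bw Grid padding in bandwidths beyond the fix hull (default 3).
#' @param lon0,lat0 Optional shared projection reference (decimal degrees);
#'   set these to a common point when several components' ranges are to be
#'   compared, so all UDs live in one planar frame. Default: the component's
#'   own mean position.
#' @return An object of class `utilization_dist`: grid vectors `x`, `y`
#'   (km), density matrix `z` (1/km^2), `bandwidth_km`, `cell_km2`, the
#'   projection reference (`lon0`, `lat0`) and the component id.
#' @export
kde_utilization <- function(ts, component = NULL, bandwidth = "reference",
                            grid_n = 200, pad_bw = 3,
                            lon0 = NULL, lat0 = NULL) {
  if (inherits(ts, "trackset")) {
    if (is.null(component)) stop("component id required", call. = FALSE)
    f <- ts$fixes
    f <- f[f$component_id == component & f$slot %in% ts$slots &
             !is.na(f$lon), ]
  } else {
    f <- ts[!is.na(ts$lon), ]
    if (is.null(component)) component <- "track"
  }
  if (nrow(f) < 10) stop("need >= 10 fixes for a kernel estimate",
                         call. = FALSE)
  if (is.null(lon0)) lon0 <- mean(f$lon)
  if (is.null(lat0)) lat0 <- mean(f$lat)
  pr <- project_local_km(f$lon, f$lat, lon0 = lon0, lat0 = lat0)
  if (stats::sd(pr$x) == 0 && stats::sd(pr$y) == 0)
    stop("degenerate track: all fixes identical", call. = FALSE)
  if (identical(bandwidth, "reference")) {
    bw <- c(stats::bw.nrd0(pr$x), stats::bw.nrd0(pr$y))
  } else {
    bw <- rep(as.numeric(bandwidth), length.out = 2)
  }
  if (any(!is.finite(bw) | bw <= 0))
    stop("bandwidth must be positive", call. = FALSE)
  lims <- c(range(pr$x) + c(-1, 1) * pad_bw * bw[1],
            range(pr$y) + c(-1, 1) * pad_bw * bw[2])
  # MASS::kde2d uses kernel s.d. = h/4
  kd <- MASS::kde2d(pr$x, pr$y, h = 4 * bw, n = grid_n, lims = lims)
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  z <- kd$z / (sum(kd$z) * cell)
  structure(list(x = kd$x, y = kd$y, z = z, bandwidth_km = bw,
                 cell_km2 = cell, lon0 = pr$lon0, lat0 = pr$lat0,
                 component = component, n_fixes = nrow(f)),
            class = "utilization_dist")
}

#' @export
print.utilization_dist <- function(x, ...) {
  cat(sprintf("utilization_dist: %s, %d fixes, bw = (%.3f, %.3f) km, %dx%d grid\n",
              x$component, x$n_fixes, x$bandwidth_km[1], x$bandwidth_km[2],
              length(x$x), length(x$y)))
  invisible(x)
}

#' Isopleth home-range region of a utilization distribution
#'
#' The q-isopleth is the smallest-area density region containing total
#' probability at least q: cells are admitted in decreasing density order
#' until the cumulative probability reaches q. The region is traced as
#' closed polygons at the resulting density threshold and its area reported
#' in hectares (km^2 x 100).
#'
#' @param ud A `utilization_dist`.
#' @param q Isopleth level in (0, 1); default 0.95.
#' @return An object of class `range_polygon`: `level`, `area_ha`, polygon
#'   `rings` (list of x/y matrices, km), the grid `mask`, and the source
#'   grid.
#' @export
ud_contour <- function(ud, q = 0.95) {
  stopifnot(inherits(ud, "utilization_dist"))
  if (!is.finite(q) || q <= 0 || q >= 1)
    stop("q must be in (0, 1)", call. = FALSE)
  p <- as.vector(ud$z) * ud$cell_km2
  ord <- order(p, decreasing = TRUE)
  cum <- cumsum(p[ord])
  k <- which(cum >= q)[1]
  if (is.na(k)) k <- length(p)
  z_thresh <- as.vector(ud$z)[ord[k]]
  mask <- ud$z >= z_thresh
  area_km2 <- sum(mask) * ud$cell_km2
  cl <- grDevices::contourLines(ud$x, ud$y, ud$z, levels = z_thresh)
  rings <- lapply(cl, function(r) cbind(x = r$x, y = r$y))
  structure(list(level = q, area_ha = area_km2 * 100, rings = rings,
                 mask = mask, x = ud$x, y = ud$y, cell_km2 = ud$cell_km2,
                 density_threshold = z_thresh, component = ud$component),
            class = "range_polygon")
}

#' Build a range polygon from explicit ring coordinates
#'
#' For analytic or externally supplied regions. Rings follow the even-odd
#' rule (a ring inside another is a hole). Area is computed by the shoelace
#' formula with even-odd signs.
#'
#' @param rings A single two-column matrix (x, y in km) or a list of them.
#' @param level Isopleth level tag in (0, 1).
#' @param component Optional label.
#' @return A `range_polygon`.
#' @export
range_polygon <- function(rings, level = 0.95, component = "polygon") {
  if (is.matrix(rings)) rings <- list(rings)
  stopifnot(length(rings) >= 1,
            all(vapply(rings, function(r) is.matrix(r) && ncol(r) == 2, TRUE)))
  area <- sum(vapply(rings, function(r)
    abs(pracma::polyarea(r[, 1], r[, 2])), 0))
  structure(list(level = level, area_ha = area * 100, rings = rings,
                 mask = NULL, x = NULL, y = NULL, cell_km2 = NULL,
                 density_threshold = NA_real_, component = component),
            class = "range_polygon")
}

#' @export
print.range_polygon <- function(x, ...) {
  cat(sprintf("range_polygon: %s, %.0f%% isopleth, %.1f ha, %d ring(s)\n",
              x$component, 100 * x$level, x$area_ha, length(x$rings)))
  invisible(x)
}

# even-odd membership of grid points in a set of rings, by the standard
# crossing-number test vectorised over points (edge loop only)
points_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (r in rings) {
    xs <- r[, 1]; ys <- r[, 2]
    n <- length(xs)
    if (xs[1] != xs[n] || ys[1] != ys[n]) { xs <- c(xs, xs[1]); ys <- c(ys, ys[1]) }
    bb <- px >= min(xs) & px <= max(xs) & py >= min(ys) & py <= max(ys)
    if (!any(bb)) next
    qx <- px[bb]; qy <- py[bb]
    hit <- rep(FALSE, length(qx))
    for (e in seq_len(length(xs) - 1)) {
      y1 <- ys[e]; y2 <- ys[e + 1]
      if (y1 == y2) next
      x1 <- xs[e]; x2 <- xs[e + 1]
      str <- (y1 > qy) != (y2 > qy)
      if (any(str))
        hit[str] <- xor(hit[str],
                        qx[str] < (x2 - x1) * (qy[str] - y1) / (y2 - y1) + x1)
    }
    full <- rep(FALSE, length(px))
    full[bb] <- hit
    inside <- xor(inside, full)
  }
  inside
}

#' Overlap between isopleth home ranges
#'
#' Ranges are rasterized onto a shared fine grid spanning their joint
#' bounding box and compared cell-wise. Modes: `"union"` (symmetric)
#' returns `100 * area(a intersect b) / area(a union b)`; `"of-first"`
#' returns `100 * area(a intersect b) / area(a)`.
#'
#' @param a,b `range_polygon` objects at the same isopleth level.
#' @param mode `"union"` (default) or `"of-first"`.
#' @param resolution Cells per axis of the shared grid (default 400).
#' @return Overlap percentage with attribute `mode`.
#' @export
range_overlap <- function(a, b, mode = c("union", "of-first"),
                          resolution = 400) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "range_polygon"), inherits(b, "range_polygon"))
  if (abs(a$level - b$level) > 1e-9)
    stop("isopleth levels differ; overlap undefined", call. = FALSE)
  masks <- rasterize_ranges(list(a, b), resolution)
  ia <- masks$masks[[1]]; ib <- masks$masks[[2]]
  inter <- sum(ia & ib)
  denom <- switch(mode, union = sum(ia | ib), `of-first` = sum(ia))
  out <- if (denom == 0) 0 else 100 * inter / denom
  attr(out, "mode") <- mode
  out
}

#' @rdname range_overlap
#' @param ranges List of `range_polygon`s (same level); the group overlap is
#'   `100 * area(intersection of all) / area(union of all)`.
#' @export
range_overlap_group <- function(ranges, resolution = 400) {
  stopifnot(length(ranges) >= 2)
  lv <- vapply(ranges, `[[`, 0, "level")
  if (diff(range(lv)) > 1e-9)
    stop("isopleth levels differ; overlap undefined", call. = FALSE)
  masks <- rasterize_ranges(ranges, resolution)$masks
  inter <- Reduce(`&`, masks)
  uni <- Reduce(`|`, masks)
  if (sum(uni) == 0) return(0)
  100 * sum(inter) / sum(uni)
}

#' Pairwise overlap matrix of several home ranges
#'
#' Rasterizes every range once onto one shared grid and compares masks
#' pairwise; much cheaper than calling [range_overlap()] per dyad.
#'
#' @param ranges Named list of `range_polygon`s at a common isopleth level.
#' @param mode `"union"` or `"of-first"` (the latter gives an asymmetric
#'   matrix: entry \[i, j\] is the percentage of range i covered by j).
#' @param resolution Cells per axis of the shared grid.
#' @return Square percentage matrix (diagonal 100).
#' @export
overlap_matrix <- function(ranges, mode = c("union", "of-first"),
                           resolution = 400) {
  mode <- match.arg(mode)
  stopifnot(length(ranges) >= 2)
  lv <- vapply(ranges, `[[`, 0, "level")
  if (diff(range(lv)) > 1e-9)
    stop("isopleth levels differ; overlap undefined", call. = FALSE)
  masks <- rasterize_ranges(ranges, resolution)$masks
  k <- length(masks)
  out <- matrix(100, k, k, dimnames = list(names(ranges), names(ranges)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    inter <- sum(masks[[i]] & masks[[j]])
    den <- if (mode == "union") sum(masks[[i]] | masks[[j]])
           else sum(masks[[i]])
    out[i, j] <- if (den == 0) 0 else 100 * inter / den
  }
  out
}

rasterize_ranges <- function(ranges, resolution) {
  allx <- unlist(lapply(ranges, function(r)
    if (length(r$rings)) unlist(lapply(r$rings, function(m) m[, 1]))
    else r$x))
  ally <- unlist(lapply(ranges, function(r)
    if (length(r$rings)) unlist(lapply(r$rings, function(m) m[, 2]))
    else r$y))
  xr <- range(allx); yr <- range(ally)
  eps <- 1e-9 + 1e-6 * max(diff(xr), diff(yr))
  gx <- seq(xr[1] - eps, xr[2] + eps, length.out = resolution)
  gy <- seq(yr[1] - eps, yr[2] + eps, length.out = resolution)
  px <- rep(gx, times = resolution)
  py <- rep(gy, each = resolution)
  masks <- lapply(ranges, function(r) {
    if (!is.null(r$mask)) {
      # UD-derived range: nearest-cell lookup in the stored grid mask
      ix <- round((px - r$x[1]) / diff(r$x[1:2])) + 1
      iy <- round((py - r$y[1]) / diff(r$y[1:2])) + 1
      ok <- ix >= 1 & ix <= length(r$x) & iy >= 1 & iy <= length(r$y)
      out <- rep(FALSE, length(px))
      out[ok] <- r$mask[cbind(ix[ok], iy[ok])]
      return(out)
    }
    if (length(r$rings) == 0)
      stop("range polygon has no rings to rasterize", call. = FALSE)
    points_in_rings(px, py, r$rings)
  })
  list(masks = masks, gx = gx, gy = gy)
}

#' Write a utilization distribution as an ESRI ASCII grid
#'
#' Coordinates are the local planar km frame of the UD (the projection
#' reference is recorded as comment-free header metadata cannot carry it;
#' see the run manifest for `lon0`/`lat0`).
#'
#' @param ud A `utilization_dist`.
#' @param path Output file.
#' @export
write_esri_ascii <- function(ud, path) {
  stopifnot(inherits(ud, "utilization_dist"))
  nx <- length(ud$x); ny <- length(ud$y)
  cs <- diff(ud$x[1:2])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", nx),
               sprintf("nrows %d", ny),
               sprintf("xllcorner %.8f", ud$x[1] - cs / 2),
               sprintf("yllcorner %.8f", ud$y[1] - cs / 2),
               sprintf("cellsize %.8f", cs),
               "NODATA_value -9999"), con)
  # rows from north (max y) to south
  for (iy in ny:1)
    writeLines(paste(sprintf("%.10g", ud$z[, iy]), collapse = " "), con)
  invisible(path)
}

#' Write range polygons as GeoJSON
#'
#' Rings are converted back to lon/lat when the projection reference is
#' known (UD-derived ranges); otherwise the km coordinates are written
#' as-is.
#'
#' @param rp A `range_polygon`.
#' @param path Output file.
#' @param lon0,lat0 Optional projection reference for back-conversion.
#' @export
write_geojson <- function(rp, path, lon0 = NULL, lat0 = NULL) {
  stopifnot(inherits(rp, "range_polygon"))
  to_coords <- function(m) {
    if (!is.null(lon0) && !is.null(lat0)) {
      lon <- lon0 + m[, 1] / (KM_PER_DEGREE * cos(lat0 * pi / 180))
      lat <- lat0 + m[, 2] / KM_PER_DEGREE
      m <- cbind(lon, lat)
    }
    if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  }
  feat <- list(
    type = "Feature",
    properties = list(component = rp$component, isopleth = rp$level,
                      area_ha = rp$area_ha),
    geometry = list(type = "MultiPolygon",
                    coordinates = lapply(rp$rings,
                                         function(r) list(to_coords(r))))
  )
  gj <- list(type = "FeatureCollection", features = list(feat))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
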