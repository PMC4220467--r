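#' Spatial spread of the social components per time segment
#'
#' At each retained slot the positions of the n components are reduced to
#' the per-dimension *population* variances of longitude and latitude
#' (degrees squared) and the spread modulus `A = sqrt(var_lon + var_lat)`
#' (degrees) -- the two-dimensional standard deviation of the n component
#' positions. Population variance (divide by n) is used so that components
#' at the vertices of a regular polygon of circumradius R give A = R
#' exactly, which is what identifies the communication-geometry radius with
#' a spread value.
#'
#' @param ts An aligned `trackset` (every component located at every
#'   retained slot).
#' @return A data frame of class `spread_series`: `slot`, `timestamp`,
#'   `var_lon`, `var_lat`, `a_deg`.
#' @export
spread_series <- function(ts) {
  stopifnot(inherits(ts, "trackset"))
  if (length(ts$components) < 2)
    stop("spread requires at least 2 components", call. = FALSE)
  pm <- position_matrices(ts, c("lon", "lat"))
  if (anyNA(pm$lon) || anyNA(pm$lat))
    stop("trackset has gaps; run align_tracks() first", call. = FALSE)
  # centre before squaring: coordinates are O(100) degrees while spreads are
  # O(0.01), so the naive E[x^2] - E[x]^2 form loses ~12 digits
  pop_var <- function(m) rowMeans((m - rowMeans(m))^2)
  v_lon <- pmax(pop_var(pm$lon), 0)
  v_lat <- pmax(pop_var(pm$lat), 0)
  out <- data.frame(slot = ts$slots,
                    timestamp = slot_times(ts$grid, ts$slots),
                    var_lon = v_lon, var_lat = v_lat,
                    a_deg = sqrt(v_lon + v_lat))
  class(out) <- c("spread_series", "data.frame")
  out
}

#' @rdname spread_series
#' @param segment A single slot index (must be retained in `ts`).
#' @return `spread_statistic`: a one-row data frame for the requested slot.
#' @export
spread_statistic <- function(ts, segment) {
  s <- spread_series(ts)
  row <- s[s$slot == segment, ]
  if (nrow(row) == 0) stop("segment ", segment, " not in trackset", call. = FALSE)
  row
}

#' Circumcircle radius of the communication isogon
#'
#' Threshold geometry: the n components sit at the vertices of an
#' equilateral polygon (isogon) whose side is the effective communication
#' distance d; the circumcircle radius `d / (2 sin(pi/n))` is the spread
#' value at which the formation is exactly at that communication distance.
#' Returned in degrees via [metres_to_degrees()].
#'
#' @param d Side length in metres (> 0).
#' @param n Number of polygon vertices (>= 3).
#' @return Radius in decimal degrees.
#' @examples
#' communication_radius(513.12, 5)  # ~0.003921 degrees (~436.5 m)
#' @export
communication_radius <- function(d, n) {
  if (!is.finite(n) || n < 3) stop("n must be >= 3", call. = FALSE)
  if (!is.finite(d) || d <= 0) stop("d must be > 0", call. = FALSE)
  metres_to_degrees(d / (2 * sin(pi / n)))
}

#' Calibrate a spread standardizer
#'
#' The spatial affinity coefficient (SAC) is the spread modulus A mapped
#' into \[0, 1\]. The default map is the quadratic min-max
#' `SAC = (A / A_max)^2` calibrated on the analysed series (zero at A = 0,
#' one at the series maximum); a linear min-max `A / A_max` is available.
#' The quadratic default is used because the two stage thresholds of the
#' reference analysis (0.1139 and 0.4571, for isogon sides d and 2d) sit in
#' ratio ~4, the square of the 2x geometric ratio. The calibration constant
#' and method are carried in the returned object and echoed in all outputs.
#'
#' @param a Numeric spread series (degrees) used for calibration, or a
#'   `spread_series`.
#' @param method `"quadratic"` (default) or `"linear"`.
#' @param a_max Optional explicit calibration maximum (degrees).
#' @return An object of class `sac_standardizer`.
#' @export
sac_standardizer <- function(a, method = c("quadratic", "linear"),
                             a_max = NULL) {
  method <- match.arg(method)
  if (inherits(a, "spread_series")) a <- a$a_deg
  if (length(a) == 0) stop("empty spread series", call. = FALSE)
  if (is.null(a_max)) a_max <- max(a)
  if (!is.finite(a_max) || a_max <= 0)
    stop("calibration requires max(A) > 0", call. = FALSE)
  structure(list(method = method, a_max = a_max),
            class = "sac_standardizer")
}

#' Standardize spread values to the SAC scale
#'
#' @param a Spread values (degrees) or a `spread_series`.
#' @param standardizer A [sac_standardizer()]; if omitted, one is calibrated
#'   on `a` itself with the default method.
#' @return Numeric SAC values in \[0, 1\] (values above the calibration
#'   maximum clip to 1).
#' @export
standardize_sac <- function(a, standardizer = NULL) {
  if (inherits(a, "spread_series")) a <- a$a_deg
  if (is.null(standardizer)) standardizer <- sac_standardizer(a)
  stopifnot(inherits(standardizer, "sac_standardizer"))
  x <- pmin(pmax(a / standardizer$a_max, 0), 1)
  if (standardizer$method == "quadratic") x^2 else x
}

#' Fusion and fission thresholds from the communication geometry
#'
#' Substitutes the isogon circumcircle radii for sides `d` and `2d` into the
#' calibrated standardizer: `SAC_fusion = standardize(radius(d, n))`,
#' `SAC_fission = standardize(radius(2d, n))`. Under the quadratic default
#' the two are in exact ratio 4 (before clipping). Explicit numeric
#' overrides may be supplied instead when the calibration of a reference
#' analysis is to be reused directly.
#'
#' @param standardizer A [sac_standardizer()] calibrated on the same series
#'   the SAC values will come from.
#' @param d Effective communication distance in metres (default 513.12).
#' @param n Number of social components (default 5).
#' @param persistence Minimum run length, in time segments, for a fusion or
#'   fission stage (default 3).
#' @param sac_fusion,sac_fission Optional explicit threshold overrides
#'   (must satisfy `sac_fusion < sac_fission`); bypass the geometry.
#' @return An object of class `threshold_set`.
#' @export
sac_thresholds <- function(standardizer, d = 513.12, n = 5, persistence = 3,
                           sac_fusion = NULL, sac_fission = NULL) {
  stopifnot(persistence >= 1)
  if (!is.null(sac_fusion) || !is.null(sac_fission)) {
    if (is.null(sac_fusion) || is.null(sac_fission))
      stop("override both thresholds or neither", call. = FALSE)
    if (!(sac_fusion < sac_fission))
      stop("sac_fusion must be < sac_fission", call. = FALSE)
    return(structure(list(d = d, n = n, radius_fusion_deg = NA_real_,
                          radius_fission_deg = NA_real_,
                          sac_fusion = sac_fusion, sac_fission = sac_fission,
                          persistence = persistence, standardizer = NULL,
                          overridden = TRUE),
                     class = "threshold_set"))
  }
  stopifnot(inherits(standardizer, "sac_standardizer"))
  r_fu <- communication_radius(d, n)
  r_fi <- communication_radius(2 * d, n)
  if (r_fi > standardizer$a_max)
    warning("threshold radius exceeds the calibration maximum; ",
            "SAC threshold clipped to 1", call. = FALSE)
  th <- structure(list(
    d = d, n = n, radius_fusion_deg = r_fu, radius_fission_deg = r_fi,
    sac_fusion = standardize_sac(r_fu, standardizer),
    sac_fission = standardize_sac(r_fi, standardizer),
    persistence = persistence, standardizer = standardizer,
    overridden = FALSE
  ), class = "threshold_set")
  if (!(th$sac_fusion < th$sac_fission))
    stop("degenerate thresholds: sac_fusion >= sac_fission after clipping",
         call. = FALSE)
  th
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("threshold_set: d=%.2f m, n=%d -> SAC_fusion=%.4f, SAC_fission=%.4f (persistence %d)%s\n",
              x$d, as.integer(x$n), x$sac_fusion, x$sac_fission,
              as.integer(x$persistence),
              if (isTRUE(x$overridden)) " [explicit override]" else ""))
  invisible(x)
}

#' Classify the timeline into fission/reform/fusion/separation stages
#'
#' A run of at least `persistence` consecutive segments with
#' `SAC <= SAC_fusion` is a fusion stage; a run of at least `persistence`
#' segments with `SAC >= SAC_fission` is a fission stage (both comparisons
#' inclusive). Shorter excursions do not interrupt a surrounding stage: two
#' fusion (fission) cores separated by fewer than `persistence` other
#' segments are merged across the excursion. Remaining segments are
#' labelled by their neighbouring events: after a fission and before the
#' next fusion they are reform; after a fusion and until the next fission
#' they are separation. Leading segments take the label implied by the next
#' event (reform before a fusion, separation before a fission); a series
#' with no threshold crossing at all is labelled separation with a warning.
#'
#' @param sac Numeric SAC series (or a data frame with a `sac` column).
#' @param thresholds A [sac_thresholds()] object.
#' @param slots Optional slot indices (defaults to `seq_along(sac)`);
#'   segmentation boundaries are reported in these units.
#' @return An object of class `stage_segmentation`: data frame `segments`
#'   (`stage`, `start_slot`, `end_slot`, `n_slots`), per-slot labels, and
#'   the threshold set used.
#' @export
classify_stages <- function(sac, thresholds, slots = NULL) {
  stopifnot(inherits(thresholds, "threshold_set"))
  if (is.data.frame(sac)) sac <- sac$sac
  if (length(sac) == 0) stop("empty SAC series", call. = FALSE)
  if (is.null(slots)) slots <- seq_along(sac)
  stopifnot(length(slots) == length(sac))
  p <- thresholds$persistence
  n <- length(sac)
  cls <- ifelse(sac <= thresholds$sac_fusion, "lo",
                ifelse(sac >= thresholds$sac_fission, "hi", "mid"))

  # cores: maximal runs of lo (hi) with length >= persistence
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  core <- data.frame(
    type = ifelse(r$values == "lo", "fusion", "fission"),
    start = starts, end = ends
  )[(r$values %in% c("lo", "hi")) & r$lengths >= p, , drop = FALSE]

  label <- rep(NA_character_, n)
  if (nrow(core) == 0) {
    warning("no fusion or fission event detected; ",
            "whole series labelled separation", call. = FALSE)
    label[] <- "separation"
  } else {
    core <- core[order(core$start), , drop = FALSE]
    # merge same-type cores across sub-persistence excursions
    merged <- core[1, , drop = FALSE]
    if (nrow(core) > 1) for (i in 2:nrow(core)) {
      last <- nrow(merged)
      gap <- core$start[i] - merged$end[last] - 1
      if (core$type[i] == merged$type[last] && gap < p) {
        merged$end[last] <- core$end[i]
      } else {
        merged <- rbind(merged, core[i, ])
      }
    }
    for (i in seq_len(nrow(merged)))
      label[merged$start[i]:merged$end[i]] <- merged$type[i]
    # gaps labelled by neighbouring events
    if (merged$start[1] > 1) {
      label[1:(merged$start[1] - 1)] <-
        if (merged$type[1] == "fusion") "reform" else "separation"
    }
    for (i in seq_len(nrow(merged))) {
      gs <- merged$end[i] + 1
      ge <- if (i < nrow(merged)) merged$start[i + 1] - 1 else n
      if (gs <= ge)
        label[gs:ge] <- if (merged$type[i] == "fission") "reform" else "separation"
    }
  }

  lr <- rle(label)
  le <- cumsum(lr$lengths)
  segs <- data.frame(
    stage = lr$values,
    start_slot = slots[le - lr$lengths + 1],
    end_slot = slots[le],
    n_slots = lr$lengths,
    stringsAsFactors = FALSE
  )
  structure(list(segments = segs, label = label, slots = slots,
                 thresholds = thresholds),
            class = "stage_segmentation")
}

#' @export
print.stage_segmentation <- function(x, ...) {
  fr <- stage_fractions(x)
  cat(sprintf("stage_segmentation: %d segments over %d slots\n",
              nrow(x$segments), length(x$label)))
  cat(sprintf("  %s: %.1f%%\n", names(fr), 100 * fr), sep = "")
  invisible(x)
}

#' Fraction of the study period spent in each stage
#'
#' @param seg A `stage_segmentation`.
#' @return Named numeric vector over the four stages (sums to 1).
#' @export
stage_fractions <- function(seg) {
  stopifnot(inherits(seg, "stage_segmentation"))
  tab <- table(factor(seg$label, levels = STAGE_LEVELS))
  stats::setNames(as.vector(tab) / length(seg$label), STAGE_LEVELS)
}

#' SAC series of a trackset
#'
#' Convenience wrapper: spread series, standardizer calibration and SAC in
#' one table.
#'
#' @param ts An aligned `trackset`.
#' @param standardizer Optional [sac_standardizer()]; calibrated on this
#'   series by default.
#' @return A data frame `slot`, `timestamp`, `a_deg`, `sac` with the
#'   standardizer attached as attribute `standardizer`.
#' @export
sac_series <- function(ts, standardizer = NULL) {
  sp <- spread_series(ts)
  if (is.null(standardizer)) standardizer <- sac_standardizer(sp)
  out <- data.frame(slot = sp$slot, timestamp = sp$timestamp,
                    a_deg = sp$a_deg,
                    sac = standardize_sac(sp$a_deg, standardizer))
  attr(out, "standardizer") <- standardizer
  out
}

#' Pairwise distances between social components
#'
#' Haversine distance for every dyad at every retained slot, with a per-dyad
#' summary (mean, s.e., min, max) available via [summarize_dyads()].
#'
#' @param ts An aligned `trackset`.
#' @return Data frame `slot`, `comp_i`, `comp_j`, `distance_km`.
#' @export
pairwise_component_distances <- function(ts) {
  stopifnot(inherits(ts, "trackset"))
  pm <- position_matrices(ts, c("lon", "lat"))
  comps <- ts$components
  dy <- utils::combn(seq_along(comps), 2)
  rows <- lapply(seq_len(ncol(dy)), function(k) {
    i <- dy[1, k]; j <- dy[2, k]
    data.frame(slot = ts$slots, comp_i = comps[i], comp_j = comps[j],
               distance_km = haversine_distance(pm$lon[, i], pm$lat[, i],
                                                pm$lon[, j], pm$lat[, j]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname pairwise_component_distances
#' @param dist Output of `pairwise_component_distances`.
#' @return `summarize_dyads`: one row per dyad with `mean_km`, `se_km`,
#'   `min_km`, `max_km`, `n`.
#' @export
summarize_dyads <- function(dist) {
  key <- interaction(dist$comp_i, dist$comp_j, drop = TRUE)
  out <- do.call(rbind, lapply(split(dist, key), function(g) {
    data.frame(comp_i = g$comp_i[1], comp_j = g$comp_j[1],
               mean_km = mean(g$distance_km),
               se_km = stats::sd(g$distance_km) / sqrt(nrow(g)),
               min_km = min(g$distance_km), max_km = max(g$distance_km),
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Standard comparisons of labelled distance (or SAC) samples
#'
#' Report plumbing around the standard routines: a one-way ANOVA when three
#' or more groups are supplied, and for exactly two groups an equal-variance
#' two-sample t-test plus a Wilcoxon rank-sum test (with its normal
#' approximation Z). Significance level is conventionally 0.05; all
#' statistics are reported with their degrees of freedom.
#'
#' @param values Numeric vector of observations.
#' @param group Group labels, same length as `values`.
#' @return Data frame with columns `method`, `statistic`, `df`, `p_value`.
#' @export
compare_distances <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(group) < 2)) stop("every group needs >= 2 values", call. = FALSE)
  if (nlevels(group) >= 3) {
    fit <- stats::aov(values ~ group)
    s <- summary(fit)[[1]]
    return(data.frame(
      method = "one-way ANOVA",
      statistic = s$`F value`[1],
      df = sprintf("%d, %d", s$Df[1], s$Df[2]),
      p_value = s$`Pr(>F)`[1], stringsAsFactors = FALSE))
  }
  a <- values[group == levels(group)[1]]
  b <- values[group == levels(group)[2]]
  tt <- stats::t.test(a, b, var.equal = TRUE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = FALSE))
  n1 <- length(a); n2 <- length(b)
  z <- (unname(wt$statistic) - n1 * n2 / 2) /
    sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  data.frame(
    method = c("two-sample t-test (equal variance)",
               "Wilcoxon rank-sum (normal approx.)"),
    statistic = c(unname(tt$statistic), z),
    df = c(sprintf("%d", as.integer(tt$parameter)),
           sprintf("%d", n1 + n2 - 2)),
    p_value = c(tt$p.value, wt$p.value),
    stringsAsFactors = FALSE
  )
}
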