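#' Configuration for the synthetic multi-component telemetry generator
#'
#' Describes a simulated study: several social components (each carrying one
#' virtual collar) moving through a scheduled alternation of fission, reform,
#' fusion and separation stages. Movement is a biased correlated random walk:
#' a shared formation centroid wanders as a correlated random walk and each
#' component relaxes toward a stage-dependent target offset from that
#' centroid. Component offsets lie on a common "formation shape" on the unit
#' circle (scaled per stage), so the realized spread statistic equals the
#' stage's target radius exactly in the noise-free limit, and the maximum
#' distance of any component from the centroid equals the same radius.
#'
#' The stage target radii are chosen so that fusion targets sit well below
#' the fusion threshold radius, fission targets well above the fission
#' threshold radius, and the intermediate target between the two; with the
#' default communication distance (513.12 m) and five components the
#' thresholds are 0.436 km and 0.873 km, and the defaults (0.25 / 0.62 /
#' 1.10 km) straddle them symmetrically so that smoothing-induced ramps
#' cross each threshold at the scheduled stage boundary without bias.
#'
#' @param n_components Number of social components (>= 2; default 5).
#' @param n_days Study length in days (default 291).
#' @param fixes_per_day Fixes per day on the diurnal grid (default 8:
#'   every 2 h from 05:00 to 19:00).
#' @param start_date First study day (default "2012-09-15").
#' @param stage_schedule Data frame with columns `stage` (one of `fission`,
#'   `reform`, `fusion`, `separation`) and `n_slots` (>= 1). Default: six
#'   fission-reform-fusion-separation cycles with stage totals in the
#'   proportions 20.9/24.7/18.4/36.0% of the grid (see
#'   [stage_schedule_from_fractions()]).
#' @param home_center Named vector `c(lon=, lat=)` of the home-range centre.
#' @param step_scale_km Step-length scale of the centroid's correlated
#'   random walk (km per 2-h slot).
#' @param heading_persistence AR(1) coefficient of the centroid velocity;
#'   controls within-day movement autocorrelation (exposed rather than
#'   fixed, since field estimates vary).
#' @param attraction_fusion_km Target spread radius (and maximum
#'   centroid-to-component distance) during fusion stages.
#' @param intermediate_km Target spread radius during reform and separation.
#' @param repulsion_fission_km Target spread radius during fission stages.
#' @param formation_relax Per-slot relaxation rate of component offsets
#'   toward their stage target (0-1].
#' @param formation_noise_km s.d. of per-slot Gaussian noise on component
#'   offsets (km, per coordinate).
#' @param herd_sizes Integer vector of component counts per planted herd
#'   (association ground truth); must sum to `n_components`. Default splits
#'   components 3 + 2 (or singletons for other n).
#' @param dop_meanlog,dop_sdlog Log-normal parameters of ordinary DOP values
#'   (capped below 8).
#' @param high_dop_rate Fraction of fixes assigned DOP >= 8 (default 0.02).
#' @param high_dop_range Range of DOP values for degraded fixes.
#' @param missing_rate Fraction of fixes dropped entirely (default 0.027).
#' @param jitter_sd_m Position jitter s.d. for ordinary fixes (metres).
#' @param high_dop_jitter_sd_m Position jitter s.d. for DOP >= 8 fixes.
#' @param seed RNG seed; identical configuration implies bit-identical
#'   output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_components = 5,
                         n_days = 291,
                         fixes_per_day = 8,
                         start_date = "2012-09-15",
                         stage_schedule = NULL,
                         home_center = c(lon = 108.0, lat = 33.8),
                         step_scale_km = 0.2,
                         heading_persistence = 0.7,
                         attraction_fusion_km = 0.25,
                         intermediate_km = 0.62,
                         repulsion_fission_km = 1.10,
                         formation_relax = 0.5,
                         formation_noise_km = 0.05,
                         herd_sizes = NULL,
                         dop_meanlog = log(2.5),
                         dop_sdlog = 0.35,
                         high_dop_rate = 0.02,
                         high_dop_range = c(8, 20),
                         missing_rate = 0.027,
                         jitter_sd_m = 10,
                         high_dop_jitter_sd_m = 50,
                         seed = 1L) {
  stopifnot(n_components >= 2, n_days >= 1, fixes_per_day >= 1,
            attraction_fusion_km > 0,
            attraction_fusion_km < repulsion_fission_km,
            intermediate_km > attraction_fusion_km,
            intermediate_km < repulsion_fission_km,
            missing_rate >= 0, missing_rate <= 1,
            high_dop_rate >= 0, high_dop_rate <= 1,
            formation_relax > 0, formation_relax <= 1,
            heading_persistence >= 0, heading_persistence < 1,
            step_scale_km >= 0, formation_noise_km >= 0)
  grid <- time_grid(start_date, n_days, fixes_per_day)
  if (is.null(stage_schedule))
    stage_schedule <- stage_schedule_from_fractions(n_slots = n_slots(grid))
  check_schedule(stage_schedule, n_slots(grid))
  if (is.null(herd_sizes)) {
    herd_sizes <- if (n_components >= 4)
      c(ceiling(n_components * 3 / 5),
        n_components - ceiling(n_components * 3 / 5))
    else rep(1L, n_components)
  }
  stopifnot(sum(herd_sizes) == n_components, all(herd_sizes >= 1))
  structure(list(
    n_components = as.integer(n_components), grid = grid,
    stage_schedule = stage_schedule, home_center = home_center,
    step_scale_km = step_scale_km, heading_persistence = heading_persistence,
    attraction_fusion_km = attraction_fusion_km,
    intermediate_km = intermediate_km,
    repulsion_fission_km = repulsion_fission_km,
    formation_relax = formation_relax,
    formation_noise_km = formation_noise_km,
    herd_sizes = as.integer(herd_sizes),
    dop_meanlog = dop_meanlog, dop_sdlog = dop_sdlog,
    high_dop_rate = high_dop_rate, high_dop_range = high_dop_range,
    missing_rate = missing_rate, jitter_sd_m = jitter_sd_m,
    high_dop_jitter_sd_m = high_dop_jitter_sd_m,
    seed = as.integer(seed)
  ), class = "synth_config")
}

STAGE_LEVELS <- c("fission", "reform", "fusion", "separation")

check_schedule <- function(sched, total) {
  stopifnot(is.data.frame(sched),
            all(c("stage", "n_slots") %in% names(sched)))
  if (!all(sched$stage %in% STAGE_LEVELS))
    stop("stage labels must be one of: ", paste(STAGE_LEVELS, collapse = ", "),
         call. = FALSE)
  if (any(sched$n_slots < 1)) stop("stage durations must be >= 1", call. = FALSE)
  if (sum(sched$n_slots) > total)
    stop(sprintf("stage schedule (%d slots) is longer than the grid (%d slots)",
                 sum(sched$n_slots), total), call. = FALSE)
  invisible(TRUE)
}

#' Build a cyclic stage schedule from target time fractions
#'
#' Splits the grid into `n_cycles` fission -> reform -> fusion -> separation
#' cycles whose per-stage totals match the requested time fractions (largest
#' remainder rounding). The default fractions are the stage composition
#' reported for the study system (20.9 / 24.7 / 18.4 / 36.0% of the study
#' period for fission / reform / fusion / separation).
#'
#' @param fractions Named fractions for the four stages; normalised to sum 1.
#' @param n_slots Total slots to schedule.
#' @param n_cycles Number of full cycles (default 6).
#' @return A data frame with columns `stage`, `n_slots`.
#' @export
stage_schedule_from_fractions <- function(
    fractions = c(fission = 0.209, reform = 0.247,
                  fusion = 0.184, separation = 0.360),
    n_slots, n_cycles = 6) {
  stopifnot(all(STAGE_LEVELS %in% names(fractions)), n_cycles >= 1,
            all(fractions > 0))
  fractions <- fractions[STAGE_LEVELS] / sum(fractions[STAGE_LEVELS])
  # largest-remainder apportionment of the per-stage totals, then each
  # stage's total spread across cycles (so realized stage fractions match
  # the targets to within one slot)
  raw <- fractions * n_slots
  tot <- floor(raw)
  rem <- n_slots - sum(tot)
  if (rem > 0) {
    up <- order(raw - tot, decreasing = TRUE)[seq_len(rem)]
    tot[up] <- tot[up] + 1
  }
  per_cycle <- vapply(STAGE_LEVELS, function(st) {
    b <- rep(tot[[st]] %/% n_cycles, n_cycles)
    extra <- tot[[st]] - sum(b)
    if (extra > 0) b[seq_len(extra)] <- b[seq_len(extra)] + 1
    b
  }, numeric(n_cycles))
  out <- data.frame(
    stage = rep(STAGE_LEVELS, n_cycles),
    n_slots = as.integer(t(per_cycle)),
    stringsAsFactors = FALSE
  )
  out[out$n_slots > 0, , drop = FALSE]
}

# Formation shapes with unit spread modulus (so target radius == realized
# spread statistic, exactly, in the noise-free limit).
#
# Two shapes are planted:
#   * u_cluster -- herd clusters: each herd's members on a small ring around
#     its herd centre, centres balanced so the configuration mean is zero.
#     Used during fission, reform and separation, when herds travel as
#     distinct sub-formations.
#   * u_fusion -- a regular n-gon (spread modulus equals the circumradius,
#     which is also the maximum offset), members interleaved in the cyclic
#     order of the cluster shape. Used during fusion: the merged troop
#     intermingles and herd identity carries no spatial signal.
formation_shape <- function(n, herd_sizes) {
  H <- length(herd_sizes)
  herd <- rep(seq_len(H), herd_sizes)
  normalise <- function(u) {
    u <- sweep(u, 2, colMeans(u))
    u / sqrt(mean(u[, 1]^2) + mean(u[, 2]^2))
  }
  ring <- function(m, w, centre_ang = pi / 2) {
    if (m == 1) return(matrix(0, 1, 2))
    a <- centre_ang + 2 * pi * (seq_len(m) - 1) / m
    w * cbind(cos(a), sin(a))
  }
  if (H == 1) {
    u_cluster <- normalise(ring(n, 1))
  } else {
    # herd centres c_h with sum(m_h * c_h) = 0; overall centre spacing 1.4
    # and within-herd ring radius 0.35 keep cross-herd gaps well above
    # within-herd spacing
    theta <- 2 * pi * (seq_len(H) - 1) / H + pi / 2
    r <- 1.4 / (2 * mean(1 / herd_sizes))
    centres <- cbind(cos(theta), sin(theta)) * r / herd_sizes
    u <- do.call(rbind, lapply(seq_len(H), function(h)
      sweep(ring(herd_sizes[h], 0.35, theta[h] + pi / 3), 2,
            centres[h, ], "+")))
    u_cluster <- normalise(u)
  }
  # fusion polygon: vertices assigned in the cyclic order of the cluster
  # shape, so the transition is a radial contraction plus small swirl
  ord <- order(atan2(u_cluster[, 2], u_cluster[, 1]))
  ang <- 2 * pi * (seq_len(n) - 1) / n + pi / 2
  u_fusion <- matrix(0, n, 2)
  u_fusion[ord, ] <- cbind(cos(ang), sin(ang))
  u_fusion <- normalise(u_fusion)
  list(u_cluster = u_cluster, u_fusion = u_fusion, herd = herd)
}

stage_per_slot <- function(config) {
  sched <- config$stage_schedule
  lab <- rep(sched$stage, sched$n_slots)
  total <- n_slots(config$grid)
  if (length(lab) < total)  # schedule shorter than grid: extend final stage
    lab <- c(lab, rep(lab[length(lab)], total - length(lab)))
  lab
}

#' Generate a clean synthetic trackset with ground truth
#'
#' Simulates the configured study. Returns the noise-free, fully-observed
#' trackset (one fix per component per grid slot) together with the ground
#' truth: the scheduled stage of every slot, the planted herd membership,
#' and the per-dyad true association indicator (same-herd dyads).
#'
#' @param config A [synth_config()].
#' @return A list with elements `trackset` and `truth` (list with
#'   `stage_per_slot`, `herd`, `dyad_truth`).
#' @export
generate_trackset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  grid <- config$grid
  total <- n_slots(grid)
  n <- config$n_components
  lab <- stage_per_slot(config)
  radius <- c(fission = config$repulsion_fission_km,
              reform = config$intermediate_km,
              fusion = config$attraction_fusion_km,
              separation = config$intermediate_km)[lab]

  shape <- formation_shape(n, config$herd_sizes)
  rot <- stats::runif(1, 0, 2 * pi)
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  u_cluster <- shape$u_cluster %*% R  # n x 2 offsets, spread modulus 1
  u_fusion <- shape$u_fusion %*% R

  rho <- config$heading_persistence
  kappa <- config$formation_relax
  # centroid correlated random walk with weak home pull
  vel <- matrix(0, total, 2)
  cen <- matrix(0, total, 2)
  eta <- matrix(stats::rnorm(2 * total, 0, config$step_scale_km), total, 2)
  for (t in 2:total) {
    vel[t, ] <- rho * vel[t - 1, ] + sqrt(1 - rho^2) * eta[t, ]
    cen[t, ] <- cen[t - 1, ] * 0.98 + vel[t, ]
  }
  # component offsets relax toward the stage target
  pos <- array(0, c(total, n, 2))
  shape_of <- function(t) if (lab[t] == "fusion") u_fusion else u_cluster
  off <- radius[1] * shape_of(1)
  noise_sd <- config$formation_noise_km
  for (t in seq_len(total)) {
    target <- radius[t] * shape_of(t)
    if (t > 1) {
      eps <- matrix(stats::rnorm(2 * n, 0, noise_sd), n, 2)
      off <- off + kappa * (target - off) + eps
    }
    pos[t, , ] <- sweep(off, 2, cen[t, ], "+")
  }
  # elevation: slow AR(1) around 1500 m per component
  elev <- matrix(0, total, n)
  ez <- matrix(stats::rnorm(total * n, 0, 20), total, n)
  elev[1, ] <- 1500 + ez[1, ]
  for (t in 2:total) elev[t, ] <- 1500 + 0.9 * (elev[t - 1, ] - 1500) + ez[t, ]

  comp_ids <- sprintf("C%02d", seq_len(n))
  # constant-t conversion: spread control in degree space stays exact
  fixes <- data.frame(
    component_id = rep(comp_ids, each = total),
    slot = rep(seq_len(total), n),
    lon = config$home_center[["lon"]] + as.vector(pos[, , 1]) / KM_PER_DEGREE,
    lat = config$home_center[["lat"]] + as.vector(pos[, , 2]) / KM_PER_DEGREE,
    elev_m = as.vector(elev),
    dop = NA_real_,
    stringsAsFactors = FALSE
  )
  ts <- trackset(fixes, grid, components = comp_ids)

  herd <- stats::setNames(shape$herd, comp_ids)
  dy <- utils::combn(comp_ids, 2)
  dyad_truth <- data.frame(
    comp_i = dy[1, ], comp_j = dy[2, ],
    same_herd = herd[dy[1, ]] == herd[dy[2, ]],
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(trackset = ts,
       truth = list(stage_per_slot = lab, herd = herd,
                    dyad_truth = dyad_truth))
}

#' Degrade a clean trackset into collar-like raw fixes
#'
#' Emulates collar imperfections: every fix receives a DOP value (a
#' configured fraction drawn at or above 8), positions are jittered with
#' DOP-dependent noise, and a configured fraction of fixes is dropped
#' entirely. Operates on the recorded rows only; returns a raw fix table as
#' written by collars (no grid completion).
#'
#' @param ts A clean `trackset` from [generate_trackset()].
#' @param config The same [synth_config()] (supplies rates and the seed; the
#'   degradation stream is a fixed offset of the generator seed so that
#'   generation and degradation are independently reproducible).
#' @return A data frame of raw fixes (`component_id`, `timestamp`, `lon`,
#'   `lat`, `elev_m`, `dop`).
#' @export
degrade <- function(ts, config) {
  stopifnot(inherits(ts, "trackset"), inherits(config, "synth_config"))
  set.seed(config$seed + 7919L)
  f <- ts$fixes[ts$fixes$slot %in% ts$slots & !is.na(ts$fixes$lon), ]
  m <- nrow(f)
  dop <- pmin(stats::rlnorm(m, config$dop_meanlog, config$dop_sdlog), 7.9)
  n_high <- round(config$high_dop_rate * m)
  hi <- if (n_high > 0) sample.int(m, n_high) else integer(0)
  dop[hi] <- stats::runif(length(hi), config$high_dop_range[1],
                          config$high_dop_range[2])
  sd_m <- rep(config$jitter_sd_m, m)
  sd_m[hi] <- config$high_dop_jitter_sd_m
  if (any(sd_m > 0)) {
    jit <- metres_to_degrees(sd_m)
    f$lon <- f$lon + stats::rnorm(m, 0, 1) * jit
    f$lat <- f$lat + stats::rnorm(m, 0, 1) * jit
  }
  f$dop <- dop
  n_miss <- round(config$missing_rate * m)
  if (n_miss > 0) f <- f[-sample.int(m, n_miss), ]
  rownames(f) <- NULL
  f[, c("component_id", "timestamp", "lon", "lat", "elev_m", "dop")]
}
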