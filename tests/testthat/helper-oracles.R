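# Independent reference implementations used as oracles. These are written
# in a deliberately different style from the package internals (explicit
# per-slot / per-window loops instead of run-length or vectorised logic).

# --- stage classifier reference: per-slot decision from sliding windows ----
ref_classify <- function(cls, p) {
  n <- length(cls)
  core <- rep(NA_character_, n)
  if (n >= p) for (s in 1:(n - p + 1)) {
    w <- s:(s + p - 1)
    if (all(cls[w] == "lo")) core[w] <- "fusion"
    if (all(cls[w] == "hi")) core[w] <- "fission"
  }
  if (all(is.na(core))) return(rep("separation", n))
  lab <- core
  core_pos <- which(!is.na(core))
  for (i in which(is.na(core))) {
    prev <- core_pos[core_pos < i]
    nxt <- core_pos[core_pos > i]
    pt <- if (length(prev)) core[max(prev)] else NA_character_
    nt <- if (length(nxt)) core[min(nxt)] else NA_character_
    gap_lo <- if (length(prev)) max(prev) else 0L
    gap_hi <- if (length(nxt)) min(nxt) else n + 1L
    gap_len <- gap_hi - gap_lo - 1L
    lab[i] <-
      if (!is.na(pt) && !is.na(nt) && pt == nt && gap_len < p) pt
      else if (!is.na(pt)) (if (pt == "fission") "reform" else "separation")
      else (if (nt == "fusion") "reform" else "separation")
  }
  lab
}

# thresholds mapping lo/mid/hi codes onto SAC values
code_to_sac <- function(cls, fu = 0.1139, fi = 0.4571) {
  c(lo = fu - 0.05, mid = (fu + fi) / 2, hi = fi + 0.05)[cls]
}

# --- HWI tally reference: slot loop with explicit branching ---------------
ref_hwi_counts <- function(nnmat, i, j) {
  X <- Yi <- Yj <- Yij <- 0L
  for (t in seq_len(nrow(nnmat))) {
    ni <- nnmat[t, i]; nj <- nnmat[t, j]
    if (is.na(ni) || is.na(nj)) next
    if (ni == j && nj == i) X <- X + 1L
    else if (nj == i) Yi <- Yi + 1L
    else if (ni == j) Yj <- Yj + 1L
    else Yij <- Yij + 1L
  }
  denom <- X + Yij + (Yi + Yj) / 2
  list(X = X, Y_i = Yi, Y_j = Yj, Y_ij = Yij,
       hwi = if (X + Yi + Yj + Yij == 0) NA_real_
             else if (X == 0) 0 else X / denom)
}

# wrap a neighbour-index matrix as an nn_table
nn_table_from_matrix <- function(m, comps = colnames(m),
                                 slots = seq_len(nrow(m))) {
  if (is.null(comps)) comps <- sprintf("C%02d", seq_len(ncol(m)))
  out <- data.frame(
    slot = rep(slots, ncol(m)),
    component_id = rep(comps, each = nrow(m)),
    neighbour_id = comps[as.vector(m)],
    distance_km = 1, tie = FALSE, stringsAsFactors = FALSE
  )
  class(out) <- c("nn_table", "data.frame")
  attr(out, "components") <- comps
  out
}

# --- set partitions and community-sum modularity --------------------------
all_partitions <- function(n) {
  # restricted growth strings
  out <- list()
  rec <- function(a, mx) {
    k <- length(a)
    if (k == n) { out[[length(out) + 1]] <<- a; return(invisible()) }
    for (v in seq_len(mx + 1)) rec(c(a, v), max(mx, v))
  }
  rec(1L, 1L)
  out
}

# modularity via the community-sum formula (independent of the package's
# ordered-pair double sum)
ref_modularity <- function(w, mem) {
  w <- as.matrix(w); diag(w) <- 0; w[is.na(w)] <- 0
  m2 <- sum(w)
  q <- 0
  for (cc in unique(mem)) {
    idx <- mem == cc
    s_in <- sum(w[idx, idx])          # doubled intra weight
    d_c <- sum(w[idx, ])
    q <- q + s_in / m2 - (d_c / m2)^2
  }
  q
}

# assoc_matrix from a raw HWI matrix
assoc_from_hwi <- function(w) {
  comps <- rownames(w)
  if (is.null(comps)) {
    comps <- sprintf("C%02d", seq_len(nrow(w)))
    dimnames(w) <- list(comps, comps)
  }
  diag(w) <- NA
  structure(list(hwi = w, counts = NULL, components = comps,
                 n_slots = NA_integer_), class = "assoc_matrix")
}

# --- geometry helpers ------------------------------------------------------
# trackset with components fixed at regular n-gon vertices (circumradius in
# degrees) around a centre, constant over all slots
polygon_trackset <- function(n, radius_deg, n_slots = 8,
                             centre = c(lon = 108, lat = 34),
                             phase = 0) {
  ang <- 2 * pi * (seq_len(n) - 1) / n + phase
  comps <- sprintf("C%02d", seq_len(n))
  grid <- time_grid("2013-01-01", ceiling(n_slots / 8))
  fixes <- expand.grid(slot = seq_len(n_slots), id = seq_len(n))
  df <- data.frame(
    component_id = comps[fixes$id],
    slot = fixes$slot,
    lon = centre[["lon"]] + radius_deg * cos(ang[fixes$id]),
    lat = centre[["lat"]] + radius_deg * sin(ang[fixes$id]),
    stringsAsFactors = FALSE
  )
  align_tracks(trackset(df, grid, components = comps))
}

# trackset from explicit lon/lat matrices (slots x components)
matrix_trackset <- function(lon, lat, elev = NULL, dop = NULL,
                            start_date = "2013-01-01", align = TRUE) {
  ns <- nrow(lon); n <- ncol(lon)
  comps <- sprintf("C%02d", seq_len(n))
  grid <- time_grid(start_date, ceiling(ns / 8))
  df <- data.frame(
    component_id = rep(comps, each = ns),
    slot = rep(seq_len(ns), n),
    lon = as.vector(lon), lat = as.vector(lat),
    elev_m = if (is.null(elev)) NA_real_ else as.vector(elev),
    dop = if (is.null(dop)) NA_real_ else as.vector(dop),
    stringsAsFactors = FALSE
  )
  df <- df[!is.na(df$lon), ]
  ts <- trackset(df, grid, components = comps)
  if (align) align_tracks(ts) else ts
}

study_truth_fractions <- c(fission = 0.209, reform = 0.247,
                           fusion = 0.184, separation = 0.360)

KM_PER_DEGREE_TEST <- 6378.137 * 2 * pi / 360
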