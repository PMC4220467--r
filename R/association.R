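#' Nearest-neighbour sampling of the social components
#'
#' For every retained slot and every component, the other component at the
#' minimum haversine distance. Ties are broken deterministically toward the
#' smallest component identifier (component order of the trackset) and
#' flagged.
#'
#' @param ts An aligned `trackset` with >= 2 components.
#' @return A data frame of class `nn_table`: `slot`, `component_id`,
#'   `neighbour_id`, `distance_km`, `tie`; component order is carried in
#'   attribute `components`.
#' @export
nearest_neighbours <- function(ts) {
  stopifnot(inherits(ts, "trackset"))
  comps <- ts$components
  n <- length(comps)
  pm <- position_matrices(ts, c("lon", "lat"))
  ns <- length(ts$slots)
  dist <- array(Inf, c(ns, n, n))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- haversine_distance(pm$lon[, i], pm$lat[, i], pm$lon[, j], pm$lat[, j])
    dist[, i, j] <- d
    dist[, j, i] <- d
  }
  rows <- lapply(seq_len(n), function(i) {
    di <- dist[, i, , drop = TRUE]
    if (is.null(dim(di))) di <- matrix(di, nrow = ns)
    dmin <- do.call(pmin, as.data.frame(di))
    # relative tolerance: collar coordinates carry ~12 significant digits
    near <- di <= dmin * (1 + 1e-9) + 1e-12
    # tie-break: first (smallest-id) component within tolerance of the min
    best <- max.col(near, ties.method = "first")
    tie <- rowSums(near) > 1
    data.frame(slot = ts$slots, component_id = comps[i],
               neighbour_id = comps[best], distance_km = dmin, tie = tie,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$slot, match(out$component_id, comps)), ]
  rownames(out) <- NULL
  class(out) <- c("nn_table", "data.frame")
  attr(out, "components") <- comps
  out
}

# nn table -> slot x component matrix of neighbour indices
nn_index_matrix <- function(nn) {
  comps <- attr(nn, "components")
  if (is.null(comps)) comps <- sort(unique(nn$component_id))
  slots <- sort(unique(nn$slot))
  m <- matrix(NA_integer_, length(slots), length(comps),
              dimnames = list(NULL, comps))
  m[cbind(match(nn$slot, slots), match(nn$component_id, comps))] <-
    match(nn$neighbour_id, comps)
  list(m = m, comps = comps, slots = slots)
}

#' Half-weight association index matrix
#'
#' Tallies, for every dyad (i, j) over all co-observed slots: `X`, slots
#' where i and j are each other's nearest neighbour; `Y_i` (`Y_j`), slots
#' where i (j) is the nearest neighbour of j (i) but not conversely; and
#' `Y_ij`, slots where each has some other nearest neighbour. The
#' half-weight index is `HWI = X / (X + Y_ij + (Y_i + Y_j) / 2)`, zero when
#' `X = 0` and defined as missing for dyads never co-observed.
#'
#' @param nn An `nn_table` from [nearest_neighbours()].
#' @return An object of class `assoc_matrix`: symmetric `hwi` matrix
#'   (diagonal `NA`), per-dyad count table `counts`, and the number of
#'   co-observed slots.
#' @export
hwi_matrix <- function(nn) {
  if (nrow(nn) == 0) stop("empty nearest-neighbour table", call. = FALSE)
  im <- nn_index_matrix(nn)
  comps <- im$comps
  n <- length(comps)
  hwi <- matrix(NA_real_, n, n, dimnames = list(comps, comps))
  counts <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- !is.na(im$m[, i]) & !is.na(im$m[, j])
    ni <- im$m[both, i]; nj <- im$m[both, j]
    X <- sum(ni == j & nj == i)
    Yi <- sum(nj == i & ni != j)   # i is j's NN, not conversely
    Yj <- sum(ni == j & nj != i)
    Yij <- sum(ni != j & nj != i)
    denom <- X + Yij + (Yi + Yj) / 2
    h <- if (sum(both) == 0) NA_real_ else if (X == 0) 0 else X / denom
    hwi[i, j] <- h; hwi[j, i] <- h
    counts[[length(counts) + 1]] <- data.frame(
      comp_i = comps[i], comp_j = comps[j], X = X, Y_i = Yi, Y_j = Yj,
      Y_ij = Yij, n_coobserved = sum(both), hwi = h,
      stringsAsFactors = FALSE)
  }
  structure(list(hwi = hwi, counts = do.call(rbind, counts),
                 components = comps, n_slots = nrow(im$m)),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("assoc_matrix: %d components, %d slots\n",
              length(x$components), x$n_slots))
  print(round(x$hwi, 3))
  invisible(x)
}

#' Weighted Newman modularity of a partition of an association matrix
#'
#' `Q = sum_ij (w_ij - k_i k_j / 2m) delta(c_i, c_j) / 2m` over ordered
#' pairs, with HWI edge weights, zero diagonal, `k_i` the node strength and
#' `2m` the total weight. Used to score dendrogram cuts.
#'
#' @param w Symmetric nonnegative weight matrix (diagonal ignored).
#' @param membership Integer/character community labels per node.
#' @return Scalar modularity.
#' @export
weighted_modularity <- function(w, membership) {
  w <- as.matrix(w)
  diag(w) <- 0
  w[is.na(w)] <- 0
  m2 <- sum(w)
  if (m2 <= 0) return(0)
  k <- rowSums(w)
  same <- outer(membership, membership, "==")
  sum((w - outer(k, k) / m2)[same]) / m2
}

#' Association dendrogram with modularity-based herd cutoff
#'
#' Average-linkage agglomeration on the dissimilarity `1 - HWI`. Every cut
#' of the tree (k = 1..n clusters) is scored with weighted Newman modularity
#' of the implied partition (HWI edge weights); the recommended cutoff is
#' the cut with maximum modularity, which defines the herd-level grouping.
#' Knot counts -- the cumulative number of bifurcations below each
#' association distance -- are reported alongside.
#'
#' @param assoc An `assoc_matrix` from [hwi_matrix()].
#' @param linkage Agglomeration method for [stats::hclust()]
#'   (default `"average"`).
#' @return An object of class `herd_dendrogram`: the `hclust` tree (heights
#'   on the 1-HWI scale), a `modularity` table (k, modularity, cut height),
#'   the recommended `cutoff_k`, `cutoff_height`, `membership` at the
#'   cutoff, and `knots` (height, cumulative bifurcations).
#' @export
cluster_dendrogram <- function(assoc, linkage = "average") {
  stopifnot(inherits(assoc, "assoc_matrix"))
  n <- length(assoc$components)
  h <- assoc$hwi
  if (anyNA(h[upper.tri(h)]))
    stop("HWI undefined for some dyad; cannot cluster", call. = FALSE)
  d <- stats::as.dist(1 - h)
  hc <- stats::hclust(d, method = linkage)
  if (n < 3) {
    warning("fewer than 3 components: dendrogram trivial, modularity skipped",
            call. = FALSE)
    return(structure(list(hclust = hc, modularity = NULL,
                          cutoff_k = n, cutoff_height = NA_real_,
                          membership = stats::setNames(seq_len(n),
                                                       assoc$components),
                          knots = NULL, hwi = h),
                     class = "herd_dendrogram"))
  }
  hts <- sort(hc$height)
  mod <- data.frame(k = seq_len(n), modularity = NA_real_,
                    height = NA_real_)
  for (k in seq_len(n)) {
    mem <- stats::cutree(hc, k = k)
    mod$modularity[k] <- weighted_modularity(h, mem)
    # height at which cutting yields k clusters: between merge n-k and n-k+1
    upper <- if (k == 1) Inf else hts[n - k + 1]
    lower <- if (k == n) 0 else hts[n - k]
    mod$height[k] <- if (is.finite(upper)) (lower + upper) / 2 else lower
  }
  k_best <- mod$k[which.max(mod$modularity)]
  knots <- data.frame(height = hts,
                      bifurcations = seq_along(hts))
  structure(list(
    hclust = hc, modularity = mod, cutoff_k = k_best,
    cutoff_height = mod$height[mod$k == k_best],
    membership = stats::cutree(hc, k = k_best),
    knots = knots, hwi = h
  ), class = "herd_dendrogram")
}

#' @export
print.herd_dendrogram <- function(x, ...) {
  cat(sprintf("herd_dendrogram: %d components", length(x$membership)))
  if (!is.null(x$modularity))
    cat(sprintf(", max modularity %.4f at k=%d (cut height %.3f)",
                max(x$modularity$modularity), x$cutoff_k, x$cutoff_height))
  cat("\nmembership:", paste(names(x$membership), x$membership,
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.herd_dendrogram <- function(x, ...) {
  graphics::plot(x$hclust, ylab = "association distance (1 - HWI)",
                 main = "Component associations", sub = "", xlab = "", ...)
  if (is.finite(x$cutoff_height))
    graphics::abline(h = x$cutoff_height, lty = 2, col = "blue")
  invisible(x)
}

#' Export a herd dendrogram as Newick
#'
#' Branch lengths are on the 1-HWI association-distance scale.
#'
#' @param dend A `herd_dendrogram`.
#' @param path Output file.
#' @export
write_dendrogram_newick <- function(dend, path) {
  stopifnot(inherits(dend, "herd_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Lagged and null association rates
#'
#' Association is mutual nearest-neighbourhood. The lagged association rate
#' at lag tau (in grid slots) is the probability that a dyad associated at
#' slot t is also associated at slot t + tau, estimated by the ratio
#' `sum a(t) a(t+tau) / sum a(t) o(t+tau)` pooled over dyads and slot pairs
#' (o = both members observed). The null association rate -- the expected
#' lagged rate with no preferred companionship -- is the pooled mean
#' association probability.
#'
#' @param nn An `nn_table`.
#' @param lags Integer lags in slots (default `0:100`); lags at or beyond
#'   the series length are dropped with a warning.
#' @return Data frame of class `lagged_rates`: `tau`, `g`, `n_pairs`, with
#'   attribute `null_rate`.
#' @export
lagged_association_rate <- function(nn, lags = 0:100) {
  im <- nn_index_matrix(nn)
  ns <- nrow(im$m)
  if (ns < 2) stop("need >= 2 slots", call. = FALSE)
  n <- ncol(im$m)
  dy <- utils::combn(seq_len(n), 2)
  # association indicator per slot per dyad (NA when either unobserved)
  a <- sapply(seq_len(ncol(dy)), function(k) {
    i <- dy[1, k]; j <- dy[2, k]
    ifelse(is.na(im$m[, i]) | is.na(im$m[, j]), NA,
           (im$m[, i] == j) & (im$m[, j] == i))
  })
  a <- matrix(as.numeric(a), nrow = ns)
  lags <- sort(unique(as.integer(lags)))
  drop <- lags >= ns | lags < 0
  if (any(drop)) {
    warning(sum(drop), " lag(s) outside the series dropped", call. = FALSE)
    lags <- lags[!drop]
  }
  # slot positions must be lag-comparable in true slot units
  slot_index <- im$slots
  pos_of_slot <- match(seq_len(max(slot_index)), slot_index)
  g <- numeric(length(lags)); npairs <- integer(length(lags))
  for (li in seq_along(lags)) {
    tau <- lags[li]
    t1 <- slot_index[slot_index + tau <= max(slot_index)]
    p1 <- pos_of_slot[t1]
    p2 <- pos_of_slot[t1 + tau]
    ok <- !is.na(p1) & !is.na(p2)
    p1 <- p1[ok]; p2 <- p2[ok]
    a1 <- a[p1, , drop = FALSE]
    a2 <- a[p2, , drop = FALSE]
    obs <- !is.na(a1) & !is.na(a2)
    num <- sum(a1 * a2, na.rm = TRUE)
    den <- sum(a1 * obs, na.rm = TRUE)
    g[li] <- if (den > 0) num / den else NA_real_
    npairs[li] <- den
  }
  out <- data.frame(tau = lags, g = g, n_pairs = npairs)
  class(out) <- c("lagged_rates", "data.frame")
  attr(out, "null_rate") <- mean(a, na.rm = TRUE)
  out
}

#' Fit companionship decay models to a lagged rate curve
#'
#' Least-squares fits of two standard forms: constant companionship
#' `g(tau) = a`, and decaying acquaintance `g(tau) = a exp(-b tau) + c`.
#' Models are compared by residual sum of squares and the small-sample
#' information criterion AICc; non-convergence of the exponential fit is
#' reported while keeping the constant model.
#'
#' @param rates A `lagged_rates` table (>= 4 finite lag bins).
#' @return List of class `decay_fits`: per-model parameter lists, `rss`,
#'   `aicc`, and `preferred` (model name with the lower AICc).
#' @export
fit_decay_models <- function(rates) {
  df <- rates[is.finite(rates$g), c("tau", "g")]
  if (nrow(df) < 4) stop("need >= 4 lag bins", call. = FALSE)
  nb <- nrow(df)
  aicc <- function(rss, k) {
    # k model parameters + 1 variance
    kk <- k + 1
    nb * log(rss / nb) + 2 * kk + if (nb - kk - 1 > 0)
      2 * kk * (kk + 1) / (nb - kk - 1) else Inf
  }
  a_hat <- mean(df$g)
  rss_const <- sum((df$g - a_hat)^2)
  models <- list(constant = list(coef = c(a = a_hat), rss = rss_const,
                                 aicc = aicc(rss_const, 1),
                                 converged = TRUE))
  c0 <- min(df$g)
  a0 <- max(df$g) - c0
  if (a0 <= 0) a0 <- 0.1
  pos <- df$g - c0 + 1e-6
  b0 <- tryCatch({
    sl <- stats::coef(stats::lm(log(pos) ~ df$tau))[2]
    max(1e-4, -unname(sl))
  }, error = function(e) 0.05)
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ a * exp(-b * tau) + c, data = df,
                      start = list(a = a0, b = b0, c = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    models$exponential <- list(coef = NULL, rss = NA_real_, aicc = Inf,
                               converged = FALSE,
                               message = conditionMessage(fit))
  } else {
    rss_exp <- sum(stats::resid(fit)^2)
    models$exponential <- list(coef = stats::coef(fit), rss = rss_exp,
                               aicc = aicc(rss_exp, 3), converged = TRUE)
  }
  pref <- names(models)[which.min(vapply(models, `[[`, 0, "aicc"))]
  structure(list(models = models, preferred = pref, n_bins = nb),
            class = "decay_fits")
}

#' @export
print.decay_fits <- function(x, ...) {
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("%-12s rss=%.5g aicc=%.2f %s\n", nm, m$rss, m$aicc,
                if (m$converged)
                  paste(names(m$coef), signif(m$coef, 4),
                        sep = "=", collapse = " ")
                else "(did not converge)"))
  }
  cat("preferred:", x$preferred, "\n")
  invisible(x)
}

#' Principal coordinates embedding of the association matrix
#'
#' Classical metric scaling of the dissimilarity `d_ij = 1 / sqrt(HWI_ij)`
#' (zero diagonal): components with stronger associations are embedded
#' closer together. Dyads with HWI = 0 have no finite dissimilarity and are
#' set to a ceiling (default 10x the largest finite d) with a warning;
#' negative eigenvalues are truncated to zero and reported.
#'
#' @param assoc An `assoc_matrix`.
#' @param dims Number of embedding dimensions (default 2).
#' @param zero_ceiling Multiplier for the HWI = 0 ceiling (default 10).
#' @return List of class `assoc_pcoa`: `points` (components x dims),
#'   `eigenvalues`, `negative_truncated`, `zero_dyads`.
#' @export
assoc_pcoa <- function(assoc, dims = 2, zero_ceiling = 10) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  h <- assoc$hwi
  n <- nrow(h)
  if (anyNA(h[upper.tri(h)]))
    stop("HWI undefined for some dyad", call. = FALSE)
  d <- 1 / sqrt(h)
  diag(d) <- 0
  zero <- !is.finite(d)
  n_zero <- sum(zero[upper.tri(zero)])
  if (n_zero > 0) {
    ceiling_d <- zero_ceiling * max(d[is.finite(d) & d > 0])
    d[zero] <- ceiling_d
    diag(d) <- 0
    warning(n_zero, " dyad(s) with HWI = 0 set to ceiling dissimilarity ",
            signif(ceiling_d, 4), call. = FALSE)
  }
  dims <- min(dims, n - 1)
  mds <- stats::cmdscale(stats::as.dist(d), k = dims, eig = TRUE)
  neg <- sum(mds$eig < -1e-12)
  if (neg > 0)
    warning(neg, " negative eigenvalue(s) truncated to zero", call. = FALSE)
  pts <- mds$points
  rownames(pts) <- assoc$components
  structure(list(points = pts, eigenvalues = pmax(mds$eig, 0),
                 raw_eigenvalues = mds$eig,
                 negative_truncated = neg, zero_dyads = n_zero),
            class = "assoc_pcoa")
}
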