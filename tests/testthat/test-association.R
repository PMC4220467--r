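test_that("nearest neighbours follow the pairwise geometry", {
  # two components: each is the other's neighbour
  ts2 <- matrix_trackset(cbind(rep(108, 8), rep(108.01, 8)),
                         matrix(34, 8, 2))
  nn2 <- nearest_neighbours(ts2)
  expect_true(all(nn2$neighbour_id != nn2$component_id))
  expect_equal(nn2$neighbour_id[nn2$component_id == "C01"], rep("C02", 8))
  # collinear A-B-C with B central and nearer to C
  ts3 <- matrix_trackset(cbind(rep(108, 8), rep(108.010, 8), rep(108.016, 8)),
                         matrix(34, 8, 3))
  nn3 <- nearest_neighbours(ts3)
  expect_equal(unique(nn3$neighbour_id[nn3$component_id == "C01"]), "C02")
  expect_equal(unique(nn3$neighbour_id[nn3$component_id == "C03"]), "C02")
  expect_equal(unique(nn3$neighbour_id[nn3$component_id == "C02"]), "C03")
  # equidistant pair: tie broken to the smaller id and flagged
  ts_tie <- matrix_trackset(cbind(rep(108, 8), rep(108.01, 8), rep(108.02, 8)),
                            matrix(0, 8, 3))
  nn_tie <- nearest_neighbours(ts_tie)
  b <- nn_tie[nn_tie$component_id == "C02", ]
  expect_equal(unique(b$neighbour_id), "C01")
  expect_true(all(b$tie))
})

test_that("nearest neighbours match an exhaustive-distance oracle", {
  set.seed(31)
  lon <- matrix(108 + rnorm(40 * 5, 0, 0.03), 40, 5)
  lat <- matrix(34 + rnorm(40 * 5, 0, 0.03), 40, 5)
  ts <- matrix_trackset(lon, lat)
  nn <- nearest_neighbours(ts)
  for (r in sample(nrow(nn), 40)) {
    s <- match(nn$slot[r], ts$slots)
    i <- match(nn$component_id[r], ts$components)
    d <- sapply(seq_len(5), function(j)
      if (j == i) Inf else haversine_distance(lon[s, i], lat[s, i],
                                              lon[s, j], lat[s, j]))
    expect_equal(match(nn$neighbour_id[r], ts$components), which.min(d))
    expect_equal(nn$distance_km[r], min(d))
  }
})

test_that("HWI follows the half-weight formula on known tallies", {
  # X=6, Yi=2, Yj=0, Yij=1 over 9 slots -> 6 / (6 + 1 + 1) = 0.75
  m <- matrix(NA_integer_, 9, 3)
  colnames(m) <- c("A", "B", "C")
  # dyad (1,2): mutual in slots 1-6; B->A one-way in 7-8; neither in 9
  m[, 1] <- c(2, 2, 2, 2, 2, 2, 3, 3, 3)
  m[, 2] <- c(1, 1, 1, 1, 1, 1, 1, 1, 3)
  m[, 3] <- rep(1, 9)
  am <- hwi_matrix(nn_table_from_matrix(m, comps = c("A", "B", "C")))
  row <- am$counts[am$counts$comp_i == "A" & am$counts$comp_j == "B", ]
  expect_equal(row$X, 6)
  expect_equal(row$Y_i + row$Y_j, 2)
  expect_equal(row$Y_ij, 1)
  expect_equal(row$hwi, 0.75)
  # permanent mutual neighbours: HWI = 1
  m2 <- cbind(rep(2L, 10), rep(1L, 10), rep(1L, 10))
  am2 <- hwi_matrix(nn_table_from_matrix(m2))
  expect_equal(am2$hwi[1, 2], 1)
  # X = 0: HWI = 0
  expect_equal(am2$hwi[1, 3], 0)
})

test_that("HWI counts conserve the co-observation total and are permutation-equivariant", {
  set.seed(37)
  m <- matrix(0L, 120, 5)
  for (i in 1:5) m[, i] <- sample(setdiff(1:5, i), 120, replace = TRUE)
  nn <- nn_table_from_matrix(m)
  am <- hwi_matrix(nn)
  expect_true(all(am$counts$X + am$counts$Y_i + am$counts$Y_j +
                    am$counts$Y_ij == 120))
  expect_true(all(am$hwi[upper.tri(am$hwi)] >= 0 &
                    am$hwi[upper.tri(am$hwi)] <= 1))
  # relabelling components permutes the matrix accordingly: component i
  # becomes perm[i], so column perm[i] of the new table holds perm[m[, i]]
  perm <- c(3, 1, 4, 5, 2)
  m_perm <- m
  m_perm[, perm] <- matrix(perm[as.vector(m)], nrow(m), 5)
  am_perm <- hwi_matrix(nn_table_from_matrix(m_perm))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(am_perm$hwi[perm[i], perm[j]], am$hwi[i, j])
})

test_that("dendrogram cut at maximum modularity recovers planted herds", {
  set.seed(41)
  comps <- sprintf("C%02d", 1:5)
  w <- matrix(0.1, 5, 5, dimnames = list(comps, comps))
  mem <- c(1, 1, 2, 1, 2)
  w[outer(mem, mem, "==")] <- 0.9
  w <- w + matrix(runif(25, -0.03, 0.03), 5, 5)
  w <- (w + t(w)) / 2
  am <- assoc_from_hwi(w)
  dend <- cluster_dendrogram(am)
  expect_equal(dend$cutoff_k, 2)
  expect_equal(unname(dend$membership == dend$membership[1]), mem == mem[1])
  # modularity at every dendrogram cut equals the community-sum oracle
  for (k in 1:5) {
    ct <- stats::cutree(dend$hclust, k)
    expect_equal(dend$modularity$modularity[k], ref_modularity(am$hwi, ct),
                 tolerance = 1e-12)
  }
  # trivial partitions never beat the reported maximum
  expect_gte(max(dend$modularity$modularity),
             dend$modularity$modularity[1])
  expect_gte(max(dend$modularity$modularity),
             dend$modularity$modularity[5])
  # heights monotone
  expect_true(!is.unsorted(dend$hclust$height))
})

test_that("flat association structure gives near-zero modularity", {
  comps <- sprintf("C%02d", 1:5)
  w <- matrix(0.5, 5, 5, dimnames = list(comps, comps))
  dend <- cluster_dendrogram(assoc_from_hwi(w))
  expect_true(all(abs(dend$modularity$modularity[2:4]) < 0.21))
  # single cluster (k=1) modularity is exactly 0 for any graph
  expect_equal(dend$modularity$modularity[1], 0, tolerance = 1e-12)
})

test_that("package modularity agrees with igraph on weighted graphs", {
  skip_if_not_installed("igraph")
  set.seed(43)
  for (k in 1:10) {
    w <- matrix(runif(25), 5, 5); w <- (w + t(w)) / 2; diag(w) <- 0
    mem <- sample(1:3, 5, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(weighted_modularity(w, mem),
                 igraph::modularity(g, mem, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("newick export preserves the tree topology", {
  comps <- sprintf("C%02d", 1:5)
  w <- matrix(0.1, 5, 5, dimnames = list(comps, comps))
  mem <- c(1, 1, 1, 2, 2)
  w[outer(mem, mem, "==")] <- 0.9
  dend <- cluster_dendrogram(assoc_from_hwi(w))
  path <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(dend, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, comps)
  expect_equal(ape::Ntip(phy), 5)
})

test_that("lagged association rate: permanent pairs, lag zero, and shuffles", {
  # permanently associated pair: g = 1 at every lag
  m <- cbind(rep(2L, 50), rep(1L, 50))
  lar <- lagged_association_rate(nn_table_from_matrix(m), lags = 0:20)
  expect_equal(lar$g, rep(1, 21))
  # g(0) = 1 by construction whenever any association exists
  set.seed(47)
  m5 <- matrix(0L, 200, 5)
  for (i in 1:5) m5[, i] <- sample(setdiff(1:5, i), 200, replace = TRUE)
  lar5 <- lagged_association_rate(nn_table_from_matrix(m5), lags = 0:30)
  expect_equal(lar5$g[1], 1)
  expect_true(all(lar5$g >= 0 & lar5$g <= 1, na.rm = TRUE))
  # out-of-range lags dropped with a warning
  expect_warning(lagged_association_rate(nn_table_from_matrix(m), 0:60),
                 "dropped")
})

test_that("lagged rate of a stationary Markov association matches its closed form", {
  # two components with persistent association: stay prob p11, entry p01
  set.seed(53)
  p11 <- 0.8; p01 <- 0.2
  ns <- 20000
  a <- integer(ns); a[1] <- 1
  for (t in 2:ns) a[t] <- rbinom(1, 1, if (a[t - 1] == 1) p11 else p01)
  # encode as mutual NN of (1,2) in a 3-component table; when apart, the
  # neighbour graph is the cycle 1->2, 2->3, 3->1 (no mutual pair at all)
  m <- matrix(0L, ns, 3)
  m[, 1] <- 2L
  m[, 2] <- ifelse(a == 1, 1L, 3L)
  m[, 3] <- 1L
  lar <- lagged_association_rate(nn_table_from_matrix(m), lags = c(1, 2, 5))
  # analytic k-step persistence probability of the two-state chain
  pstat <- p01 / (1 - p11 + p01)
  step <- function(k) pstat + (1 - pstat) * (p11 - p01)^k
  for (i in seq_len(3)) {
    # dyads (1,3) and (2,3) are never associated; they do not enter g
    expect_equal(lar$g[i], step(lar$tau[i]), tolerance = 0.03)
  }
})

test_that("decay model fitting identifies constant and exponential curves", {
  # constant series: constant model wins with a = level
  rates <- data.frame(tau = 0:20, g = rep(0.8, 21))
  f1 <- fit_decay_models(rates)
  expect_equal(f1$preferred, "constant")
  expect_equal(unname(f1$models$constant$coef["a"]), 0.8)
  # noisy offset exponential: parameters recovered within 10%
  set.seed(59)
  tau <- 0:60
  g <- 0.5 * exp(-0.1 * tau) + 0.2 + rnorm(61, 0, 0.01)
  f2 <- fit_decay_models(data.frame(tau = tau, g = g))
  expect_equal(f2$preferred, "exponential")
  cf <- f2$models$exponential$coef
  expect_equal(unname(cf["a"]), 0.5, tolerance = 0.1)
  expect_equal(unname(cf["b"]), 0.1, tolerance = 0.1)
  expect_equal(unname(cf["c"]), 0.2, tolerance = 0.1)
  # b -> 0 limit: exponential reduces to a constant a + c
  g3 <- 0.3 * exp(-1e-9 * tau) + 0.4
  f3 <- fit_decay_models(data.frame(tau = tau, g = g3))
  cf3 <- f3$models$exponential$coef
  if (f3$models$exponential$converged)
    expect_equal(unname(cf3["a"] * exp(-cf3["b"] * 30) + cf3["c"]), 0.7,
                 tolerance = 1e-3)
  expect_error(fit_decay_models(data.frame(tau = 0:2, g = rep(1, 3))),
               ">= 4 lag bins")
})

test_that("principal coordinates embedding respects the 1/sqrt(HWI) metric", {
  comps <- c("A", "B", "C")
  w <- matrix(0.25, 3, 3, dimnames = list(comps, comps))
  pc <- assoc_pcoa(assoc_from_hwi(w))
  d <- as.matrix(dist(pc$points))
  # equal HWIs embed as an equilateral triangle
  expect_equal(sd(d[upper.tri(d)]), 0, tolerance = 1e-9)
  expect_equal(d[1, 2], 1 / sqrt(0.25), tolerance = 1e-9)
  # already-Euclidean distances (collinear points) reproduce exactly
  x <- c(0, 1, 3, 6)
  dm <- abs(outer(x, x, "-"))
  hw <- 1 / dm^2; diag(hw) <- NA
  dimnames(hw) <- list(letters[1:4], letters[1:4])
  pc2 <- suppressWarnings(assoc_pcoa(assoc_from_hwi(hw), dims = 2))
  d2 <- as.matrix(dist(pc2$points))
  expect_equal(d2[upper.tri(d2)], dm[upper.tri(dm)], tolerance = 1e-9)
  # zero HWI gets the ceiling with a warning
  w0 <- matrix(c(NA, 0.5, 0, 0.5, NA, 0.5, 0, 0.5, NA), 3, 3,
               dimnames = list(comps, comps))
  expect_warning(pc3 <- assoc_pcoa(assoc_from_hwi(w0)), "ceiling")
  expect_equal(pc3$zero_dyads, 1)
})

test_that("pcoa eigenvalues match a direct double-centred eigendecomposition", {
  set.seed(61)
  w <- matrix(runif(25, 0.1, 1), 5, 5); w <- (w + t(w)) / 2
  comps <- sprintf("C%02d", 1:5)
  dimnames(w) <- list(comps, comps)
  pc <- suppressWarnings(assoc_pcoa(assoc_from_hwi(w), dims = 4))
  d <- 1 / sqrt(w); diag(d) <- 0
  # spectral oracle: B = -0.5 J D^2 J
  J <- diag(5) - matrix(1 / 5, 5, 5)
  B <- -0.5 * J %*% d^2 %*% J
  ev <- eigen(B, symmetric = TRUE)$values
  expect_equal(sort(pc$raw_eigenvalues, decreasing = TRUE)[1:4],
               ev[1:4], tolerance = 1e-9)
})
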