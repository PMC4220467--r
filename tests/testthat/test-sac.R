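test_that("spread statistic is zero at coincidence and the circumradius on regular polygons", {
  ts0 <- matrix_trackset(matrix(108, 8, 3), matrix(34, 8, 3))
  expect_equal(spread_series(ts0)$a_deg, rep(0, 8))
  for (n in 3:8) {
    R <- 0.01
    ts <- polygon_trackset(n, R)
    expect_equal(spread_series(ts)$a_deg, rep(R, 8), tolerance = 1e-12)
  }
})

test_that("spread statistic matches a direct-summation variance oracle", {
  set.seed(14)
  for (k in 1:30) {
    lon <- matrix(108 + rnorm(8 * 5, 0, 0.02), 8, 5)
    lat <- matrix(34 + rnorm(8 * 5, 0, 0.02), 8, 5)
    sp <- spread_series(matrix_trackset(lon, lat))
    for (s in 1:8) {
      vx <- sum((lon[s, ] - mean(lon[s, ]))^2) / 5
      vy <- sum((lat[s, ] - mean(lat[s, ]))^2) / 5
      expect_equal(sp$a_deg[s], sqrt(vx + vy), tolerance = 1e-12)
      expect_equal(sp$var_lon[s], vx, tolerance = 1e-14)
    }
  }
})

test_that("spread is homogeneous under scaling and SAC translation-invariant", {
  set.seed(15)
  lon <- matrix(108 + rnorm(16 * 5, 0, 0.02), 16, 5)
  lat <- matrix(34 + rnorm(16 * 5, 0, 0.02), 16, 5)
  a1 <- spread_series(matrix_trackset(lon, lat))$a_deg
  # scale about per-slot centroid by 3
  cl <- rowMeans(lon); ct <- rowMeans(lat)
  lon3 <- cl + 3 * (lon - cl); lat3 <- ct + 3 * (lat - ct)
  a3 <- spread_series(matrix_trackset(lon3, lat3))$a_deg
  expect_equal(a3, 3 * a1, tolerance = 1e-9)
  # rigid translation leaves SAC unchanged
  s1 <- standardize_sac(a1)
  s2 <- standardize_sac(spread_series(matrix_trackset(lon + 0.3,
                                                      lat - 0.2))$a_deg)
  expect_equal(s2, s1, tolerance = 1e-9)
})

test_that("communication radius follows circumcircle trigonometry", {
  # hexagon: side equals circumradius
  expect_equal(communication_radius(513.12, 6), metres_to_degrees(513.12),
               tolerance = 1e-12)
  expect_equal(degrees_to_metres(communication_radius(513.12, 6)), 513.12)
  # pentagon
  r5 <- communication_radius(513.12, 5)
  expect_equal(degrees_to_metres(r5), 513.12 / (2 * sin(pi / 5)),
               tolerance = 1e-9)
  expect_equal(degrees_to_metres(r5), 436.46, tolerance = 1e-2)
  expect_equal(r5, 0.003921, tolerance = 1e-4)
  # linear homogeneity in d
  expect_equal(communication_radius(2 * 513.12, 5), 2 * r5, tolerance = 1e-14)
  expect_error(communication_radius(513.12, 2), "n must be")
  expect_error(communication_radius(-1, 5), "d must be")
})

test_that("SAC standardization maps the spread into [0,1]", {
  a <- c(0, 0.25, 0.5, 1) * 0.02
  std <- sac_standardizer(a)  # quadratic default
  s <- standardize_sac(a, std)
  expect_equal(s, c(0, 0.0625, 0.25, 1))
  lin <- sac_standardizer(a, method = "linear")
  expect_equal(standardize_sac(a, lin), c(0, 0.25, 0.5, 1))
  # order preservation and clipping above the calibration maximum
  expect_equal(standardize_sac(0.04, std), 1)
  expect_error(sac_standardizer(rep(0, 5)), "max\\(A\\) > 0")
})

test_that("thresholds derive from the isogon geometry in exact ratio 4", {
  a_max <- 0.02
  std <- sac_standardizer(c(0.001, a_max))
  th <- sac_thresholds(std, d = 513.12, n = 5)
  expect_lt(th$sac_fusion, th$sac_fission)
  expect_equal(th$sac_fission / th$sac_fusion, 4, tolerance = 1e-12)
  expect_equal(th$sac_fusion,
               (communication_radius(513.12, 5) / a_max)^2, tolerance = 1e-12)
  # fission radius beyond the calibration maximum clips to 1 with a warning
  d_big <- 1.2 * degrees_to_metres(a_max) * sin(pi / 5)
  expect_warning(th2 <- sac_thresholds(std, d = d_big, n = 5),
                 "clipped")
  expect_equal(th2$sac_fission, 1)
  expect_equal(th2$sac_fusion, 0.36, tolerance = 1e-12)
  # explicit overrides bypass the geometry
  th3 <- sac_thresholds(NULL, sac_fusion = 0.1139, sac_fission = 0.4571)
  expect_true(th3$overridden)
  expect_error(sac_thresholds(NULL, sac_fusion = 0.5, sac_fission = 0.1))
})

test_that("stage classification follows the four-stage state machine", {
  th <- sac_thresholds(NULL, sac_fusion = 0.1139, sac_fission = 0.4571)
  # constant low series: one fusion stage spanning everything
  seg <- classify_stages(rep(0.05, 10), th)
  expect_equal(seg$segments$stage, "fusion")
  expect_equal(stage_fractions(seg)[["fusion"]], 1)
  # hand-traced sequence: fission(1-3), reform(4-5), fusion(6-8)
  s <- c(0.6, 0.6, 0.6, 0.3, 0.3, 0.05, 0.05, 0.05)
  seg2 <- classify_stages(s, th)
  expect_equal(seg2$label,
               c(rep("fission", 3), rep("reform", 2), rep("fusion", 3)))
  # boundary: SAC exactly at the fusion threshold counts as fusion
  seg3 <- classify_stages(rep(0.1139, 6), th)
  expect_equal(unique(seg3$label), "fusion")
  # no crossings at all: separation with a warning
  expect_warning(seg4 <- classify_stages(rep(0.3, 8), th), "separation")
  expect_equal(unique(seg4$label), "separation")
  expect_error(classify_stages(numeric(0), th), "empty")
})

test_that("sub-persistence excursions do not interrupt a stage", {
  th <- sac_thresholds(NULL, sac_fusion = 0.1139, sac_fission = 0.4571)
  s <- c(rep(0.05, 4), 0.3, 0.3, rep(0.05, 4))  # 2-slot mid excursion
  seg <- classify_stages(s, th)
  expect_equal(unique(seg$label), "fusion")
  fr <- stage_fractions(seg)
  expect_equal(unname(fr[["fusion"]]), 1)
})

test_that("classifier agrees with the sliding-window reference on random series", {
  th <- sac_thresholds(NULL, sac_fusion = 0.1139, sac_fission = 0.4571)
  set.seed(19)
  for (k in 1:200) {
    n <- sample(5:40, 1)
    cls <- sample(c("lo", "mid", "hi"), n, replace = TRUE)
    got <- suppressWarnings(classify_stages(code_to_sac(cls), th)$label)
    expect_equal(got, ref_classify(cls, 3))
  }
})

test_that("stage fractions are the per-stage slot shares", {
  th <- sac_thresholds(NULL, sac_fusion = 0.1139, sac_fission = 0.4571,
                       persistence = 2)
  s <- c(0.6, 0.6, 0.3, 0.3, 0.3, 0.05, 0.05, 0.05, 0.05, 0.05)
  fr <- stage_fractions(classify_stages(s, th))
  expect_equal(unname(fr[c("fission", "reform", "fusion")]),
               c(0.2, 0.3, 0.5))
  expect_equal(sum(fr), 1)
})

test_that("pairwise component distances match a haversine oracle", {
  # identical tracks: all-zero distances
  ts0 <- matrix_trackset(matrix(108, 8, 2), matrix(34, 8, 2))
  expect_equal(pairwise_component_distances(ts0)$distance_km, rep(0, 8))
  # constant longitudinal offset at the equator
  off <- 0.004609
  ts1 <- matrix_trackset(cbind(rep(10, 8), rep(10 + off, 8)),
                         matrix(0, 8, 2))
  d <- pairwise_component_distances(ts1)$distance_km
  expect_equal(d, rep(0.51312, 8), tolerance = 1e-4)
  # random trackset equals the per-slot oracle
  set.seed(23)
  lon <- matrix(108 + rnorm(8 * 4, 0, 0.05), 8, 4)
  lat <- matrix(34 + rnorm(8 * 4, 0, 0.05), 8, 4)
  ts <- matrix_trackset(lon, lat)
  dd <- pairwise_component_distances(ts)
  for (r in sample(nrow(dd), 20)) {
    i <- match(dd$comp_i[r], ts$components)
    j <- match(dd$comp_j[r], ts$components)
    s <- match(dd$slot[r], ts$slots)
    expect_equal(dd$distance_km[r],
                 haversine_distance(lon[s, i], lat[s, i],
                                    lon[s, j], lat[s, j]))
  }
  # summary block
  sm <- summarize_dyads(dd)
  expect_equal(nrow(sm), choose(4, 2))
  g <- dd[dd$comp_i == sm$comp_i[1] & dd$comp_j == sm$comp_j[1], ]
  expect_equal(sm$mean_km[1], mean(g$distance_km))
  expect_equal(sm$se_km[1], sd(g$distance_km) / sqrt(nrow(g)))
})

test_that("group comparisons reproduce the textbook statistics", {
  set.seed(27)
  # identical groups: near-zero statistic, p ~ 1
  x <- rnorm(50)
  r0 <- compare_distances(c(x, x), rep(c("a", "b"), each = 50))
  expect_equal(r0$statistic[1], 0, tolerance = 1e-12)
  expect_equal(r0$p_value[1], 1, tolerance = 1e-9)
  # separated by 10 sd: rejection at alpha = 0.05
  y <- rnorm(100); z <- rnorm(100, 10)
  r1 <- compare_distances(c(y, z), rep(c("a", "b"), each = 100))
  expect_true(all(r1$p_value < 0.05))
  # three groups: F equals the direct between/within ratio
  v <- c(rnorm(40, 0), rnorm(40, 0.5), rnorm(40, 1))
  gl <- rep(c("a", "b", "c"), each = 40)
  r2 <- compare_distances(v, gl)
  grand <- mean(v)
  ssb <- sum(tapply(v, gl, function(g) length(g) * (mean(g) - grand)^2))
  ssw <- sum(tapply(v, gl, function(g) sum((g - mean(g))^2)))
  f_ref <- (ssb / 2) / (ssw / (120 - 3))
  expect_equal(r2$statistic[1], f_ref, tolerance = 1e-9)
  expect_equal(r2$df[1], "2, 117")
  expect_error(compare_distances(v, rep("a", 120)), ">= 2 groups")
})
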