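test_that("centroid and distances match brute-force summation", {
  expect_equal(team_centroid(rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2))),
               c(1, 1))
  expect_equal(team_centroid(rbind(c(7, -3))), c(7, -3))
  expect_equal(centroid_distances(rbind(c(0, 0), c(2, 0))), c(1, 1))
  expect_equal(centroid_distances(rbind(c(5, 5), c(5, 5))), c(0, 0))
  set.seed(42)
  for (i in 1:20) {
    pts <- matrix(runif(8, 0, 1e5), 4, 2)
    ctr <- c(sum(pts[, 1]) / 4, sum(pts[, 2]) / 4)  # independent summation
    expect_equal(team_centroid(pts), ctr)
    d <- vapply(1:4, function(k) sqrt(sum((pts[k, ] - ctr)^2)), numeric(1))
    expect_equal(centroid_distances(pts), d, tolerance = 1e-9)
  }
  expect_error(team_centroid(matrix(numeric(0), 0, 2)), "at least one")
})

test_that("pair distances enumerate all unordered pairs", {
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(sort(pair_distances(sq)), sort(c(1, 1, 1, 1, sqrt(2),
                                                sqrt(2))))
  expect_length(pair_distances(matrix(runif(8), 4, 2)), 6)
  set.seed(7)
  pts <- matrix(runif(10, 0, 1e4), 5, 2)
  oracle <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    oracle <- c(oracle, sqrt(sum((pts[i, ] - pts[j, ])^2)))
  }
  expect_equal(sort(pair_distances(pts)), sort(oracle))
  expect_error(pair_distances(rbind(c(0, 0))), "at least two")
})

test_that("cluster_players with min_pts 1 is epsilon-graph components", {
  # all within 100 m -> one cluster; all apart -> singletons
  expect_equal(length(unique(cluster_players(rbind(c(0, 0), c(5000, 0),
                                                   c(0, 5000), c(5000, 5000))))), 1L)
  far <- rbind(c(0, 0), c(30000, 0), c(0, 30000), c(30000, 30000))
  expect_equal(length(unique(cluster_players(far))), 4L)
  # chaining: A-B and B-C at 90 m, A-C at 180 m -> one component
  chain <- rbind(c(0, 0), c(9000, 0), c(18000, 0))
  expect_equal(length(unique(cluster_players(chain))), 1L)
  expect_error(cluster_players(rbind(c(0, 0)), min_pts = 2), "min_pts")

  skip_if_not_installed("igraph")
  set.seed(99)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    pts <- matrix(runif(2 * n, 0, 4e4), n, 2)
    labels <- cluster_players(pts)
    adj <- as.matrix(dist(pts)) <= 10000
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
    # identical partitions (labels may differ by renaming)
    expect_equal(length(unique(labels)), comp$no)
    expect_true(all(tapply(comp$membership, labels,
                           function(g) length(unique(g))) == 1))
  }
})

test_that("interdependence states follow the cluster-count rule", {
  expect_equal(classify_interdependence(c(1, 1, 1, 1)), "HIGH")
  expect_equal(classify_interdependence(c(1, 2, 3, 4)), "LOW")
  expect_equal(classify_interdependence(c(1, 1, 2, 2)), "MEDIUM")
  expect_true(is.na(classify_interdependence(1, n_alive = 1)))
})

test_that("distance normalization is log1p of remaining-time scaling", {
  expect_equal(normalize_distance(0, 0, 1800), 0)
  expect_equal(normalize_distance(10000, 0, 1800), log1p(10000))
  # late-game samples are up-weighted
  expect_gt(normalize_distance(10000, 0.9 * 1800, 1800),
            normalize_distance(10000, 0, 1800))
  # floor caps the late-game multiplier at 1/floor
  expect_equal(normalize_distance(100, 1799, 1800),
               log1p(100 / 0.1))
  expect_error(normalize_distance(1, 0, 0), "duration")
  # monotone in d at fixed t
  d <- seq(0, 5e4, by = 1e4)
  expect_false(is.unsorted(normalize_distance(d, 500, 1800)))
})

test_that("collaboration features: degenerate and split-team cases", {
  # all four players coincident at all times: HIGH share 1, collab ~ 0
  tight <- team_table_at(rbind(c(1e5, 1e5), c(1e5, 1e5), c(1e5, 1e5),
                               c(1e5, 1e5)))
  ft <- collaboration_features(tight, duration_s = 1800)
  expect_equal(ft$share_high, 1)
  expect_equal(ft$collab_high, 0)
  expect_equal(ft$collab_low, 0)
  # two 2-player subgroups 1 km apart: MEDIUM throughout
  split2 <- team_table_at(rbind(c(0, 0), c(1000, 0),
                                c(100000, 0), c(101000, 0)))
  ft2 <- collaboration_features(split2, duration_s = 1800)
  expect_equal(ft2$share_med, 1)
  expect_true(ft2$collab_high <= ft2$collab_low)
})

test_that("shares sum to one and collab_high <= collab_low on simulated teams", {
  beh <- behavior_features(simulate_match(small_config(11), 1)$telemetry)
  keep <- beh$n_timepoints > 0
  expect_true(all(abs(beh$share_high[keep] + beh$share_med[keep] +
                        beh$share_low[keep] - 1) < 1e-12))
  expect_true(all(beh$collab_high[keep] <= beh$collab_low[keep] + 1e-12))
})

test_that("behavior features are invariant under rigid motions", {
  set.seed(5)
  xy <- matrix(runif(8, 4e4, 6e4), 4, 2)
  tab <- team_table_at(xy)
  ft <- collaboration_features(tab, duration_s = 1800)
  # rotate by 37 degrees about the map center and translate
  th <- 37 * pi / 180
  ctr <- c(5e4, 5e4)
  rot <- function(p) {
    q <- sweep(p, 2, ctr)
    cbind(q[, 1] * cos(th) - q[, 2] * sin(th),
          q[, 1] * sin(th) + q[, 2] * cos(th)) +
      matrix(ctr + c(1234, -987), nrow(p), 2, byrow = TRUE)
  }
  ft2 <- collaboration_features(team_table_at(rot(xy)), duration_s = 1800)
  for (col in c("share_high", "share_med", "share_low", "collab_high",
                "collab_low", "sd_dist")) {
    expect_equal(ft2[[col]], ft[[col]], tolerance = 1e-9)
  }
})

test_that("mean HIGH share falls as together-time falls and dispersion grows", {
  # p_together is the dial for clustering time; cohesion for tightness
  shares <- sapply(c(0.9, 0.4, 0.1), function(p) {
    cfg <- sim_config(seed = 21, map_name = "Karakin", n_teams = 10,
                      n_matches = 2, cap_s = 600, p_together = p,
                      cohesion_sigma_cm = 2e3)
    coh <- simulate_cohort(cfg, reference_landings = 1000)
    mean(behavior_features(coh$matches)$share_high, na.rm = TRUE)
  })
  expect_true(all(diff(shares) < 0))
  # cohesion sweep at full together-time (degenerate split process)
  shares2 <- sapply(c(2e3, 2e4, 2e5), function(sg) {
    cfg <- sim_config(seed = 22, map_name = "Karakin", n_teams = 10,
                      n_matches = 2, cap_s = 600, p_together = 1,
                      cohesion_sigma_cm = sg)
    coh <- simulate_cohort(cfg, reference_landings = 1000)
    mean(behavior_features(coh$matches)$share_high, na.rm = TRUE)
  })
  expect_true(all(diff(shares2) < 0))
})
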