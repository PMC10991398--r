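test_that("cell_index partitions the map into half-open 10 m cells", {
  expect_equal(cell_index(0, 0, 1000, 204)[1, ], c(i = 0L, j = 0L))
  expect_equal(cell_index(999, 1000, 1000, 204)[1, ], c(i = 0L, j = 1L))
  # the max-coordinate edge belongs to the last cell
  expect_equal(cell_index(204000, 204000, 1000, 204)[1, ],
               c(i = 203L, j = 203L))
  expect_error(cell_index(-1, 0, 1000, 204), "outside")
  # every in-bounds point maps to exactly one cell
  set.seed(8)
  xy <- matrix(runif(200, 0, 204000), 100, 2)
  ij <- cell_index(xy[, 1], xy[, 2], 1000, 204)
  expect_true(all(ij >= 0 & ij <= 203))
})

test_that("heatmaps count landings with conservation", {
  same <- data.frame(x_cm = c(100, 500, 900), y_cm = c(100, 500, 900))
  hm <- build_heatmap(same, "Karakin")
  expect_equal(hm$counts[1, 1], 3L)
  expect_equal(sum(hm$counts), 3L)
  set.seed(9)
  n <- 500
  ld <- data.frame(x_cm = runif(n, 0, 204000), y_cm = runif(n, 0, 204000))
  expect_equal(sum(build_heatmap(ld, "Karakin")$counts), n)
  expect_error(build_heatmap(data.frame(x_cm = 5e5, y_cm = 0), "Karakin"),
               "outside")
})

test_that("hotspot-concentrated landings put the modal cell at the hotspot", {
  cfg <- sim_config(seed = 43, map_name = "Karakin",
                    landing_risk_preference = 1,
                    hotspot_centers = rbind(c(50000, 150000)),
                    hotspot_weights = 1, hotspot_sigma_cm = 3000,
                    cohesion_sigma_cm = 500)
  ld <- simulate_reference_landings(cfg, 20000)
  hm <- build_heatmap(ld, "Karakin")
  peak <- which(hm$counts == max(hm$counts), arr.ind = TRUE)[1, ]
  peak_xy <- (peak - 0.5) * 1000
  expect_lt(sqrt(sum((peak_xy - c(50000, 150000))^2)), 3 * 3000)
})

test_that("landing risk is a reference-cell lookup", {
  ref <- data.frame(x_cm = c(100, 200, 800, 50000), y_cm = c(100, 300, 900,
                                                             50000))
  hm <- build_heatmap(ref, "Karakin")
  expect_equal(landing_risk(data.frame(x_cm = 500, y_cm = 500), hm), 3L)
  expect_equal(landing_risk(data.frame(x_cm = 100000, y_cm = 100000), hm), 0L)
  hm2 <- build_heatmap(ref, "Sanhok")
  expect_error(landing_risk(data.frame(x_cm = 1, y_cm = 1), hm2,
                            map_name = "Karakin"), "mismatch")
  # lookup equals rebuild-and-index on random cohorts
  set.seed(10)
  ld <- data.frame(x_cm = runif(300, 0, 204000),
                   y_cm = runif(300, 0, 204000))
  hm3 <- build_heatmap(ld, "Karakin")
  lr <- landing_risk(ld, hm3)
  for (k in sample(300, 20)) {
    ij <- cell_index(ld$x_cm[k], ld$y_cm[k], 1000, 204)
    expect_equal(lr[k], sum(floor(ld$x_cm / 1000) == ij[1] &
                              floor(ld$y_cm / 1000) == ij[2]))
  }
})

test_that("team landing risk takes member extremes", {
  expect_equal(team_landing_risk(c(0, 3, 5, 5)), c(high = 5, low = 0))
  expect_equal(team_landing_risk(7), c(high = 7, low = 7))
  set.seed(11)
  for (i in 1:10) {
    v <- sample(0:20, 4)
    s <- sort(v)
    expect_equal(unname(team_landing_risk(v)), c(s[4], s[1]))
  }
  expect_error(team_landing_risk(numeric(0)), "empty")
})

test_that("high-risk cutoff is the median over nonzero cells", {
  hm <- build_heatmap(data.frame(x_cm = c(100, 1100, 2100, rep(3100, 9)),
                                 y_cm = 100), "Karakin")
  # nonzero counts {1,1,1,9}: cutoff 1, only the 9-cell is high-risk
  expect_equal(risk_cell_threshold(hm), 1)
  expect_equal(sum(hm$counts > risk_cell_threshold(hm)), 1L)
  # uniform landings, one per cell: nothing above the median
  hmu <- build_heatmap(data.frame(x_cm = seq(100, 9100, by = 1000),
                                  y_cm = 100), "Karakin")
  expect_equal(sum(hmu$counts > risk_cell_threshold(hmu)), 0L)
  empty <- build_heatmap(data.frame(x_cm = numeric(0), y_cm = numeric(0)),
                         "Karakin")
  expect_error(risk_cell_threshold(empty), "all-zero")
  # classification against a sort-based oracle
  set.seed(12)
  ldr <- data.frame(x_cm = runif(200, 0, 204000),
                    y_cm = runif(200, 0, 204000))
  hmr <- build_heatmap(ldr, "Karakin")
  cut <- risk_cell_threshold(hmr)
  nz <- sort(hmr$counts[hmr$counts > 0])
  expect_equal(cut, median(nz))
})

test_that("overtime risk accumulates 10 s per sampled point, max over members", {
  ref <- data.frame(x_cm = rep(c(500, 500, 500, 90500), c(5, 5, 5, 1)),
                    y_cm = rep(c(500, 500, 500, 90500), c(5, 5, 5, 1)))
  hm <- build_heatmap(ref, "Karakin")
  cutoff <- risk_cell_threshold(hm)   # high-risk: the 15-count cell
  # one member parked in the high-risk cell for 30 timepoints
  tab <- team_table_at(rbind(c(500, 500), c(150000, 150000)),
                       times = seq(0, 290, by = 10))
  ot <- overtime_risk(tab, hm, cutoff)
  expect_equal(unname(ot["time_high_risk_s"]), 300)
  expect_equal(unname(ot["time_low_risk_s"]), 300)
  # nobody in high-risk cells
  tab2 <- team_table_at(rbind(c(120000, 120000), c(150000, 150000)))
  expect_equal(unname(overtime_risk(tab2, hm, cutoff)["time_high_risk_s"]),
               0)
})

test_that("risk categories discretize at cohort quantiles, monotonically", {
  expect_equal(risk_category(c(1, 2, 3)), c(-1L, 0L, 1L))
  expect_equal(risk_category(rep(4, 10)), rep(0L, 10))
  set.seed(13)
  v <- runif(300)
  lab <- risk_category(v, q_low = 1/3, q_high = 2/3)
  expect_true(all(abs(table(lab) - 100) <= 2))
  # tertile oracle
  qs <- quantile(v, c(1/3, 2/3), names = FALSE)
  expect_equal(lab, ifelse(v < qs[1], -1L, ifelse(v > qs[2], 1L, 0L)))
  # monotone: raising a value never lowers its label
  v2 <- v; v2[5] <- v2[5] + 10
  expect_gte(risk_category(v2, 1/3, 2/3)[5], lab[5])
})

test_that("mean overtime risk rises with landing risk preference", {
  means <- sapply(c(0, 0.5, 1), function(p) {
    cfg <- sim_config(seed = 44, map_name = "Karakin", n_teams = 13,
                      n_matches = 4, cap_s = 600,
                      landing_risk_preference = p)
    coh <- simulate_cohort(cfg, reference_landings = 20000)
    mean(risk_features(coh$matches, coh$heatmap)$time_high_risk_s)
  })
  expect_true(all(diff(means) > 0))
})
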