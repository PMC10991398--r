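test_that("every generator is deterministic under its seed", {
  cfg <- small_config(31)
  a <- simulate_match(cfg, 1)
  b <- simulate_match(cfg, 1)
  expect_identical(a$telemetry$landings, b$telemetry$landings)
  expect_identical(a$telemetry$final_ranks, b$telemetry$final_ranks)
  expect_identical(location_table(a$telemetry), location_table(b$telemetry))
  # distinct matches of a cohort differ; distinct seeds give disjoint ids
  c1 <- simulate_cohort(small_config(31), reference_landings = 500)
  c2 <- simulate_cohort(small_config(32), reference_landings = 500)
  ids1 <- sapply(c1$matches, function(m) m$meta$match_id)
  ids2 <- sapply(c2$matches, function(m) m$meta$match_id)
  expect_length(intersect(ids1, ids2), 0)
})

test_that("landing anchors follow the hotspot mixture law", {
  # no hotspot preference: uniform over the map (chi-square GOF, 4x4 grid)
  cfg <- sim_config(seed = 41, map_name = "Karakin", n_teams = 25,
                    landing_risk_preference = 0, cohesion_sigma_cm = 1)
  set.seed(41)
  tp <- squadrank:::.draw_team_params(cfg)
  anchors <- do.call(rbind, lapply(1:400, function(i)
    simulate_landings(cfg, tp)$anchors))
  cell <- floor(anchors[, 1] / 51000) * 4 + floor(anchors[, 2] / 51000)
  gof <- chisq.test(table(factor(cell, levels = 0:15)))
  expect_gt(gof$p.value, 0.01)
  # full preference, one hotspot: anchors concentrate within 3 sigma
  cfg2 <- sim_config(seed = 42, map_name = "Karakin", n_teams = 25,
                     landing_risk_preference = 1,
                     hotspot_centers = rbind(c(100000, 100000)),
                     hotspot_weights = 1, hotspot_sigma_cm = 4000)
  set.seed(42)
  tp2 <- squadrank:::.draw_team_params(cfg2)
  anchors2 <- do.call(rbind, lapply(1:400, function(i)
    simulate_landings(cfg2, tp2)$anchors))
  # per-axis three-sigma bound (the scatter is Gaussian per coordinate)
  ok3 <- abs(anchors2[, 1] - 1e5) <= 3 * 4000 &
    abs(anchors2[, 2] - 1e5) <= 3 * 4000
  expect_gt(mean(ok3), 0.99)
})

test_that("trajectories respect dispersion and circle containment", {
  sch <- shrink_schedule(204000, cap_s = 600)
  # expected member-centroid distance grows with cohesion sigma
  meandist <- sapply(c(1e3, 1e4, 5e4), function(sg) {
    cfg <- sim_config(seed = 51, map_name = "Karakin", n_teams = 10,
                      cap_s = 600, p_together = 1, cohesion_sigma_cm = sg)
    set.seed(51)
    tp <- squadrank:::.draw_team_params(cfg)
    land <- simulate_landings(cfg, tp)
    traj <- simulate_trajectories(cfg, land$anchors, sch, tp)
    d <- 0
    for (k in seq_along(traj$t_s)) {
      for (i in 1:10) {
        pts <- cbind(traj$X[, i, k], traj$Y[, i, k])
        d <- d + mean(centroid_distances(pts))
      }
    }
    d
  })
  expect_true(all(diff(meandist) > 0))
  # cohesion -> 0 with no splits: all pair distances -> 0
  cfg0 <- sim_config(seed = 52, map_name = "Karakin", n_teams = 5,
                     cap_s = 300, p_together = 1, cohesion_sigma_cm = 1e-6)
  set.seed(52)
  tp0 <- squadrank:::.draw_team_params(cfg0)
  traj0 <- simulate_trajectories(cfg0, simulate_landings(cfg0, tp0)$anchors,
                                 shrink_schedule(204000, cap_s = 300), tp0)
  expect_lt(max(abs(traj0$X[1, , ] - traj0$X[2, , ])), 1e-3)
  # together-regime positions stay inside circle radius + 3 sigma (+ map)
  cfg1 <- sim_config(seed = 53, map_name = "Karakin", n_teams = 10,
                     cap_s = 600, p_together = 1, cohesion_sigma_cm = 5e3)
  set.seed(53)
  tp1 <- squadrank:::.draw_team_params(cfg1)
  traj1 <- simulate_trajectories(cfg1, simulate_landings(cfg1, tp1)$anchors,
                                 sch, tp1)
  ctr <- 204000 / 2
  ok <- TRUE
  for (k in 2:length(traj1$t_s)) {
    r <- shrink_radius(traj1$t_s[k], sch)
    dd <- sqrt((traj1$X[, , k] - ctr)^2 + (traj1$Y[, , k] - ctr)^2)
    ok <- ok && all(dd <= r + 3 * 5e3 + 1e-6)
  }
  expect_true(ok)
  expect_true(all(traj1$X >= 0 & traj1$X <= 204000))
})

test_that("a null hazard makes every team equally likely to win", {
  hz <- hazard_params(b_high = 0, b_med = 0, b_low = 0, q_high = 0,
                      m_exp = 0, b_collab_low = 0, b_collab_high = 0,
                      b_risk = 0, frailty_sd = 0)
  cfg <- sim_config(seed = 61, map_name = "Karakin", n_teams = 4,
                    team_size = 2, cap_s = 500, hazard = hz)
  winners <- integer(0)
  for (m in 1:600) {
    sm <- simulate_match(cfg, m)
    winners <- c(winners, which(sm$telemetry$final_ranks == 1L))
  }
  gof <- chisq.test(table(factor(winners, levels = 1:4)))
  expect_gt(gof$p.value, 0.01)
})

test_that("dominant negative curvature makes mid-share teams outrank extremes", {
  # propensity 6 s - 6 s^2: an inverted-U peaked at share 0.5, the planted
  # "too much of a good thing" in its purest form
  hz <- hazard_params(alpha = -3.6, b_high = 6, b_med = 0, b_low = 0,
                      q_high = -6, m_exp = 0, b_collab_low = 0,
                      b_collab_high = 0, b_risk = 0, frailty_sd = 0)
  cfg <- sim_config(seed = 62, map_name = "Karakin", n_matches = 40,
                    cap_s = 900, hazard = hz)
  coh <- simulate_cohort(cfg, reference_landings = 1000)
  beh <- behavior_features(coh$matches)
  tabs <- cohort_tables(coh$matches)
  d <- merge(beh, tabs$ranks)
  bin <- cut(d$share_high, c(-0.01, 0.25, 0.75, 1.01))
  mr <- tapply(d$final_rank, bin, mean)
  expect_lt(mr[2], mr[1])
  expect_lt(mr[2], mr[3])
})

test_that("cohort bookkeeping: truth rows, ranks, and outlier flag", {
  cfg <- sim_config(seed = 71, map_name = "Karakin", n_teams = 25,
                    n_matches = 3, cap_s = 600)
  coh <- simulate_cohort(cfg, reference_landings = 1000)
  expect_equal(nrow(coh$truth), 75)
  for (m in coh$matches) {
    expect_setequal(as.integer(m$final_ranks), 1:25)
  }
  # outlier injection marks teams whose member teleports across the map
  cfg2 <- sim_config(seed = 72, map_name = "Karakin", n_teams = 25,
                     n_matches = 2, cap_s = 600, outlier_team_rate = 0.1)
  coh2 <- simulate_cohort(cfg2, reference_landings = 1000)
  expect_gt(sum(coh2$truth$outlier_team), 0)
})
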