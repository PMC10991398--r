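make_prep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 81, map_name = "Karakin", n_teams = 25,
                        n_matches = 3, cap_s = 900)
      coh <- simulate_cohort(cfg, reference_landings = 5000)
      cache <<- list(coh = coh,
                     beh = behavior_features(coh$matches),
                     rsk = risk_features(coh$matches, coh$heatmap),
                     tabs = cohort_tables(coh$matches))
    }
    cache
  }
})

test_that("record assembly joins on team-match keys and averages experience", {
  p <- make_prep()
  rec <- assemble_records(p$beh, p$rsk, p$tabs$ranks, p$tabs$rosters)
  expect_equal(nrow(rec) + nrow(attr(rec, "excluded")), 75)
  # team experience is the mean of member rank points
  one <- rec[1, ]
  members <- p$tabs$rosters[p$tabs$rosters$match_id == one$match_id &
                              p$tabs$rosters$team_id == one$team_id, ]
  expect_equal(one$team_experience, mean(members$rank_points))
  # an orphaned key is reported by name
  expect_error(assemble_records(p$beh[-1, ], p$rsk, p$tabs$ranks,
                                p$tabs$rosters),
               p$beh$team_id[1])
})

test_that("Z-filter is single-pass with a full violation report", {
  d <- data.frame(x = c(rnorm(50), 100), y = rnorm(51))
  zf <- zscore_filter(d, c("x", "y"))
  expect_equal(nrow(zf$kept) + nrow(zf$dropped), nrow(d))
  expect_equal(zf$report$row, 51L)
  expect_equal(zf$report$variable, "x")
  # kept rows contain no |z| > 3 w.r.t. the ORIGINAL mean/sd
  z_orig <- abs((zf$kept$x - mean(d$x)) / sd(d$x))
  expect_true(all(z_orig <= 3))
  # identical values: skipped with a warning, nothing dropped
  d2 <- data.frame(x = rep(1, 10), y = rnorm(10))
  expect_warning(zf2 <- zscore_filter(d2, c("x", "y")), "zero-variance")
  expect_equal(nrow(zf2$dropped), 0L)
})

test_that("a planted coordinate-spike team is caught by the Z-filter", {
  # on the 8 km map a teleporting member sits far outside the scale of
  # legitimate team splits (a few hundred meters)
  cfg <- sim_config(seed = 82, n_teams = 25, n_matches = 4, cap_s = 900,
                    outlier_team_rate = 0.03)
  coh <- simulate_cohort(cfg, reference_landings = 5000)
  expect_gt(sum(coh$truth$outlier_team), 0)
  prep <- prepare_cohort(coh)
  dropped_keys <- paste(prep$dropped$match_id, prep$dropped$team_id)
  truth_keys <- paste(coh$truth$match_id, coh$truth$team_id)[
    coh$truth$outlier_team]
  expect_true(all(truth_keys %in% dropped_keys))
})

test_that("conjoint experience counts shared-teammate recurrence", {
  # fully disjoint rosters: zero everywhere
  r0 <- data.frame(match_id = rep(c("m1", "m2"), each = 4),
                   team_id = "t1",
                   player_id = sprintf("p%d", 1:8))
  expect_true(all(conjoint_experience(r0) == 0))
  # one intact 4-player team in two matches, 96 unique others per match
  r1 <- rbind(
    data.frame(match_id = "m1", team_id = "t1", player_id = sprintf("s%d", 1:4)),
    data.frame(match_id = "m2", team_id = "t9", player_id = sprintf("s%d", 1:4)),
    data.frame(match_id = "m1", team_id = "u", player_id = sprintf("u%d", 1:96)),
    data.frame(match_id = "m2", team_id = "v", player_id = sprintf("v%d", 1:96)))
  ce <- conjoint_experience(r1)
  expect_equal(unname(ce["quartet_pct"]), 4 / 196 * 100)
  expect_equal(unname(ce["overall_pct"]), 4 / 196 * 100)
  # inclusive ordering and brute-force oracle on a random cohort
  set.seed(14)
  rr <- do.call(rbind, lapply(1:6, function(m) {
    data.frame(match_id = paste0("m", m), team_id = rep(paste0("t", 1:5), each = 4),
               player_id = sample(sprintf("p%02d", 1:40), 20))
  }))
  ce2 <- conjoint_experience(rr)
  expect_gte(ce2["overall_pct"], max(ce2["dyad_pct"], ce2["triad_pct"],
                                     ce2["quartet_pct"]))
  # oracle: double loop over each player's team-match pairs
  key <- paste(rr$match_id, rr$team_id)
  oracle_counts <- c(0L, 0L, 0L)
  players <- unique(rr$player_id)
  for (p in players) {
    ks <- unique(key[rr$player_id == p])
    best <- 0L
    if (length(ks) >= 2) {
      for (a in 1:(length(ks) - 1)) for (b in (a + 1):length(ks)) {
        ma <- setdiff(rr$player_id[key == ks[a]], p)
        mb <- setdiff(rr$player_id[key == ks[b]], p)
        best <- max(best, length(intersect(ma, mb)))
      }
    }
    oracle_counts <- oracle_counts + (best >= 1:3)
  }
  expect_equal(unname(ce2[c("dyad_pct", "triad_pct", "quartet_pct")]),
               100 * oracle_counts / length(players))
})

test_that("match controls broadcast per-match means, order-invariantly", {
  p <- make_prep()
  rec <- assemble_records(p$beh, p$rsk, p$tabs$ranks, p$tabs$rosters)
  rec$risk_frac_high <- 0.5
  mc <- match_controls(rec, include_strategy = TRUE)
  # group-by oracle via independent loop
  for (mid in unique(mc$match_id)) {
    rows <- mc[mc$match_id == mid, ]
    expect_equal(unique(rows$mean_max_dist), mean(rows$collab_low))
    expect_equal(unique(rows$mean_sd_dist), mean(rows$sd_dist))
    expect_equal(unique(rows$match_mean_risk), mean(rows$time_high_risk_s))
  }
  # permutation of rows leaves controls untouched
  perm <- sample(nrow(rec))
  mc2 <- match_controls(rec[perm, ], include_strategy = TRUE)
  expect_equal(mc2$mean_max_dist, mc$mean_max_dist[perm])
})

test_that("strategy proxy buckets the high-risk time ratio", {
  expect_equal(strategy_proxy(0, 100), "exploration")
  expect_equal(strategy_proxy(100, 100), "exploitation")
  expect_equal(strategy_proxy(50, 100), "ambidexterity")
  expect_error(strategy_proxy(1, 0), "positive")
})

test_that("experience strata relabel k-means clusters by ascending center", {
  v <- rep(c(0, 5, 10), each = 3)
  st <- experience_strata(v, seed = 4)
  expect_equal(as.character(st$labels),
               rep(c("LOW", "MEDIUM", "HIGH"), each = 3))
  expect_equal(st$sizes, c(3L, 3L, 3L))
  expect_true(all(diff(st$centers) > 0))
  # labels invariant to input order at fixed seed
  set.seed(15)
  v2 <- c(rnorm(40, 0, 0.3), rnorm(30, 4, 0.3), rnorm(30, 9, 0.3))
  perm <- sample(100)
  s1 <- experience_strata(v2, seed = 4)
  s2 <- experience_strata(v2[perm], seed = 4)
  expect_equal(as.character(s2$labels), as.character(s1$labels)[perm])
  expect_error(experience_strata(c(1, 1, 1, 2), k = 3), "distinct")
  # strata partition the cohort
  expect_equal(sum(s1$sizes), 100L)
})
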