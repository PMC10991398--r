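## Cohort assembly: join features with ranks and experience, filter
## outliers, compute match-level controls and experience strata.

#' Ranks and rosters tables from telemetry
#'
#' @param matches A [match_telemetry()] or list of them.
#' @return List with `ranks` (`match_id`, `team_id`, `final_rank`) and
#'   `rosters` (`match_id`, `team_id`, `player_id`, `rank_points`).
#' @export
cohort_tables <- function(matches) {
  if (inherits(matches, "match_telemetry")) matches <- list(matches)
  ranks <- do.call(rbind, lapply(matches, function(m) {
    data.frame(match_id = m$meta$match_id, team_id = names(m$final_ranks),
               final_rank = as.integer(m$final_ranks),
               stringsAsFactors = FALSE)
  }))
  rosters <- do.call(rbind, lapply(matches, function(m) {
    st <- unique(m$states[, c("player_id", "team_id")])
    pr <- m$profiles
    data.frame(match_id = m$meta$match_id, team_id = st$team_id,
               player_id = st$player_id,
               rank_points = pr$rank_points[match(st$player_id,
                                                  pr$player_id)],
               stringsAsFactors = FALSE)
  }))
  list(ranks = ranks, rosters = rosters)
}

#' Assemble team-match records
#'
#' Inner-joins behavior features, risk features, final ranks, and team
#' experience (mean member rank points) on `(match_id, team_id)`. Key
#' mismatches raise an error naming the orphans; behavior rows with no
#' evaluable timepoint (`n_timepoints == 0`) are excluded and reported via
#' the `"excluded"` attribute.
#'
#' @param behavior Output of [behavior_features()].
#' @param risk Output of [risk_features()].
#' @param ranks Data frame `match_id`, `team_id`, `final_rank`.
#' @param rosters Data frame `match_id`, `team_id`, `player_id`,
#'   `rank_points`.
#' @return Data frame of team-match records.
#' @export
assemble_records <- function(behavior, risk, ranks, rosters) {
  key <- function(d) paste(d$match_id, d$team_id, sep = "\r")
  kb <- key(behavior); kr <- key(risk); kk <- key(ranks)
  orphans <- c(setdiff(kb, kr), setdiff(kr, kb), setdiff(kb, kk))
  if (length(orphans)) {
    stop("assemble_records: keys missing from some input(s): ",
         paste(utils::head(gsub("\r", "/", orphans), 5), collapse = ", "))
  }
  invalid <- behavior$n_timepoints == 0L | !is.finite(behavior$share_high)
  excluded <- behavior[invalid, c("match_id", "team_id")]
  behavior <- behavior[!invalid, , drop = FALSE]
  out <- merge(behavior, risk, by = c("match_id", "team_id"))
  out <- merge(out, ranks, by = c("match_id", "team_id"))
  texp <- stats::aggregate(rank_points ~ match_id + team_id, data = rosters,
                           FUN = mean)
  names(texp)[3] <- "team_experience"
  out <- merge(out, texp, by = c("match_id", "team_id"))
  out <- out[order(out$match_id, out$team_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Z-score outlier filter
#'
#' Drops any row whose value on any listed variable deviates from that
#' variable's mean by more than `z_max` standard deviations, with mean and
#' SD computed once on the input table (single pass, no re-estimation after
#' drops). Zero-variance variables are skipped with a warning.
#'
#' @param table Data frame.
#' @param variables Character vector of numeric columns to screen.
#' @param z_max Threshold in SD units (default 3).
#' @return List: `kept` (data frame), `dropped` (data frame), `report`
#'   (data frame `row`, `variable`, `z` for every violation).
#' @export
zscore_filter <- function(table, variables, z_max = 3) {
  if (nrow(table) < 2L) stop("zscore_filter: need >= 2 rows")
  drop <- rep(FALSE, nrow(table))
  rep_rows <- list()
  for (v in variables) {
    x <- table[[v]]
    if (is.null(x)) stop("zscore_filter: no such column: ", v)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning("zscore_filter: zero-variance variable skipped: ", v)
      next
    }
    z <- (x - mean(x)) / s
    bad <- abs(z) > z_max
    if (any(bad)) {
      rep_rows[[v]] <- data.frame(row = which(bad), variable = v,
                                  z = z[bad], stringsAsFactors = FALSE)
      drop <- drop | bad
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(row = integer(0), variable = character(0), z = numeric(0))
  rownames(report) <- NULL
  list(kept = table[!drop, , drop = FALSE],
       dropped = table[drop, , drop = FALSE],
       report = report)
}

#' Conjoint-experience percentages
#'
#' A player has conjoint experience when they appear in at least two
#' matches sharing at least one teammate between some pair of those
#' matches; dyadic/triadic/quartet conjoint experience requires at least
#' 1/2/3 shared teammates respectively (inclusive: a quartet player also
#' counts as dyadic and triadic). Percentages are over all distinct players
#' in the cohort.
#'
#' @param rosters Data frame `match_id`, `team_id`, `player_id`.
#' @return Named vector `overall_pct`, `dyad_pct`, `triad_pct`,
#'   `quartet_pct` (in percent).
#' @export
conjoint_experience <- function(rosters) {
  tm_key <- paste(rosters$match_id, rosters$team_id, sep = "\r")
  teams <- split(rosters$player_id, tm_key)
  by_player <- split(rep(names(teams), lengths(teams)), unlist(teams))
  players <- names(by_player)
  max_common <- vapply(players, function(p) {
    tms <- by_player[[p]]
    if (length(tms) < 2L) return(0L)
    mates <- lapply(teams[tms], setdiff, p)
    best <- 0L
    for (a in seq_len(length(mates) - 1L)) for (b in (a + 1L):length(mates)) {
      best <- max(best, length(intersect(mates[[a]], mates[[b]])))
    }
    best
  }, integer(1))
  n <- length(players)
  c(overall_pct = 100 * sum(max_common >= 1L) / n,
    dyad_pct = 100 * sum(max_common >= 1L) / n,
    triad_pct = 100 * sum(max_common >= 2L) / n,
    quartet_pct = 100 * sum(max_common >= 3L) / n)
}

#' Strategy proxy from overtime risk
#'
#' A coarse exploration/exploitation label from the fraction of evaluated
#' time a team's most risk-taking member spent in high-risk cells:
#' exploration below 1/3, exploitation above 2/3, ambidexterity between.
#' This is a documented proxy (the underlying strategy constructs have no
#' operational definition in telemetry) and is disabled by default in
#' [match_controls()].
#'
#' @param time_high_risk_s Time in high-risk cells (s), vectorized.
#' @param evaluated_time_s Total evaluated time (s), vectorized.
#' @return Character labels in
#'   `{"exploration", "ambidexterity", "exploitation"}`.
#' @export
strategy_proxy <- function(time_high_risk_s, evaluated_time_s) {
  if (any(evaluated_time_s <= 0)) stop("strategy_proxy: evaluated_time_s must be positive")
  r <- time_high_risk_s / evaluated_time_s
  ifelse(r < 1 / 3, "exploration",
         ifelse(r > 2 / 3, "exploitation", "ambidexterity"))
}

#' Match-level control variables
#'
#' Per match, the means over its teams of the dispersion and tightness
#' collaboration features (`mean_max_dist`, `mean_min_dist`), of the
#' per-team SD of normalized pair distances (`mean_sd_dist`), and of
#' overtime risk (`match_mean_risk`); optionally a strategy-mix score (mean
#' of exploration = -1 / ambidexterity = 0 / exploitation = +1 labels from
#' [strategy_proxy()]). All controls are broadcast back to team rows.
#'
#' @param records Assembled team-match records (must contain `collab_low`,
#'   `collab_high`, `sd_dist`, `time_high_risk_s`, `n_timepoints`).
#' @param include_strategy Add `match_strategy_mix` (default `FALSE`; the
#'   proxy is opt-in).
#' @return `records` with control columns appended.
#' @export
match_controls <- function(records, include_strategy = FALSE) {
  g <- records$match_id
  bc <- function(x) stats::ave(x, g, FUN = mean)
  records$mean_max_dist <- bc(records$collab_low)
  records$mean_min_dist <- bc(records$collab_high)
  records$mean_sd_dist <- bc(records$sd_dist)
  records$match_mean_risk <- bc(records$time_high_risk_s)
  if (include_strategy) {
    lab <- strategy_proxy(records$time_high_risk_s,
                          10 * records$n_timepoints)
    score <- c(exploration = -1, ambidexterity = 0, exploitation = 1)[lab]
    records$match_strategy_mix <- bc(unname(score))
  }
  records
}

#' K-means experience strata
#'
#' Clusters team experience into `k` strata with multiple restarts under a
#' fixed seed, then relabels clusters LOW/MEDIUM/HIGH by ascending center,
#' mirroring simple-slopes stratification on an experience moderator.
#'
#' @param values Numeric vector of team experience values.
#' @param k Number of strata (default 3).
#' @param seed RNG seed for the restarts.
#' @param nstart Number of random restarts (default 10).
#' @return List of class `stratum_assignment`: `centers` (ascending),
#'   `labels` (factor LOW/MEDIUM/HIGH per value), `sizes`, `seed`.
#' @export
experience_strata <- function(values, k = 3, seed = 1L, nstart = 10) {
  if (length(unique(values)) < k) {
    stop("experience_strata: need at least ", k, " distinct values")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  km <- stats::kmeans(matrix(values, ncol = 1), centers = k, nstart = nstart)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  ord <- order(km$centers)
  level_names <- if (k == 3) c("LOW", "MEDIUM", "HIGH") else
    paste0("S", seq_len(k))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- factor(level_names[relabel[km$cluster]], levels = level_names)
  structure(list(centers = as.numeric(km$centers[ord]),
                 labels = labels,
                 sizes = as.integer(table(labels)),
                 seed = seed),
            class = "stratum_assignment")
}

#' @export
print.stratum_assignment <- function(x, ...) {
  cat("<stratum_assignment>\n")
  print(data.frame(stratum = levels(x$labels), center = x$centers,
                   size = x$sizes))
  invisible(x)
}

#' Prepare an analysis cohort from simulated matches
#'
#' Convenience wrapper running the full preparation stage on a
#' [simulate_cohort()] result: feature extraction, record assembly,
#' match-level controls, Z-score outlier filtering on the behavior and risk
#' features, and K-means experience stratification.
#'
#' @param cohort Output of [simulate_cohort()] (list with `matches` and
#'   `heatmap`).
#' @param eps_cm Clustering epsilon (cm).
#' @param z_max Z-score threshold (3 disables nothing realistic, only
#'   spikes).
#' @param q_low,q_high Risk-category quantiles.
#' @param strata_seed Seed for [experience_strata()].
#' @param include_strategy Include the strategy-mix proxy control.
#' @return List: `records` (filtered, with `stratum` column), `dropped`,
#'   `filter_report`, `strata`, `behavior`, `risk`.
#' @export
prepare_cohort <- function(cohort, eps_cm = 10000, z_max = 3,
                           q_low = 0.5, q_high = 0.5, strata_seed = 1L,
                           include_strategy = FALSE) {
  beh <- behavior_features(cohort$matches, eps_cm = eps_cm)
  rsk <- risk_features(cohort$matches, cohort$heatmap,
                       q_low = q_low, q_high = q_high)
  tabs <- cohort_tables(cohort$matches)
  rec <- assemble_records(beh, rsk, tabs$ranks, tabs$rosters)
  ## overtime risk as a mix rather than raw seconds: high- plus low-risk
  ## seconds track a team's survival time, which within a match is the rank
  ## itself; the high-risk share of that time is the risk signal
  tot <- rec$time_high_risk_s + rec$time_low_risk_s
  rec$risk_frac_high <- ifelse(tot > 0, rec$time_high_risk_s / tot, 0)
  rec$risk_frac_low <- 1 - rec$risk_frac_high
  rec <- match_controls(rec, include_strategy = include_strategy)
  screen <- c("share_high", "share_med", "share_low", "collab_high",
              "collab_low", "sd_dist", "landing_risk_high",
              "landing_risk_low", "time_high_risk_s", "time_low_risk_s",
              "team_experience")
  zf <- zscore_filter(rec, screen, z_max = z_max)
  rec <- zf$kept
  strata <- experience_strata(rec$team_experience, seed = strata_seed)
  rec$stratum <- strata$labels
  list(records = rec, dropped = zf$dropped, filter_report = zf$report,
       strata = strata, behavior = beh, risk = rsk)
}
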