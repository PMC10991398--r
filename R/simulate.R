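## Agent-based squad battle-royale simulator.
##
## Teams parachute onto a square map (landing anchors drawn from a hotspot
## mixture with per-team risk preference), then follow a reflected random
## walk biased to stay inside the shrinking play circle, with members
## scattered around the team centroid. Whole teams are eliminated by a
## per-10 s logistic hazard driven by their running behavior features, so
## the final ranking carries a planted, experience-moderated curvilinear
## dependence on behavioral interdependence that the downstream pipeline can
## try to recover.

#' Planted hazard parameters
#'
#' Coefficients of the team performance propensity
#' \deqn{\pi = b_{high} s_H + b_{med} s_M + b_{low} s_L +
#'   (q_{high} + m_{exp} z) s_H^2 + b^{cl} c_{low} + b^{ch} c_{high} +
#'   b^{risk} r}
#' where \eqn{s_H, s_M, s_L} are the running interdependence shares,
#' \eqn{c_{low}, c_{high}} the running collaboration features, \eqn{r} the
#' running fraction of time in high-risk cells, and \eqn{z} the team's
#' standardized experience. Each alive team is eliminated in a 10 s interval
#' with probability \eqn{\mathrm{logit}^{-1}(\alpha - \pi)}: higher
#' propensity means longer survival and a better (lower) final rank, so a
#' negative \eqn{q_{high}} plants an inverted-U of performance in the
#' high-interdependence share, and a positive \eqn{m_{exp}} flattens that
#' curvature for experienced teams.
#'
#' @param alpha Baseline per-interval elimination log-odds.
#' @param b_high,b_med,b_low Linear propensity coefficients on the
#'   HIGH/MEDIUM/LOW interdependence shares.
#' @param q_high Quadratic propensity coefficient on the HIGH share.
#' @param m_exp Moderation: the effective curvature is
#'   `q_high + m_exp * z` with `z` the standardized team experience. The
#'   default cancels the curvature near the high-experience stratum of the
#'   default experience mixture.
#' @param b_collab_low,b_collab_high Coefficients on the collaboration
#'   features (centered internally at `collab_center`).
#' @param b_risk Coefficient on the fraction of elapsed time the most
#'   risk-taking member has spent in high-risk cells.
#' @param frailty_sd SD of a per-team Gaussian propensity intercept
#'   (unobserved skill heterogeneity; dilutes the feature-rank coupling to
#'   realistic explanatory power).
#' @param endgame_ramp Additive increase of the baseline elimination
#'   log-odds, ramped linearly from `ramp_start_s` to the match cap: the
#'   closing circle forces combat, so matches resolve instead of timing
#'   out with a field of survivors.
#' @param ramp_start_s Time at which the endgame ramp begins.
#' @param collab_center Centering constants `c(low, high)` for the
#'   collaboration features inside the hazard.
#' @return A list of class `hazard_params`.
#' @export
hazard_params <- function(alpha = -4.1,
                          b_high = 2.4, b_med = 0.25, b_low = -0.5,
                          q_high = -2.6, m_exp = 1.611,
                          b_collab_low = 0.15, b_collab_high = 0.10,
                          b_risk = -0.3, frailty_sd = 0,
                          endgame_ramp = 4, ramp_start_s = 1100,
                          collab_center = c(8, 6)) {
  p <- list(alpha = alpha, b_high = b_high, b_med = b_med, b_low = b_low,
            q_high = q_high, m_exp = m_exp, b_collab_low = b_collab_low,
            b_collab_high = b_collab_high, b_risk = b_risk,
            frailty_sd = frailty_sd, endgame_ramp = endgame_ramp,
            ramp_start_s = ramp_start_s, collab_center = collab_center)
  if (!all(vapply(p, function(x) all(is.finite(x)), logical(1)))) {
    stop("hazard_params: all coefficients must be finite")
  }
  class(p) <- "hazard_params"
  p
}

#' Default season-experience mixture
#'
#' Team mean experience is drawn from a three-component Gaussian mixture
#' whose component means and weights mirror the experience strata of large
#' ranked-squad cohorts (means 0.013 / 3.358 / 4.914, weights roughly
#' 61/22/17%); values are truncated at zero.
#'
#' @return List with `means`, `sds`, `weights`, and the implied overall
#'   `mean` and `sd` used to standardize experience in the hazard.
#' @export
experience_mixture <- function() {
  means <- c(0.013, 3.358, 4.914)
  sds <- c(0.2, 0.3, 0.4)
  w <- c(85388, 30645, 24666)
  w <- w / sum(w)
  mu <- sum(w * means)
  v <- sum(w * (means^2 + sds^2)) - mu^2
  list(means = means, sds = sds, weights = w, mean = mu, sd = sqrt(v))
}

#' Simulation configuration
#'
#' Study-condition defaults: 100 players in 25 teams of 4, 10 s location
#' sampling, hotspot-concentrated landings, a shrinking play circle, and the
#' planted hazard of [hazard_params()]. Per-team inputs
#' (`landing_risk_preference`, `cohesion_sigma_cm`, `experience_mean`) may be
#' a scalar, a length-`n_teams` vector, or `NULL` to draw fresh values per
#' match (risk preference uniform on `[0,1]`; cohesion log-uniform on
#' `[2e3, 2e5]` cm so interdependence spans LOW to HIGH; experience from
#' [experience_mixture()]).
#'
#' @param seed Integer RNG seed.
#' @param map_name Map (default `"Erangel"`).
#' @param n_teams,team_size Cohort shape (defaults 25 x 4).
#' @param n_matches Number of matches to simulate.
#' @param hotspot_centers Matrix of hotspot centers (cm); `NULL` for five
#'   fixed hotspots at characteristic map fractions.
#' @param hotspot_weights Mixture weights over hotspots.
#' @param hotspot_sigma_cm Scatter of landing anchors around a hotspot.
#' @param landing_risk_preference Per-team probability of targeting a
#'   hotspot rather than a uniform spot.
#' @param cohesion_sigma_cm Per-team member dispersion around the centroid
#'   in the together regime.
#' @param p_together Per-team stationary fraction of time in the together
#'   regime (`NULL`: uniform on `[0.05, 0.95]`; set 1 for always-clustered
#'   squads).
#' @param split_dist_cm Per-team separation scale of split episodes
#'   (`NULL`: uniform on 1.5-5x `eps_cm`).
#' @param split_dwell Mean split-episode length in 10 s steps (default 3,
#'   i.e. squads regroup after about half a minute apart).
#' @param step_sigma_cm Centroid random-walk step SD per 10 s.
#' @param experience_mean Per-team mean rank points.
#' @param experience_sd Within-team SD of member rank points.
#' @param hazard A [hazard_params()] object.
#' @param cap_s Match duration cap (s).
#' @param outlier_team_rate Probability that a team gets one "hacker"
#'   member whose coordinates teleport across the map (for testing the
#'   Z-score filter); 0 by default.
#' @param eps_cm,cell_cm,norm_floor Feature-extraction constants used for
#'   the running hazard features (match the analysis defaults).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       map_name = "Erangel",
                       n_teams = 25L, team_size = 4L, n_matches = 1L,
                       hotspot_centers = NULL, hotspot_weights = NULL,
                       hotspot_sigma_cm = 5000,
                       landing_risk_preference = NULL,
                       cohesion_sigma_cm = NULL,
                       p_together = NULL,
                       split_dist_cm = NULL,
                       split_dwell = 3,
                       step_sigma_cm = 6000,
                       experience_mean = NULL, experience_sd = 0.3,
                       hazard = hazard_params(),
                       cap_s = 1800,
                       outlier_team_rate = 0,
                       eps_cm = 10000, cell_cm = 1000, norm_floor = 0.1) {
  side <- map_side_cm(map_name)
  if (is.null(hotspot_centers)) {
    fr <- rbind(c(0.25, 0.25), c(0.70, 0.30), c(0.50, 0.60),
                c(0.30, 0.75), c(0.80, 0.80))
    hotspot_centers <- fr * side
    if (is.null(hotspot_weights)) hotspot_weights <- c(3, 2, 2, 1, 1)
  }
  hotspot_weights <- hotspot_weights / sum(hotspot_weights)
  stopifnot(all(hotspot_weights >= 0), n_teams >= 2, team_size >= 1,
            n_matches >= 1, hotspot_sigma_cm > 0, step_sigma_cm > 0,
            experience_sd >= 0)
  chk_per_team <- function(x, nm, lo = -Inf, hi = Inf) {
    if (!is.null(x)) {
      if (!length(x) %in% c(1L, n_teams)) {
        stop("sim_config: ", nm, " must be NULL, scalar, or length n_teams")
      }
      if (any(x < lo | x > hi)) stop("sim_config: ", nm, " out of range")
    }
    x
  }
  cfg <- list(
    seed = as.integer(seed), map_name = map_name, map_side_cm = side,
    n_teams = as.integer(n_teams), team_size = as.integer(team_size),
    n_matches = as.integer(n_matches),
    hotspot_centers = hotspot_centers, hotspot_weights = hotspot_weights,
    hotspot_sigma_cm = hotspot_sigma_cm,
    landing_risk_preference = chk_per_team(landing_risk_preference,
                                           "landing_risk_preference", 0, 1),
    cohesion_sigma_cm = chk_per_team(cohesion_sigma_cm, "cohesion_sigma_cm",
                                     0),
    p_together = chk_per_team(p_together, "p_together", 0, 1),
    split_dist_cm = chk_per_team(split_dist_cm, "split_dist_cm", 0),
    split_dwell = split_dwell,
    step_sigma_cm = step_sigma_cm,
    experience_mean = chk_per_team(experience_mean, "experience_mean", 0),
    experience_sd = experience_sd,
    hazard = hazard, cap_s = cap_s,
    outlier_team_rate = outlier_team_rate,
    eps_cm = eps_cm, cell_cm = cell_cm, norm_floor = norm_floor,
    exp_mix = experience_mixture())
  class(cfg) <- "sim_config"
  cfg
}

## Draw per-team parameters for one match (uses the current RNG stream).
.draw_team_params <- function(config) {
  nt <- config$n_teams
  take <- function(x, draw) if (is.null(x)) draw else rep_len(x, nt)
  mix <- config$exp_mix
  comp <- sample.int(3L, nt, replace = TRUE, prob = mix$weights)
  list(
    risk_pref = take(config$landing_risk_preference, stats::runif(nt)),
    cohesion = take(config$cohesion_sigma_cm,
                    exp(stats::runif(nt, log(1e3), log(2e4)))),
    p_together = take(config$p_together, stats::runif(nt, 0.05, 0.80)),
    split_dist = take(config$split_dist_cm,
                      stats::runif(nt, 1.5, 5) * config$eps_cm),
    exp_mean = take(config$experience_mean,
                    pmax(0, stats::rnorm(nt, mix$means[comp],
                                         mix$sds[comp]))))
}

#' Simulate parachute landings for one match
#'
#' Each team draws a landing anchor: with probability equal to its landing
#' risk preference the anchor comes from the hotspot mixture (hotspot chosen
#' by weight, Gaussian scatter `hotspot_sigma_cm`), otherwise it is uniform
#' over the map. Members land at the anchor plus Gaussian `cohesion_sigma_cm`
#' offsets, clipped to the map.
#'
#' @param config A [sim_config()].
#' @param team_params Per-team parameters (internal; drawn from `config`
#'   when `NULL`). Uses the current RNG stream; call `set.seed()` or go
#'   through [simulate_match()] for reproducibility.
#' @return List with `landings` (data frame `player_id`, `team_id`, `x_cm`,
#'   `y_cm`, `t_s`) and `anchors` (n_teams x 2 matrix).
#' @export
simulate_landings <- function(config, team_params = NULL) {
  if (is.null(team_params)) team_params <- .draw_team_params(config)
  nt <- config$n_teams; ts <- config$team_size; side <- config$map_side_cm
  use_hot <- stats::runif(nt) < team_params$risk_pref
  anchors <- matrix(stats::runif(2 * nt, 0, side), nt, 2)
  if (any(use_hot)) {
    k <- sum(use_hot)
    h <- sample.int(nrow(config$hotspot_centers), k, replace = TRUE,
                    prob = config$hotspot_weights)
    anchors[use_hot, ] <- config$hotspot_centers[h, , drop = FALSE] +
      matrix(stats::rnorm(2 * k, 0, config$hotspot_sigma_cm), k, 2)
  }
  anchors <- pmin(pmax(anchors, 0), side)
  team_id <- rep(sprintf("t%02d", seq_len(nt)), each = ts)
  player_id <- sprintf("%s-p%d", team_id, rep(seq_len(ts), nt))
  x <- rep(anchors[, 1], each = ts) +
    stats::rnorm(nt * ts, 0, rep(team_params$cohesion, each = ts))
  y <- rep(anchors[, 2], each = ts) +
    stats::rnorm(nt * ts, 0, rep(team_params$cohesion, each = ts))
  list(landings = data.frame(player_id = player_id, team_id = team_id,
                             x_cm = pmin(pmax(x, 0), side),
                             y_cm = pmin(pmax(y, 0), side),
                             t_s = 0, stringsAsFactors = FALSE),
       anchors = anchors)
}

## Reflect coordinates into [0, side].
.reflect <- function(x, side) {
  x <- abs(x)
  side - abs(side - x %% (2 * side))
}

## Persistent two-state regime chain per team: 1 = together, 0 = split.
## Stationary together-probability p_tog; split episodes last ~dwell steps.
.simulate_regimes <- function(p_tog, nT, dwell = 6) {
  nt <- length(p_tog)
  stay_split <- 1 - 1 / dwell
  ## stationary p_tog = (1-b)/(2-a-b) with a = P(stay tog), b = stay_split
  leave_tog <- pmin(0.999, (1 - stay_split) * (1 - p_tog) / pmax(p_tog, 1e-6))
  R <- matrix(NA_integer_, nt, nT)
  R[, 1] <- as.integer(stats::runif(nt) < p_tog)
  for (k in 2:nT) {
    u <- stats::runif(nt)
    stay <- ifelse(R[, k - 1] == 1L, 1 - leave_tog, 1 - (1 - stay_split))
    R[, k] <- ifelse(u < stay, R[, k - 1], 1L - R[, k - 1])
  }
  R
}

#' Simulate team trajectories for one match
#'
#' Team centroids perform a Gaussian random walk (`step_sigma_cm` per 10 s)
#' reflected at the map edges and projected back inside 90% of the current
#' play-circle radius whenever they stray outside it. Around the centroid,
#' squads alternate between a *together* regime (members = centroid plus
#' independent Gaussian offsets of SD `cohesion_sigma_cm`, truncated at 3
#' sigma, resampled each step) and persistent *split* episodes in which the
#' team either breaks into two tight pairs separated by the team's split
#' distance or scatters every member independently at that scale. The
#' per-team stationary together-fraction (`p_together`) and split distance
#' are drawn independently of the cohesion sigma, so how often a squad
#' clusters and how tight it is when clustered vary separately, as they do
#' in real squads. All positions are clipped to the map.
#'
#' @param config A [sim_config()].
#' @param anchors n_teams x 2 matrix of landing anchors.
#' @param schedule A [shrink_schedule()] for the map.
#' @param team_params Per-team parameters (internal).
#' @return List with arrays `X`, `Y` of dim `(team_size, n_teams, n_steps)`
#'   and the time grid `t_s` (0, 10, ..., cap).
#' @export
simulate_trajectories <- function(config, anchors, schedule,
                                  team_params = NULL) {
  if (is.null(team_params)) team_params <- .draw_team_params(config)
  nt <- config$n_teams; ts <- config$team_size; side <- config$map_side_cm
  tgrid <- seq(0, config$cap_s, by = 10)
  nT <- length(tgrid)
  ctr <- c(side / 2, side / 2)
  radius <- shrink_radius(tgrid, schedule)
  cx <- matrix(NA_real_, nt, nT); cy <- cx
  cx[, 1] <- anchors[, 1]; cy[, 1] <- anchors[, 2]
  for (k in 2:nT) {
    nx <- .reflect(cx[, k - 1] + stats::rnorm(nt, 0, config$step_sigma_cm), side)
    ny <- .reflect(cy[, k - 1] + stats::rnorm(nt, 0, config$step_sigma_cm), side)
    dx <- nx - ctr[1]; dy <- ny - ctr[2]
    d <- sqrt(dx^2 + dy^2)
    lim <- 0.9 * radius[k]
    out <- d > lim & d > 0
    if (any(out)) {
      f <- lim / d[out]
      nx[out] <- ctr[1] + dx[out] * f
      ny[out] <- ctr[2] + dy[out] * f
    }
    cx[, k] <- nx; cy[, k] <- ny
  }
  ## regimes: together vs split; split episodes are pair-splits or scatters
  tog <- .simulate_regimes(team_params$p_together, nT, config$split_dwell)
  pair_split <- matrix(stats::runif(nt * nT) < 0.5, nt, nT)  # else scatter
  clip3 <- function(z) pmin(pmax(z, -3), 3)
  np <- nt * ts
  sig <- rep(team_params$cohesion, each = ts)
  ## together-regime offsets
  tx <- clip3(matrix(stats::rnorm(np * nT), np, nT)) * sig
  ty <- clip3(matrix(stats::rnorm(np * nT), np, nT)) * sig
  ## pair-split: members 1,2 at +u d/2, members 3,4 at -u d/2, tight pairs
  phi <- matrix(stats::runif(nt * nT, 0, 2 * pi), nt, nT)
  half_d <- rep(team_params$split_dist, each = ts) / 2
  pair_sign <- rep(rep(c(1, -1), each = ceiling(ts / 2))[seq_len(ts)], nt)
  sig_pair <- pmin(sig, config$eps_cm / 4)
  px <- pair_sign * half_d * cos(phi)[rep(seq_len(nt), each = ts), ] +
    clip3(matrix(stats::rnorm(np * nT), np, nT)) * sig_pair
  py <- pair_sign * half_d * sin(phi)[rep(seq_len(nt), each = ts), ] +
    clip3(matrix(stats::rnorm(np * nT), np, nT)) * sig_pair
  ## scatter: each member independently at 0.75-2.5x the split distance
  ang <- matrix(stats::runif(np * nT, 0, 2 * pi), np, nT)
  dist <- matrix(stats::runif(np * nT, 0.75, 2.5), np, nT) *
    rep(team_params$split_dist, each = ts)
  sx <- dist * cos(ang); sy <- dist * sin(ang)
  ## select offsets by regime
  tog_p <- tog[rep(seq_len(nt), each = ts), , drop = FALSE]
  pair_p <- pair_split[rep(seq_len(nt), each = ts), , drop = FALSE]
  offx <- ifelse(tog_p == 1L, tx, ifelse(pair_p, px, sx))
  offy <- ifelse(tog_p == 1L, ty, ifelse(pair_p, py, sy))
  X <- array(NA_real_, c(ts, nt, nT)); Y <- X
  for (k in seq_len(nT)) {
    X[, , k] <- pmin(pmax(rep(cx[, k], each = ts) + offx[, k], 0), side)
    Y[, , k] <- pmin(pmax(rep(cy[, k], each = ts) + offy[, k], 0), side)
  }
  list(X = X, Y = Y, t_s = tgrid, regimes = tog)
}

## Running (cumulative) hazard features for every team and timepoint.
## Returns matrices [n_teams x nT]: share_high/med/low, collab_low/high,
## risk_frac, all cumulative means over evaluated timepoints up to t.
.running_features <- function(config, X, Y, tgrid, duration_s, heatmap,
                              cutoff, schedule = NULL) {
  nt <- config$n_teams; ts <- config$team_size; nT <- length(tgrid)
  state_mask <- if (is.null(schedule)) NULL else
    shrink_radius(tgrid, schedule) >= 3 * config$eps_cm
  sh <- sm <- sl <- cl <- ch <- rf <- matrix(0, nt, nT)
  for (i in seq_len(nt)) {
    Xi <- matrix(X[, i, ], ts, nT); Yi <- matrix(Y[, i, ], ts, nT)
    A <- matrix(TRUE, ts, nT)
    pt <- .per_timepoint_behavior(Xi, Yi, A, tgrid, config$eps_cm,
                                  duration_s, config$norm_floor,
                                  state_mask = state_mask)
    ne <- cumsum(pt$state_eval)
    ne1 <- pmax(ne, 1L)
    nev <- pmax(cumsum(pt$eval), 1L)
    sh[i, ] <- cumsum(ifelse(pt$state_eval & pt$state == 1L, 1, 0)) / ne1
    sm[i, ] <- cumsum(ifelse(pt$state_eval & pt$state == 2L, 1, 0)) / ne1
    sl[i, ] <- cumsum(ifelse(pt$state_eval & pt$state == 3L, 1, 0)) / ne1
    cl[i, ] <- cumsum(ifelse(pt$eval, pt$nd_max, 0)) / nev
    ch[i, ] <- cumsum(ifelse(pt$eval, pt$nd_min, 0)) / nev
    if (!is.null(heatmap)) {
      ij <- cell_index(as.vector(Xi), as.vector(Yi), heatmap$cell_cm,
                       heatmap$n_cells)
      hi <- matrix(heatmap$counts[cbind(ij[, 1] + 1L, ij[, 2] + 1L)] > cutoff,
                   ts, nT)
      cum_hi <- t(apply(hi, 1, cumsum))              # per member
      rf[i, ] <- apply(cum_hi, 2, max) / seq_len(nT) # most risk-taking member
    }
  }
  list(share_high = sh, share_med = sm, share_low = sl,
       collab_low = cl, collab_high = ch, risk_frac = rf)
}

#' Simulate team eliminations for one match
#'
#' Per 10 s interval, each alive team is eliminated with probability
#' `plogis(alpha - propensity)` where the propensity combines the team's
#' running features and planted coefficients (see [hazard_params()]).
#' Ranks are assigned in reverse elimination order (last team alive wins);
#' simultaneous eliminations are broken by team id order, and teams still
#' alive at the cap are ranked by their final hazard, ascending. No team is
#' eliminated during the initial exploration hold (the landing/looting
#' phase), which also guarantees every team a minimum feature-evaluation
#' window.
#'
#' @param config A [sim_config()].
#' @param feats Running-feature matrices (internal, from the trajectory
#'   stage).
#' @param z_exp Standardized team experience vector (length n_teams).
#' @param tgrid Time grid of the match.
#' @param hazard_start_s Time before which no eliminations occur (default
#'   300 s, the initial hold).
#' @return List: `rank` (named integer vector by team id), `t_elim` (NA for
#'   teams alive at match end), `hazard_final`.
#' @export
simulate_eliminations <- function(config, feats, z_exp, tgrid,
                                  hazard_start_s = 300, frailty = NULL) {
  hz <- config$hazard
  nt <- config$n_teams
  nT <- length(tgrid)
  team_ids <- sprintf("t%02d", seq_len(nt))
  if (is.null(frailty)) frailty <- rep(0, nt)
  q_eff <- hz$q_high + hz$m_exp * z_exp
  alive <- rep(TRUE, nt)
  t_elim <- rep(NA_real_, nt)
  elim_order <- character(0)
  p_last <- rep(stats::plogis(hz$alpha), nt)
  k_start <- max(2L, sum(tgrid <= hazard_start_s) + 1L)
  cap <- max(tgrid)
  ramp <- if (cap > hz$ramp_start_s) {
    hz$endgame_ramp * pmax(0, (tgrid - hz$ramp_start_s) /
                                (cap - hz$ramp_start_s))
  } else rep(0, nT)
  for (k in k_start:nT) {
    prop <- hz$b_high * feats$share_high[, k] +
      hz$b_med * feats$share_med[, k] +
      hz$b_low * feats$share_low[, k] +
      q_eff * feats$share_high[, k]^2 +
      hz$b_collab_low * (feats$collab_low[, k] - hz$collab_center[1]) +
      hz$b_collab_high * (feats$collab_high[, k] - hz$collab_center[2]) +
      hz$b_risk * feats$risk_frac[, k] + frailty
    p <- stats::plogis(hz$alpha + ramp[k] - prop)
    p_last[alive] <- p[alive]
    u <- stats::runif(nt)
    hit <- which(alive & u < p)
    if (length(hit)) {
      hit <- hit[order(team_ids[hit])]  # tie-break by team id
      for (i in hit) {
        if (sum(alive) <= 1L) break
        alive[i] <- FALSE
        t_elim[i] <- tgrid[k]
        elim_order <- c(elim_order, team_ids[i])
      }
    }
    if (sum(alive) <= 1L) break
  }
  rank <- rep(NA_integer_, nt); names(rank) <- team_ids
  ne <- length(elim_order)
  if (ne) rank[elim_order] <- nt - seq_len(ne) + 1L
  surv <- which(alive)
  ## exact hazard ties among cap survivors break at random, not by row order
  rank[surv[order(p_last[surv], stats::runif(length(surv)))]] <-
    seq_along(surv)
  list(rank = rank, t_elim = setNames(t_elim, team_ids),
       hazard_final = setNames(p_last, team_ids))
}

#' Simulate one full match
#'
#' Runs landings, trajectories, running features, and eliminations, then
#' assembles a validated [match_telemetry()] (location records truncate at
#' team elimination, with the death-time record flagged `alive = FALSE`)
#' and a ground-truth row per team.
#'
#' @param config A [sim_config()].
#' @param match_idx Index of the match within the cohort (enters the match
#'   id).
#' @param heatmap Optional reference [build_heatmap()] for the running risk
#'   feature (when `NULL` the risk term of the hazard is inert).
#' @param seed Optional seed set before simulation (defaults to a value
#'   derived from `config$seed` and `match_idx`).
#' @return List with `telemetry` ([match_telemetry()]) and `truth`
#'   (data frame of per-team planted parameters).
#' @export
simulate_match <- function(config, match_idx = 1L, heatmap = NULL,
                           seed = NULL) {
  if (is.null(seed)) {
    seed <- (as.numeric(config$seed) * 1000003 + match_idx * 7919) %%
      2147483629
  }
  set.seed(as.integer(seed))
  nt <- config$n_teams; ts <- config$team_size
  match_id <- sprintf("m%d-%04d", config$seed, match_idx)
  team_ids <- sprintf("t%02d", seq_len(nt))
  schedule <- shrink_schedule(config$map_side_cm, cap_s = config$cap_s)
  tp <- .draw_team_params(config)
  land <- simulate_landings(config, tp)
  traj <- simulate_trajectories(config, land$anchors, schedule, tp)
  ## pin the t = 0 sample to the landing positions
  traj$X[, , 1] <- matrix(land$landings$x_cm, ts, nt)
  traj$Y[, , 1] <- matrix(land$landings$y_cm, ts, nt)

  ## optional "hacker" outlier: one member teleports across the map
  outlier_team <- rep(FALSE, nt)
  if (config$outlier_team_rate > 0) {
    outlier_team <- stats::runif(nt) < config$outlier_team_rate
    for (i in which(outlier_team)) {
      nT <- length(traj$t_s)
      traj$X[1, i, ] <- stats::runif(nT, 0, config$map_side_cm)
      traj$Y[1, i, ] <- stats::runif(nT, 0, config$map_side_cm)
    }
  }

  ## experience: member rank points around the team mean
  rank_points <- pmax(0, stats::rnorm(nt * ts, rep(tp$exp_mean, each = ts),
                                      config$experience_sd))
  team_exp <- colMeans(matrix(rank_points, ts, nt))
  z_exp <- (team_exp - config$exp_mix$mean) / config$exp_mix$sd

  cutoff <- if (!is.null(heatmap)) risk_cell_threshold(heatmap) else NA
  feats <- .running_features(config, traj$X, traj$Y, traj$t_s, config$cap_s,
                             heatmap, cutoff, schedule = schedule)
  frailty <- stats::rnorm(nt, 0, config$hazard$frailty_sd)
  el <- simulate_eliminations(config, feats, z_exp, traj$t_s,
                              frailty = frailty)

  duration <- if (all(is.na(el$t_elim))) config$cap_s else
    min(config$cap_s, max(el$t_elim, na.rm = TRUE))

  ## assemble truncated states: records stop at team elimination
  nT <- length(traj$t_s)
  keep_T <- sum(traj$t_s <= duration)
  states <- vector("list", nt)
  player_ids <- sprintf("%s-p%d", rep(team_ids, each = ts),
                        rep(seq_len(ts), nt))
  for (i in seq_len(nt)) {
    te <- el$t_elim[i]
    kT <- if (is.na(te)) keep_T else sum(traj$t_s <= te)
    tt <- traj$t_s[seq_len(kT)]
    alive <- rep(TRUE, kT)
    if (!is.na(te)) alive[kT] <- FALSE
    states[[i]] <- data.frame(
      player_id = rep(player_ids[(i - 1L) * ts + seq_len(ts)], each = kT),
      team_id = team_ids[i],
      t_s = rep(tt, ts),
      x_cm = as.vector(t(matrix(traj$X[, i, seq_len(kT)], ts, kT))),
      y_cm = as.vector(t(matrix(traj$Y[, i, seq_len(kT)], ts, kT))),
      alive = rep(alive, ts),
      stringsAsFactors = FALSE)
  }
  states <- do.call(rbind, states)

  meta <- list(match_id = match_id, map_name = config$map_name,
               map_side_cm = config$map_side_cm, n_players = nt * ts,
               team_size = ts, duration_s = duration)
  profiles <- data.frame(player_id = player_ids, rank_points = rank_points,
                         stringsAsFactors = FALSE)
  tel <- match_telemetry(meta = meta, states = states,
                         landings = land$landings, profiles = profiles,
                         final_ranks = el$rank)
  truth <- data.frame(
    match_id = match_id, team_id = team_ids,
    cohesion_sigma_cm = tp$cohesion,
    p_together = tp$p_together,
    split_dist_cm = tp$split_dist,
    landing_risk_preference = tp$risk_pref,
    experience_mean = tp$exp_mean,
    team_experience = team_exp,
    z_exp = z_exp,
    q_eff = config$hazard$q_high + config$hazard$m_exp * z_exp,
    frailty = frailty,
    outlier_team = outlier_team,
    final_rank = as.integer(el$rank[team_ids]),
    stringsAsFactors = FALSE)
  list(telemetry = tel, truth = truth)
}

#' Simulate reference landings for the risk heatmap
#'
#' Draws landing events only (no trajectories or eliminations) for a
#' held-out cohort, mirroring the construction of landing-risk heatmaps
#' from a large reference sample of players.
#'
#' @param config A [sim_config()].
#' @param n_players Number of reference landings (default 50000).
#' @param seed Seed (default derived from `config$seed`).
#' @return Data frame of landings.
#' @export
simulate_reference_landings <- function(config, n_players = 50000,
                                        seed = NULL) {
  if (is.null(seed)) seed <- (as.numeric(config$seed) * 1000003 + 999983) %%
      2147483629
  set.seed(as.integer(seed))
  n_matches <- ceiling(n_players / (config$n_teams * config$team_size))
  out <- vector("list", n_matches)
  for (m in seq_len(n_matches)) {
    out[[m]] <- simulate_landings(config)$landings
  }
  out <- do.call(rbind, out)
  out[seq_len(min(n_players, nrow(out))), , drop = FALSE]
}

#' Simulate a cohort of matches
#'
#' Generates `n_matches` telemetry objects plus the per-team ground-truth
#' table, after building a held-out reference heatmap that drives the
#' running risk feature of the hazard. Optionally writes each match as a
#' JSON-Lines file and the ground truth as CSV.
#'
#' @param config A [sim_config()] (its `n_matches` is used).
#' @param out_dir Optional directory; when given, writes
#'   `telemetry/<match_id>.jsonl` files and `ground_truth.csv`.
#' @param reference_landings Number of held-out landings for the heatmap.
#' @return List: `matches` (list of [match_telemetry()]), `truth`
#'   (data frame), `heatmap` (the reference [build_heatmap()]).
#' @export
simulate_cohort <- function(config, out_dir = NULL,
                            reference_landings = 50000) {
  ref <- simulate_reference_landings(config, reference_landings)
  heatmap <- build_heatmap(ref, config$map_name, config$cell_cm)
  matches <- vector("list", config$n_matches)
  truth <- vector("list", config$n_matches)
  for (m in seq_len(config$n_matches)) {
    sm <- simulate_match(config, m, heatmap)
    matches[[m]] <- sm$telemetry
    truth[[m]] <- sm$truth
  }
  truth <- do.call(rbind, truth)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "telemetry"), recursive = TRUE,
               showWarnings = FALSE)
    for (m in matches) {
      write_telemetry(m, file.path(out_dir, "telemetry",
                                   paste0(m$meta$match_id, ".jsonl")))
    }
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  list(matches = matches, truth = truth, heatmap = heatmap)
}
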