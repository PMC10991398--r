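## Team behavioral-interdependence and collaboration features.
##
## A team's spatial state at a sampled timepoint is classified from the
## epsilon-graph over its alive members (edges join members within eps_cm):
##   HIGH   - one connected component (everyone clustered together)
##   LOW    - every alive member its own component
##   MEDIUM - anything in between
## With min_pts = 1, DBSCAN on a handful of points is exactly connected
## components of that graph: no point can be noise.

#' Team centroid
#'
#' Arithmetic mean of member coordinates.
#'
#' @param points Numeric matrix with one row per member and two columns (x, y).
#' @return Length-2 numeric vector (x, y).
#' @export
team_centroid <- function(points) {
  points <- rbind(points)
  if (nrow(points) < 1L) stop("team_centroid: need at least one point")
  colMeans(points[, 1:2, drop = FALSE])
}

#' Distances from each member to the team centroid
#'
#' @inheritParams team_centroid
#' @return Numeric vector of Euclidean distances, one per row of `points`.
#' @export
centroid_distances <- function(points) {
  points <- rbind(points)
  ctr <- team_centroid(points)
  sqrt((points[, 1] - ctr[1])^2 + (points[, 2] - ctr[2])^2)
}

#' All unordered pair distances within a team
#'
#' @inheritParams team_centroid
#' @return Numeric vector of `choose(n, 2)` Euclidean distances, in
#'   `combn(n, 2)` column order.
#' @export
pair_distances <- function(points) {
  points <- rbind(points)
  n <- nrow(points)
  if (n < 2L) stop("pair_distances: need at least two points")
  idx <- utils::combn(n, 2)
  sqrt((points[idx[1, ], 1] - points[idx[2, ], 1])^2 +
       (points[idx[1, ], 2] - points[idx[2, ], 2])^2)
}

#' Cluster teammates by spatial proximity
#'
#' DBSCAN with `min_pts = 1` and Euclidean `eps_cm`, which on team-sized
#' point sets reduces exactly to connected components of the graph joining
#' points at distance `<= eps_cm` (chaining included, no noise points).
#' The default epsilon is 100 m, on the scale at which teammates share
#' audiovisual input.
#'
#' @inheritParams team_centroid
#' @param eps_cm Neighborhood radius in cm (default 10000 = 100 m).
#' @param min_pts Minimum density; only 1 is supported (any point forms a
#'   cluster by itself).
#' @return Integer cluster labels (1-based, in order of first appearance).
#' @export
cluster_players <- function(points, eps_cm = 10000, min_pts = 1) {
  if (min_pts != 1L) stop("cluster_players: only min_pts = 1 is supported")
  if (eps_cm <= 0) stop("cluster_players: eps_cm must be positive")
  points <- rbind(points)
  n <- nrow(points)
  if (n < 1L) stop("cluster_players: need at least one point")
  ## union-find over the epsilon graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d2 <- (points[i, 1] - points[j, 1])^2 + (points[i, 2] - points[j, 2])^2
      if (d2 <= eps_cm^2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Classify a team's interdependence state
#'
#' @param labels Cluster labels of the alive members (from
#'   [cluster_players()]).
#' @param n_alive Number of alive members the labels cover.
#' @return `"HIGH"` (one cluster), `"LOW"` (all singletons), `"MEDIUM"`
#'   otherwise; `NA` when fewer than two members are alive (the state is
#'   undefined and the timepoint is excluded from features).
#' @export
classify_interdependence <- function(labels, n_alive = length(labels)) {
  if (n_alive < 2L) return(NA_character_)
  k <- length(unique(labels))
  if (k == 1L) "HIGH" else if (k == n_alive) "LOW" else "MEDIUM"
}

#' Normalize a pair distance for the shrinking play area
#'
#' Raw intra-team distances shrink mechanically as the circle closes,
#' which would masquerade as rising collaboration late in the match. The
#' distance is therefore divided by the remaining-time fraction (floored to
#' avoid blow-up at match end) before a `log1p` transform, up-weighting
#' late-match separation and compressing large distances:
#' `log1p(d / max(floor, (duration - t) / duration))`.
#'
#' @param d_cm Distance in cm (>= 0), vectorized.
#' @param t_s Time of the sample (s), vectorized.
#' @param duration_s Match duration (s).
#' @param floor Lower bound on the remaining-time fraction (default 0.1).
#' @return Dimensionless normalized log distance.
#' @export
normalize_distance <- function(d_cm, t_s, duration_s, floor = 0.1) {
  if (duration_s <= 0) stop("normalize_distance: duration_s must be positive")
  if (any(d_cm < 0)) stop("normalize_distance: d_cm must be non-negative")
  rem <- pmax(floor, (duration_s - t_s) / duration_s)
  log1p(d_cm / rem)
}

## ---- vectorized per-timepoint engine ------------------------------------

## Component-count lookup tables: for n members, comps[alive_mask+1,
## edge_mask+1] = number of connected components among alive members given
## the alive-pair edges present. Cached per n (used for n <= 5).
.comp_table_env <- new.env(parent = emptyenv())

.component_table <- function(n) {
  key <- as.character(n)
  tab <- .comp_table_env[[key]]
  if (!is.null(tab)) return(tab)
  np <- choose(n, 2)
  idx <- utils::combn(n, 2)
  tab <- matrix(NA_integer_, nrow = 2^n, ncol = 2^np)
  for (am in 0:(2^n - 1)) {
    alive <- which(bitwAnd(am, 2^(0:(n - 1))) > 0)
    if (length(alive) < 2L) next
    for (em in 0:(2^np - 1)) {
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (p in seq_len(np)) {
        if (bitwAnd(em, bitwShiftL(1L, p - 1L)) > 0) {
          i <- idx[1, p]; j <- idx[2, p]
          if (i %in% alive && j %in% alive) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[rj] <- ri
          }
        }
      }
      tab[am + 1L, em + 1L] <- length(unique(vapply(alive, find, integer(1))))
    }
  }
  .comp_table_env[[key]] <- tab
  tab
}

## Per-timepoint behavior quantities for one team.
## X, Y, A: [n_members x n_time] coordinate and alive matrices (NA / FALSE
## where a member has no record). Returns per-timepoint state codes
## (1 HIGH, 2 MEDIUM, 3 LOW, NA unevaluated) and min/max normalized pair
## distances over alive pairs.
.per_timepoint_behavior <- function(X, Y, A, t_s, eps_cm, duration_s,
                                    floor = 0.1, state_mask = NULL) {
  n <- nrow(X); Tn <- ncol(X)
  A[is.na(A)] <- FALSE
  k_alive <- colSums(A)
  eval_t <- k_alive >= 2L
  if (is.null(state_mask)) state_mask <- rep(TRUE, Tn)
  state <- rep(NA_integer_, Tn)
  nd_min <- rep(NA_real_, Tn)
  nd_max <- rep(NA_real_, Tn)
  if (!any(eval_t)) {
    return(list(eval = eval_t, state = state, nd_min = nd_min, nd_max = nd_max))
  }
  idx <- utils::combn(n, 2)
  np <- ncol(idx)
  D <- matrix(NA_real_, nrow = np, ncol = Tn)
  PA <- matrix(FALSE, nrow = np, ncol = Tn)
  for (p in seq_len(np)) {
    i <- idx[1, p]; j <- idx[2, p]
    D[p, ] <- sqrt((X[i, ] - X[j, ])^2 + (Y[i, ] - Y[j, ])^2)
    PA[p, ] <- A[i, ] & A[j, ]
  }
  ## states via component-count lookup (n <= 5) or per-timepoint union-find
  if (n <= 5L) {
    tab <- .component_table(n)
    am <- as.integer(2^(0:(n - 1)) %*% A)
    within <- PA & !is.na(D) & (D <= eps_cm)
    within[is.na(within)] <- FALSE
    em <- as.integer(2^(0:(np - 1)) %*% within)
    ncomp <- tab[cbind(am + 1L, em + 1L)]
  } else {
    ncomp <- rep(NA_integer_, Tn)
    for (tt in which(eval_t)) {
      alive <- which(A[, tt])
      lab <- cluster_players(cbind(X[alive, tt], Y[alive, tt]), eps_cm)
      ncomp[tt] <- length(unique(lab))
    }
  }
  state[eval_t] <- ifelse(ncomp[eval_t] == 1L, 1L,
                    ifelse(ncomp[eval_t] == k_alive[eval_t], 3L, 2L))
  ## normalized min/max/SD of pair distances over alive pairs
  rem <- pmax(floor, (duration_s - t_s) / duration_s)
  ND <- log1p(sweep(D, 2, rem, "/"))
  ND[!PA] <- NA_real_
  nd_rows <- lapply(seq_len(np), function(p) ND[p, ])
  nd_min <- do.call(pmin, c(nd_rows, list(na.rm = TRUE)))
  nd_max <- do.call(pmax, c(nd_rows, list(na.rm = TRUE)))
  cnt <- colSums(PA)
  NDm <- ND; NDm[!PA] <- 0
  s1 <- colSums(NDm); s2 <- colSums(NDm^2)
  nd_sd <- rep(NA_real_, Tn)
  multi <- cnt >= 2
  nd_sd[multi] <- sqrt(pmax(0, (s2[multi] - s1[multi]^2 / cnt[multi]) /
                              (cnt[multi] - 1)))
  nd_sd[cnt == 1] <- 0
  state[!state_mask] <- NA_integer_
  list(eval = eval_t, state_eval = eval_t & state_mask, state = state,
       nd_min = nd_min, nd_max = nd_max, nd_sd = nd_sd)
}

## Reshape one team's long location table into member x time matrices.
.team_matrices <- function(team_table) {
  members <- sort(unique(team_table$player_id))
  times <- sort(unique(team_table$t_s))
  n <- length(members); Tn <- length(times)
  X <- matrix(NA_real_, n, Tn); Y <- X
  A <- matrix(FALSE, n, Tn)
  ri <- match(team_table$player_id, members)
  ci <- match(team_table$t_s, times)
  X[cbind(ri, ci)] <- team_table$x_cm
  Y[cbind(ri, ci)] <- team_table$y_cm
  A[cbind(ri, ci)] <- team_table$alive
  list(X = X, Y = Y, A = A, t_s = times, members = members)
}

#' Behavioral-interdependence and collaboration features for one team-match
#'
#' For every sampled timepoint with at least two alive members, the team's
#' interdependence state (HIGH/MEDIUM/LOW, via [cluster_players()]) and the
#' normalized log pair distances are computed; states aggregate to time
#' shares and the per-timepoint extremes average to the two collaboration
#' measures (`collab_low` from the farthest pair: dispersion; `collab_high`
#' from the closest pair: tightness).
#'
#' @param team_table Location table rows for one team in one match (columns
#'   `player_id`, `t_s`, `x_cm`, `y_cm`, `alive`).
#' @param eps_cm Clustering epsilon in cm (default 100 m).
#' @param duration_s Match duration used for distance normalization.
#' @param floor Remaining-time floor passed to [normalize_distance()].
#' @param schedule Optional [shrink_schedule()]. When supplied, the
#'   interdependence *state* is only evaluated while the play-circle radius
#'   exceeds `state_radius_mult * eps_cm`: once the circle approaches the
#'   clustering scale every surviving team is one cluster by construction,
#'   so endgame timepoints carry no interdependence signal and would inflate
#'   the HIGH share of long-surviving teams. Pair-distance collaboration
#'   features are evaluated at all timepoints (they carry their own
#'   shrink-area normalization).
#' @param state_radius_mult Radius multiple of `eps_cm` below which states
#'   stop being evaluated (default 3).
#' @return One-row data frame: `share_high`, `share_med`, `share_low`,
#'   `collab_high`, `collab_low`, `sd_dist`, `n_timepoints` (state-evaluated
#'   timepoints). When no timepoint has two alive members the row has
#'   `n_timepoints = 0` and `NA` features and must be excluded downstream.
#' @export
collaboration_features <- function(team_table, eps_cm = 10000, duration_s,
                                   floor = 0.1, schedule = NULL,
                                   state_radius_mult = 3) {
  tm <- .team_matrices(team_table)
  state_mask <- if (is.null(schedule)) NULL else
    shrink_radius(tm$t_s, schedule) >= state_radius_mult * eps_cm
  pt <- .per_timepoint_behavior(tm$X, tm$Y, tm$A, tm$t_s, eps_cm, duration_s,
                                floor, state_mask = state_mask)
  ev <- pt$eval
  sev <- pt$state_eval
  if (sum(sev) == 0L || sum(ev) == 0L) {
    return(data.frame(share_high = NA_real_, share_med = NA_real_,
                      share_low = NA_real_, collab_high = NA_real_,
                      collab_low = NA_real_, sd_dist = NA_real_,
                      n_timepoints = 0L))
  }
  st <- pt$state[sev]
  data.frame(
    share_high = mean(st == 1L),
    share_med  = mean(st == 2L),
    share_low  = mean(st == 3L),
    collab_high = mean(pt$nd_min[ev]),
    collab_low  = mean(pt$nd_max[ev]),
    sd_dist = mean(pt$nd_sd[ev]),
    n_timepoints = sum(sev))
}

#' Behavior features for every team in a match (or cohort)
#'
#' @param matches A [match_telemetry()] object or list of them.
#' @param eps_cm Clustering epsilon in cm.
#' @param floor Remaining-time floor for distance normalization.
#' @param schedule A [shrink_schedule()] used to mask endgame state
#'   evaluation (see [collaboration_features()]); by default the map's
#'   standard schedule. Pass `NA` to disable masking.
#' @return Data frame with one row per team-match: `match_id`, `team_id`,
#'   `share_high`, `share_med`, `share_low`, `collab_high`, `collab_low`,
#'   `sd_dist`, `n_timepoints`. Rows with `n_timepoints == 0` are retained
#'   here and dropped by [assemble_records()].
#' @export
behavior_features <- function(matches, eps_cm = 10000, floor = 0.1,
                              schedule = NULL) {
  if (inherits(matches, "match_telemetry")) matches <- list(matches)
  out <- lapply(matches, function(m) {
    sch <- if (is.null(schedule)) shrink_schedule(m$meta$map_side_cm) else
      if (identical(schedule, NA)) NULL else schedule
    st <- m$states
    idx <- split(seq_len(nrow(st)), st$team_id)
    rows <- lapply(names(idx), function(tid) {
      ii <- idx[[tid]]
      ft <- collaboration_features(
        data.frame(player_id = st$player_id[ii], t_s = st$t_s[ii],
                   x_cm = st$x_cm[ii], y_cm = st$y_cm[ii],
                   alive = st$alive[ii], stringsAsFactors = FALSE),
        eps_cm = eps_cm, duration_s = m$meta$duration_s, floor = floor,
        schedule = sch)
      cbind(data.frame(match_id = m$meta$match_id, team_id = tid,
                       stringsAsFactors = FALSE), ft)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$match_id, out$team_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
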