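#' Construct a match telemetry object
#'
#' A `match_telemetry` bundles everything recorded for one squad match:
#' match metadata, sampled player locations (every 10 s), parachute landing
#' events, per-player season experience, and the final team ranking.
#'
#' Location records for a player stop at team elimination: the last record of
#' an eliminated player carries `alive = FALSE`; all earlier records carry
#' `alive = TRUE`. Surviving players have records to the end of the match.
#'
#' @param meta List with fields `match_id`, `map_name`, `map_side_cm`,
#'   `n_players`, `team_size`, `duration_s`.
#' @param states Data frame with columns `player_id`, `team_id`, `t_s`,
#'   `x_cm`, `y_cm`, `alive` (one row per player per sampled timepoint).
#' @param landings Data frame with columns `player_id`, `team_id`, `x_cm`,
#'   `y_cm`, `t_s` (one row per player).
#' @param profiles Data frame with columns `player_id`, `rank_points`.
#' @param final_ranks Named integer vector: `team_id` -> final rank
#'   (1 = winner; larger is worse; ties are not representable).
#' @param validate Validate invariants (default `TRUE`).
#' @return An object of class `match_telemetry`.
#' @seealso [read_telemetry()], [write_telemetry()], [location_table()]
#' @export
match_telemetry <- function(meta, states, landings, profiles, final_ranks,
                            validate = TRUE) {
  m <- structure(
    list(meta = meta,
         states = as.data.frame(states),
         landings = as.data.frame(landings),
         profiles = as.data.frame(profiles),
         final_ranks = final_ranks),
    class = "match_telemetry")
  if (validate) validate_telemetry(m)
  m
}

#' @export
print.match_telemetry <- function(x, ...) {
  cat(sprintf("<match_telemetry> %s on %s (%d cm side)\n",
              x$meta$match_id, x$meta$map_name, x$meta$map_side_cm))
  cat(sprintf("  %d players in teams of %d; duration %.0f s\n",
              x$meta$n_players, x$meta$team_size, x$meta$duration_s))
  cat(sprintf("  %d location records, %d landings, %d profiles, %d teams ranked\n",
              nrow(x$states), nrow(x$landings), nrow(x$profiles),
              length(x$final_ranks)))
  invisible(x)
}

#' Validate a match telemetry object
#'
#' Enforces the dialect invariants: map side matches the map name; player
#' counts divide into teams; coordinates lie inside the map; per-player
#' sampling times form an arithmetic grid with 10 s step (any common offset);
#' exactly one landing per player; finite non-negative rank points; final
#' ranks are a permutation of `1..n_teams` over the teams present in the
#' location records.
#'
#' @param m A [match_telemetry()] object.
#' @return `m`, invisibly; stops with an informative error on violation.
#' @export
validate_telemetry <- function(m) {
  meta <- m$meta
  need <- c("match_id", "map_name", "map_side_cm", "n_players", "team_size",
            "duration_s")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("meta missing fields: ", paste(miss, collapse = ", "))
  side <- map_side_cm(meta$map_name)
  if (meta$map_side_cm != side) {
    stop("invariant violated: map_side_cm (", meta$map_side_cm,
         ") does not match map ", meta$map_name, " (", side, ")")
  }
  if (meta$n_players %% meta$team_size != 0) {
    stop("invariant violated: n_players (", meta$n_players,
         ") not divisible by team_size (", meta$team_size, ")")
  }
  if (meta$duration_s <= 0 || meta$duration_s > 1800) {
    stop("invariant violated: duration_s must be in (0, 1800]")
  }

  st <- m$states
  if (nrow(st) == 0L) stop("invariant violated: states must be non-empty")
  for (col in c("player_id", "team_id", "t_s", "x_cm", "y_cm", "alive")) {
    if (is.null(st[[col]])) stop("states missing column: ", col)
  }
  oob <- st$x_cm < 0 | st$x_cm > side | st$y_cm < 0 | st$y_cm > side
  if (any(oob)) {
    stop("invariant violated: ", sum(oob),
         " state coordinate(s) outside [0, ", side, "]")
  }
  # 10 s arithmetic sampling grid per player (common offset allowed)
  bad_grid <- vapply(split(st$t_s, st$player_id), function(tt) {
    tt <- sort(tt)
    length(tt) > 1L && any(abs(diff(tt) - 10) > 1e-9)
  }, logical(1))
  if (any(bad_grid)) {
    stop("invariant violated: sampling grid not 10 s-spaced for player(s): ",
         paste(utils::head(names(bad_grid)[bad_grid], 5), collapse = ", "))
  }

  ld <- m$landings
  if (anyDuplicated(ld$player_id)) {
    dup <- unique(ld$player_id[duplicated(ld$player_id)])
    stop("invariant violated: duplicate landing for player(s): ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  oob <- ld$x_cm < 0 | ld$x_cm > side | ld$y_cm < 0 | ld$y_cm > side
  if (any(oob)) stop("invariant violated: landing coordinates outside map")

  pr <- m$profiles
  if (any(!is.finite(pr$rank_points)) || any(pr$rank_points < 0)) {
    stop("invariant violated: rank_points must be finite and non-negative")
  }

  fr <- m$final_ranks
  teams <- unique(st$team_id)
  if (!all(names(fr) %in% teams)) {
    stop("invariant violated: ranked team(s) absent from states: ",
         paste(setdiff(names(fr), teams), collapse = ", "))
  }
  if (!setequal(sort(as.integer(fr)), seq_along(fr))) {
    stop("invariant violated: final_ranks must be a permutation of 1..",
         length(fr), " (ties forbidden)")
  }
  invisible(m)
}

## ---- JSON-Lines dialect -------------------------------------------------
## One JSON object per line; "record_type" in {meta, state, landing, profile,
## rank}. Numbers are serialized at full precision so read(write(m)) == m.

#' Write match telemetry to a JSON-Lines file
#'
#' @param match A validated [match_telemetry()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_telemetry <- function(match, path) {
  validate_telemetry(match)
  esc <- function(s) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", s))
  num <- function(x) sprintf("%.17g", x)  # round-trips doubles exactly
  st <- match$states
  state_lines <- sprintf(
    '{"record_type":"state","player_id":"%s","team_id":"%s","t_s":%s,"x_cm":%s,"y_cm":%s,"alive":%s}',
    esc(st$player_id), esc(st$team_id), num(st$t_s), num(st$x_cm),
    num(st$y_cm), ifelse(st$alive, "true", "false"))
  ld <- match$landings
  landing_lines <- sprintf(
    '{"record_type":"landing","player_id":"%s","team_id":"%s","x_cm":%s,"y_cm":%s,"t_s":%s}',
    esc(ld$player_id), esc(ld$team_id), num(ld$x_cm), num(ld$y_cm),
    num(ld$t_s))
  pr <- match$profiles
  profile_lines <- sprintf(
    '{"record_type":"profile","player_id":"%s","rank_points":%s}',
    esc(pr$player_id), num(pr$rank_points))
  j <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                    na = "null")
  meta_line <- j(c(list(record_type = "meta"), match$meta))
  rank_line <- j(list(record_type = "rank",
                      ranks = as.list(setNames(as.integer(match$final_ranks),
                                               names(match$final_ranks)))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(meta_line, state_lines, landing_lines, profile_lines,
               rank_line), con)
  invisible(path)
}

#' Read match telemetry from a JSON-Lines file
#'
#' Inverse of [write_telemetry()]: parses one JSON record per line and
#' validates all dialect invariants. Malformed lines are reported with their
#' line number.
#'
#' @param path File written by [write_telemetry()] (or conforming to the
#'   dialect).
#' @return A validated [match_telemetry()] object.
#' @export
read_telemetry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    recs[[i]] <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) stop("parse error at line ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    if (is.null(recs[[i]]$record_type)) {
      stop("parse error at line ", i, ": missing record_type", call. = FALSE)
    }
  }
  types <- vapply(recs, function(r) as.character(r$record_type), character(1))
  bad <- !types %in% c("meta", "state", "landing", "profile", "rank")
  if (any(bad)) {
    stop("parse error at line ", which(bad)[1], ": unknown record_type '",
         types[which(bad)[1]], "'", call. = FALSE)
  }
  if (sum(types == "meta") != 1L) stop("expected exactly one meta record")
  if (sum(types == "rank") != 1L) stop("expected exactly one rank record")

  meta <- recs[[which(types == "meta")]]
  meta$record_type <- NULL

  pick <- function(type, cols, numeric_cols = character(), logical_cols = character()) {
    rs <- recs[types == type]
    out <- lapply(cols, function(cl)
      unlist(lapply(rs, function(r) r[[cl]]), use.names = FALSE))
    names(out) <- cols
    for (cl in numeric_cols) out[[cl]] <- as.numeric(out[[cl]])
    for (cl in logical_cols) out[[cl]] <- as.logical(out[[cl]])
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  states <- pick("state", c("player_id", "team_id", "t_s", "x_cm", "y_cm",
                            "alive"),
                 numeric_cols = c("t_s", "x_cm", "y_cm"),
                 logical_cols = "alive")
  landings <- pick("landing", c("player_id", "team_id", "x_cm", "y_cm", "t_s"),
                   numeric_cols = c("x_cm", "y_cm", "t_s"))
  profiles <- pick("profile", c("player_id", "rank_points"),
                   numeric_cols = "rank_points")
  rk <- recs[[which(types == "rank")]]$ranks
  final_ranks <- setNames(as.integer(unlist(rk)), names(rk))

  match_telemetry(meta = meta, states = states, landings = landings,
                  profiles = profiles, final_ranks = final_ranks)
}

#' Long location table for one match
#'
#' One row per (player, sampled timepoint), sorted by `(t_s, team_id,
#' player_id)`. This is the canonical input to the behavior and risk feature
#' extractors.
#'
#' @param match A [match_telemetry()] object.
#' @return Data frame with columns `player_id`, `team_id`, `t_s`, `x_cm`,
#'   `y_cm`, `alive`.
#' @export
location_table <- function(match) {
  st <- match$states
  st <- st[order(st$t_s, st$team_id, st$player_id),
           c("player_id", "team_id", "t_s", "x_cm", "y_cm", "alive")]
  rownames(st) <- NULL
  st
}
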