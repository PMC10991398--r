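# Small hand-built telemetry objects and compact simulation configs used
# across the suite.

# A tiny valid match: 2 teams of 2 on Karakin, 3 timepoints.
tiny_match <- function() {
  states <- expand.grid(t_s = c(0, 10, 20),
                        player_id = c("a1", "a2", "b1", "b2"),
                        stringsAsFactors = FALSE)
  states$team_id <- ifelse(grepl("^a", states$player_id), "A", "B")
  states$x_cm <- c(1000, 1100, 1200)[match(states$t_s, c(0, 10, 20))] +
    100 * as.integer(factor(states$player_id))
  states$y_cm <- 5000 + 50 * as.integer(factor(states$player_id))
  states$alive <- TRUE
  landings <- data.frame(player_id = c("a1", "a2", "b1", "b2"),
                         team_id = c("A", "A", "B", "B"),
                         x_cm = c(1000, 1050, 9000, 9100),
                         y_cm = c(5000, 5010, 7000, 7050),
                         t_s = 0, stringsAsFactors = FALSE)
  profiles <- data.frame(player_id = c("a1", "a2", "b1", "b2"),
                         rank_points = c(1, 2, 3, 4),
                         stringsAsFactors = FALSE)
  match_telemetry(
    meta = list(match_id = "tiny", map_name = "Karakin",
                map_side_cm = 204000, n_players = 4L, team_size = 2L,
                duration_s = 30),
    states = states[, c("player_id", "team_id", "t_s", "x_cm", "y_cm",
                        "alive")],
    landings = landings, profiles = profiles,
    final_ranks = c(A = 1L, B = 2L))
}

# Compact simulator config for fast tests.
small_config <- function(seed, ...) {
  sim_config(seed = seed, map_name = "Karakin", n_teams = 5L,
             team_size = 4L, n_matches = 2L, cap_s = 600, ...)
}

# One-team location table at fixed positions over a set of timepoints.
team_table_at <- function(xy, times = seq(0, 90, by = 10)) {
  n <- nrow(xy)
  data.frame(
    player_id = rep(sprintf("p%d", seq_len(n)), each = length(times)),
    t_s = rep(times, n),
    x_cm = rep(xy[, 1], each = length(times)),
    y_cm = rep(xy[, 2], each = length(times)),
    alive = TRUE, stringsAsFactors = FALSE)
}
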