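## Landing-risk heatmaps and risk features.
##
## Riskiness of a location is operationalized as the number of parachute
## landings it attracts in a reference cohort, binned on a 10 x 10 m grid
## (816x816 cells on the 8 km maps, 408x408 on Sanhok, 204x204 on Karakin).

#' Map coordinates to a 10 m grid cell
#'
#' Cells are half-open `[i*cell, (i+1)*cell)`, 0-based; the maximum map
#' coordinate maps to the last cell.
#'
#' @param x_cm,y_cm Coordinates in cm (vectorized).
#' @param cell_cm Cell side in cm (default 1000 = 10 m).
#' @param n_cells Number of cells per side.
#' @return Two-column integer matrix of 0-based cell indices `(i, j)`.
#' @export
cell_index <- function(x_cm, y_cm, cell_cm = 1000, n_cells) {
  side <- cell_cm * n_cells
  if (any(x_cm < 0 | x_cm > side | y_cm < 0 | y_cm > side)) {
    stop("cell_index: coordinates outside [0, ", side, "]")
  }
  i <- pmin(as.integer(floor(x_cm / cell_cm)), n_cells - 1L)
  j <- pmin(as.integer(floor(y_cm / cell_cm)), n_cells - 1L)
  cbind(i = i, j = j)
}

#' Build a landing-count heatmap
#'
#' @param landings Data frame with columns `x_cm`, `y_cm` (a match's
#'   `landings` table, or a pooled reference cohort of landings).
#' @param map_name Map the landings belong to; coordinates are validated
#'   against its bounds.
#' @param cell_cm Cell side in cm (default 10 m).
#' @return An object of class `risk_heatmap`: `map_name`, `cell_cm`,
#'   `n_cells`, and an integer `counts` matrix (row = x cell `i` + 1,
#'   column = y cell `j` + 1) whose total equals `nrow(landings)`.
#' @export
build_heatmap <- function(landings, map_name, cell_cm = 1000) {
  side <- map_side_cm(map_name)
  n_cells <- as.integer(side / cell_cm)
  if (any(landings$x_cm < 0 | landings$x_cm > side |
          landings$y_cm < 0 | landings$y_cm > side)) {
    stop("build_heatmap: landings outside map ", map_name,
         " (mixed-map input?)")
  }
  ij <- cell_index(landings$x_cm, landings$y_cm, cell_cm, n_cells)
  counts <- matrix(0L, n_cells, n_cells)
  tab <- table(ij[, 1] * n_cells + ij[, 2])  # sparse accumulation
  lin <- as.integer(names(tab))
  counts[cbind(lin %/% n_cells + 1L, lin %% n_cells + 1L)] <- as.integer(tab)
  structure(list(map_name = map_name, cell_cm = cell_cm, n_cells = n_cells,
                 counts = counts),
            class = "risk_heatmap")
}

#' @export
print.risk_heatmap <- function(x, ...) {
  cat(sprintf("<risk_heatmap> %s: %d x %d cells of %.0f m, %d landings\n",
              x$map_name, x$n_cells, x$n_cells, x$cell_cm / 100,
              sum(x$counts)))
  invisible(x)
}

#' Landing risk of one or more landings
#'
#' The risk of a landing is the reference-cohort landing count of its cell.
#'
#' @param landings Data frame with `x_cm`, `y_cm` columns.
#' @param heatmap A [build_heatmap()] reference heatmap.
#' @param map_name Map of the landings; must match the heatmap.
#' @return Integer vector of cell counts, one per landing.
#' @export
landing_risk <- function(landings, heatmap, map_name = heatmap$map_name) {
  if (!identical(map_name, heatmap$map_name)) {
    stop("landing_risk: map mismatch (", map_name, " vs heatmap ",
         heatmap$map_name, ")")
  }
  ij <- cell_index(landings$x_cm, landings$y_cm, heatmap$cell_cm,
                   heatmap$n_cells)
  heatmap$counts[cbind(ij[, 1] + 1L, ij[, 2] + 1L)]
}

#' Team landing risk: extremes over members
#'
#' @param member_risks Numeric vector of member landing risks.
#' @return Named vector `c(high = max, low = min)`.
#' @export
team_landing_risk <- function(member_risks) {
  if (length(member_risks) < 1L) stop("team_landing_risk: empty team")
  c(high = max(member_risks), low = min(member_risks))
}

#' High-risk cell cutoff of a heatmap
#'
#' A cell is "high-risk" iff its landing count exceeds the median count over
#' nonzero cells (zero cells are overwhelmingly empty wilderness and would
#' drag any quantile to zero).
#'
#' @param heatmap A [build_heatmap()] object with at least one landing.
#' @return The cutoff count; cells with `count > cutoff` are high-risk.
#' @export
risk_cell_threshold <- function(heatmap) {
  nz <- heatmap$counts[heatmap$counts > 0L]
  if (length(nz) == 0L) stop("risk_cell_threshold: all-zero heatmap")
  stats::median(nz)
}

#' Time spent in high- and low-risk cells
#'
#' Each alive sampled point contributes 10 s (the sampling interval) to its
#' member's high- or low-risk clock. The team values are the maxima over
#' members: `time_high_risk_s` tracks the most risk-taking member,
#' `time_low_risk_s` the member who most exhibits low-risk behavior.
#'
#' @param team_table Location-table rows for one team.
#' @param heatmap Reference [build_heatmap()].
#' @param cutoff High-risk cutoff, from [risk_cell_threshold()].
#' @return Named vector `c(time_high_risk_s = ..., time_low_risk_s = ...)`.
#' @export
overtime_risk <- function(team_table, heatmap, cutoff) {
  tt <- team_table[team_table$alive, , drop = FALSE]
  if (nrow(tt) == 0L) {
    return(c(time_high_risk_s = 0, time_low_risk_s = 0))
  }
  ij <- cell_index(tt$x_cm, tt$y_cm, heatmap$cell_cm, heatmap$n_cells)
  hi <- heatmap$counts[cbind(ij[, 1] + 1L, ij[, 2] + 1L)] > cutoff
  f <- factor(tt$player_id)
  t_hi <- tapply(hi, f, sum) * 10
  t_lo <- tapply(!hi, f, sum) * 10
  c(time_high_risk_s = max(t_hi), time_low_risk_s = max(t_lo))
}

#' Cohort risk category
#'
#' Discretizes a cohort's overtime-risk values at quantile thresholds into
#' low (-1), medium (0), and high (+1) risk strategies. At the defaults both
#' thresholds sit at the median, so 0 is only assigned to exact median ties;
#' setting e.g. `q_low = 1/3, q_high = 2/3` yields three populated classes.
#'
#' @param values Numeric vector (one per team), e.g. `time_high_risk_s`.
#' @param q_low,q_high Quantile thresholds in `[0, 1]` (defaults 0.5, 0.5).
#' @return Integer labels in `{-1, 0, 1}`, same length as `values`.
#' @export
risk_category <- function(values, q_low = 0.5, q_high = 0.5) {
  if (length(values) < 2L) stop("risk_category: need a cohort of >= 2 values")
  lo <- stats::quantile(values, q_low, names = FALSE)
  hi <- stats::quantile(values, q_high, names = FALSE)
  ifelse(values < lo, -1L, ifelse(values > hi, 1L, 0L))
}

#' Risk features for every team in a match (or cohort)
#'
#' Combines landing risk extremes and overtime risk per team, then assigns
#' the cohort-wide risk category from `time_high_risk_s`.
#'
#' @param matches A [match_telemetry()] or list of them (all on the
#'   heatmap's map).
#' @param heatmap Reference heatmap (built from a held-out landing cohort to
#'   avoid self-counting; pass a heatmap built from these matches' own
#'   landings for self-inclusive risk).
#' @param cutoff High-risk cutoff; default [risk_cell_threshold()] of
#'   `heatmap`.
#' @param q_low,q_high Quantiles for [risk_category()].
#' @return Data frame: `match_id`, `team_id`, `landing_risk_high`,
#'   `landing_risk_low`, `time_high_risk_s`, `time_low_risk_s`,
#'   `risk_category`.
#' @export
risk_features <- function(matches, heatmap,
                          cutoff = risk_cell_threshold(heatmap),
                          q_low = 0.5, q_high = 0.5) {
  if (inherits(matches, "match_telemetry")) matches <- list(matches)
  out <- lapply(matches, function(m) {
    lr <- landing_risk(m$landings, heatmap, m$meta$map_name)
    tlr_hi <- tapply(lr, m$landings$team_id, max)
    tlr_lo <- tapply(lr, m$landings$team_id, min)
    ## overtime: one cell lookup for all alive samples of the match
    st <- m$states
    al <- which(st$alive)
    ij <- cell_index(st$x_cm[al], st$y_cm[al], heatmap$cell_cm,
                     heatmap$n_cells)
    hi <- heatmap$counts[cbind(ij[, 1] + 1L, ij[, 2] + 1L)] > cutoff
    pl <- factor(st$player_id[al])
    t_hi <- tapply(hi, pl, sum) * 10
    t_lo <- tapply(!hi, pl, sum) * 10
    p2t <- st$team_id[al][match(levels(pl), st$player_id[al])]
    teams <- sort(unique(m$states$team_id))
    ot_hi <- tapply(t_hi, p2t, max)[teams]
    ot_lo <- tapply(t_lo, p2t, max)[teams]
    ot_hi[is.na(ot_hi)] <- 0; ot_lo[is.na(ot_lo)] <- 0
    data.frame(match_id = m$meta$match_id, team_id = teams,
               landing_risk_high = as.numeric(tlr_hi[teams]),
               landing_risk_low = as.numeric(tlr_lo[teams]),
               time_high_risk_s = as.numeric(ot_hi),
               time_low_risk_s = as.numeric(ot_lo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$risk_category <- risk_category(out$time_high_risk_s, q_low, q_high)
  rownames(out) <- NULL
  out
}
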