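#' Play-area shrink schedule
#'
#' The playable circle starts with radius equal to the map half-diagonal and
#' holds for an initial exploration window, then contracts at a constant rate
#' of 22.8 m/s (2280 cm/s). Each time the circle reaches a trigger diameter,
#' contraction pauses for 3 min 20 s before resuming; the cycle continues
#' until the circle closes, which happens before the 30-min match cap.
#'
#' Trigger diameters default to geometric halving of the initial diameter
#' (five halvings), after which the circle contracts to radius zero.
#'
#' @param map_side_cm Map side length in cm.
#' @param hold0_s Initial hold before the first contraction (s).
#' @param shrink_rate_cm_per_s Contraction rate of the radius (cm/s).
#' @param pause_s Pause at each trigger diameter (s).
#' @param cap_s Match duration cap (s).
#' @param trigger_diameters Decreasing vector of circle diameters (cm) at
#'   which contraction pauses; `NULL` for the geometric-halving default.
#' @return An object of class `shrink_schedule` holding the piecewise-linear
#'   radius knots.
#' @examples
#' sch <- shrink_schedule(204000)
#' shrink_radius(c(0, 300, 310), sch)
#' @export
shrink_schedule <- function(map_side_cm,
                            hold0_s = 300,
                            shrink_rate_cm_per_s = 2280,
                            pause_s = 200,
                            cap_s = 1800,
                            trigger_diameters = NULL) {
  r0 <- map_side_cm * sqrt(2) / 2  # half-diagonal: circle covers the map
  if (is.null(trigger_diameters)) {
    trigger_diameters <- 2 * r0 / 2^(1:5)
  }
  trig_r <- sort(trigger_diameters / 2, decreasing = TRUE)
  if (any(trig_r >= r0)) stop("trigger diameters must be below the initial diameter")
  kt <- c(0, hold0_s)
  kr <- c(r0, r0)
  t_cur <- hold0_s; r_cur <- r0
  for (rk in trig_r) {
    t_cur <- t_cur + (r_cur - rk) / shrink_rate_cm_per_s
    kt <- c(kt, t_cur); kr <- c(kr, rk)
    t_cur <- t_cur + pause_s
    kt <- c(kt, t_cur); kr <- c(kr, rk)
    r_cur <- rk
  }
  t_cur <- t_cur + r_cur / shrink_rate_cm_per_s
  kt <- c(kt, t_cur); kr <- c(kr, 0)
  structure(list(knot_t = kt, knot_r = kr, cap_s = cap_s,
                 hold0_s = hold0_s, shrink_rate_cm_per_s = shrink_rate_cm_per_s,
                 pause_s = pause_s, map_side_cm = map_side_cm,
                 initial_radius_cm = r0),
            class = "shrink_schedule")
}

#' Circle radius at a given time
#'
#' Piecewise-linear evaluation of the shrink schedule; constant after the
#' schedule completes (and after `cap_s`).
#'
#' @param t_s Time(s) from match start, in seconds (vectorized).
#' @param schedule A [shrink_schedule()].
#' @return Radius in cm, same length as `t_s`.
#' @export
shrink_radius <- function(t_s, schedule) {
  if (any(t_s < 0)) stop("t_s must be non-negative")
  t_eval <- pmin(t_s, schedule$cap_s)
  stats::approx(schedule$knot_t, schedule$knot_r, xout = t_eval,
                rule = 2)$y
}
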