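## Model battery around rank_clm: stratified simple-slopes fits, quadratic
## and interaction robustness fits, binary top-k logistic checks, and
## worked-example coefficient contrasts.

#' Default analysis formula
#'
#' The standard team-performance specification: final rank on the
#' interdependence shares, the two collaboration features, landing risk,
#' and the high-risk share of overtime. `share_med` is omitted from the
#' default linear terms because the three shares sum to one; overtime risk
#' enters as the high-risk fraction of risk-classified time rather than raw
#' seconds (raw high- plus low-risk seconds track a team's survival time,
#' i.e. its rank within the match, and the low fraction is the exact
#' complement of the high one).
#'
#' @param controls Include the match-level control columns.
#' @param collab Include the collaboration terms (default `TRUE`). The
#'   collaboration features trend with the length of a team's feature
#'   window (the time-remaining normalization up-weights late samples), so
#'   in simulated cohorts they partly proxy survival itself; parameter-
#'   recovery analyses therefore set `collab = FALSE`, while descriptive
#'   fits keep the full battery.
#' @return A formula.
#' @export
default_rank_formula <- function(controls = FALSE, collab = TRUE) {
  rhs <- c("share_high", "share_low",
           if (collab) c("collab_low", "collab_high"),
           "landing_risk_high", "landing_risk_low", "risk_frac_high")
  if (controls) {
    rhs <- c(rhs, "mean_max_dist", "mean_min_dist", "mean_sd_dist",
             "match_mean_risk")
  }
  stats::as.formula(paste("final_rank ~", paste(rhs, collapse = " + ")),
                    env = globalenv())
}

#' Stratified fits (simple slopes by experience)
#'
#' Fits the same specification separately within each experience stratum,
#' the stratification route to simple slopes of an experience-moderated
#' effect.
#'
#' @param data Cohort records with a `stratum` column (see
#'   [experience_strata()]).
#' @param formula Model formula (default [default_rank_formula()]).
#' @param min_n Minimum rows required per stratum (default 100).
#' @param fitter Fitting function applied per stratum (default [rank_clm()];
#'   [fit_quadratic()] can be supplied to obtain stratified curvature).
#' @param ... Passed to `fitter`.
#' @return Named list of fits, one per stratum level present.
#' @export
fit_stratified <- function(data, formula = default_rank_formula(),
                           min_n = 100, fitter = rank_clm, ...) {
  stopifnot(!is.null(data$stratum))
  out <- list()
  for (s in levels(factor(data$stratum))) {
    d <- data[data$stratum == s, , drop = FALSE]
    if (nrow(d) < min_n) {
      stop("fit_stratified: stratum ", s, " has only ", nrow(d),
           " rows (< ", min_n, ")")
    }
    out[[s]] <- fitter(formula, d, ...)
  }
  out
}

## Append centered-and-squared columns "<term>_sq" to data.
.add_quadratic <- function(data, terms) {
  for (tm in terms) {
    x <- data[[tm]]
    if (is.null(x)) stop("no such term to square: ", tm)
    data[[paste0(tm, "_sq")]] <- (x - mean(x))^2
  }
  data
}

#' Quadratic (curvilinear) robustness fit
#'
#' Adds mean-centered squared interdependence shares to the specification
#' and refits; centering before squaring decouples the curvature terms
#' from the linear trends.
#'
#' @param formula Base formula.
#' @param data Cohort records.
#' @param quad_terms Terms to center and square (default the HIGH share).
#' @param ... Passed to [rank_clm()].
#' @return A [rank_clm()] fit including `<term>_sq` coefficients.
#' @export
fit_quadratic <- function(formula, data, quad_terms = "share_high", ...) {
  data <- .add_quadratic(data, quad_terms)
  f2 <- stats::update(formula,
                      paste("~ . +", paste(paste0(quad_terms, "_sq"),
                                           collapse = " + ")))
  rank_clm(f2, data, ...)
}

#' Experience-interaction robustness fit
#'
#' Adds products of the listed terms with standardized team experience
#' (`<term>_x_exp`) and refits.
#'
#' @param formula Base formula.
#' @param data Cohort records (needs `team_experience`).
#' @param terms Terms to interact (default the HIGH share).
#' @param ... Passed to [rank_clm()].
#' @return A [rank_clm()] fit including the interaction coefficients.
#' @export
fit_interaction <- function(formula, data, terms = "share_high", ...) {
  ex <- data$team_experience
  if (is.null(ex)) stop("fit_interaction: data lacks team_experience")
  if (stats::sd(ex) == 0) {
    stop("fit_interaction: zero-variance term: team_experience")
  }
  z <- (ex - mean(ex)) / stats::sd(ex)
  for (tm in terms) {
    data[[paste0(tm, "_x_exp")]] <- data[[tm]] * z
  }
  f2 <- stats::update(formula,
                      paste("~ . +", paste(paste0(terms, "_x_exp"),
                                           collapse = " + ")))
  rank_clm(f2, data, ...)
}

#' Binary top-k logistic robustness fit
#'
#' Logistic regression of `final_rank <= k` on the same terms, the
#' robustness companion to the ordinal fit.
#'
#' @param formula Base formula (response must be `final_rank`).
#' @param data Cohort records.
#' @param k Rank cutoff (5 or 10 in the standard battery).
#' @return A `glm` fit with an extra `separation` flag (TRUE when the fit
#'   shows signs of complete separation).
#' @export
fit_logistic_topk <- function(formula, data, k = 5) {
  y <- as.integer(data$final_rank <= k)
  if (length(unique(y)) < 2L) {
    stop("fit_logistic_topk: outcome is degenerate at k = ", k,
         " (all ", if (all(y == 1L)) "successes" else "failures", ")")
  }
  data$.topk <- y
  f2 <- stats::update(formula, .topk ~ .)
  fit <- suppressWarnings(stats::glm(f2, data = data,
                                     family = stats::binomial()))
  fit$separation <- !fit$converged ||
    any(abs(stats::coef(fit)[-1]) > 50, na.rm = TRUE)
  if (fit$separation) warning("fit_logistic_topk: possible separation; fit flagged")
  fit
}

#' Difference between two coefficients, in ranking positions
#'
#' `beta_a - beta_b`, optionally rounded to whole ranking positions; the
#' worked contrast between the LOW and HIGH interdependence coefficients of
#' a stratified fit expresses how many positions separate the two play
#' styles.
#'
#' @param fit A [rank_clm()] fit, or a named coefficient vector.
#' @param term_a,term_b Coefficient names.
#' @param round_to_int Round the difference to the nearest integer.
#' @return A number.
#' @export
coefficient_difference <- function(fit, term_a, term_b,
                                   round_to_int = FALSE) {
  b <- if (inherits(fit, "rank_clm")) coef(fit) else fit
  miss <- setdiff(c(term_a, term_b), names(b))
  if (length(miss)) {
    stop("coefficient_difference: missing term(s): ",
         paste(miss, collapse = ", "))
  }
  d <- unname(b[term_a] - b[term_b])
  if (round_to_int) round(d) else d
}

#' Stratified curvature summary (simple slopes of a moderated inverted-U)
#'
#' Fits the quadratic specification within each experience stratum and
#' summarizes the curvature of rank in the HIGH-interdependence share:
#' estimate, match-cluster-robust standard error (see [vcov_cluster()]),
#' Wald p and confidence interval, plus the implied location of the
#' performance peak `m - lin / (2 quad)` (the share at which expected rank
#' is minimized when the quadratic is positive). An inverted-U of
#' performance appears as a positive, significant quadratic with an
#' interior peak; a flat (near-linear) stratum as a CI covering zero.
#'
#' @param records Cohort records with `stratum` and `match_id` columns.
#' @param formula Base formula (default drops the collaboration terms,
#'   which in simulated cohorts partly proxy survival; see
#'   [default_rank_formula()]).
#' @param term Share whose curvature is summarized (default
#'   `"share_high"`).
#' @param level Confidence level (default 0.95).
#' @param min_n Minimum rows per stratum.
#' @return Data frame with one row per stratum: `stratum`, `n`, `lin`,
#'   `quad`, `se`, `z`, `p`, `ci_low`, `ci_high`, `peak`.
#' @export
moderation_summary <- function(records,
                               formula = default_rank_formula(collab = FALSE),
                               term = "share_high", level = 0.95,
                               min_n = 100) {
  sq <- paste0(term, "_sq")
  q <- stats::qnorm(1 - (1 - level) / 2)
  out <- lapply(levels(factor(records$stratum)), function(s) {
    d <- records[records$stratum == s, , drop = FALSE]
    if (nrow(d) < min_n) {
      stop("moderation_summary: stratum ", s, " has ", nrow(d), " rows")
    }
    f <- fit_quadratic(formula, d, quad_terms = term)
    V <- vcov_cluster(f, d$match_id)
    b <- coef(f)
    se <- sqrt(V[sq, sq])
    z <- b[[sq]] / se
    peak <- mean(d[[term]]) - b[[term]] / (2 * b[[sq]])
    data.frame(stratum = s, n = nrow(d), lin = b[[term]], quad = b[[sq]],
               se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
               ci_low = b[[sq]] - q * se, ci_high = b[[sq]] + q * se,
               peak = peak, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Published reference coefficient estimates
#'
#' Cumulative-link coefficient estimates for the interdependence-state
#' variables, by experience stratum, as published by a large-scale analysis
#' of 140,699 ranked PUBG squads. Shipped for worked-example contrasts
#' (e.g. the LOW-minus-HIGH interdependence gap of 16 ranking positions in
#' low-experience teams and 13 in high-experience teams).
#'
#' @return Data frame with columns `model`, `term`, `estimate`, `ci_low`,
#'   `ci_high`.
#' @export
reference_coefficients <- function() {
  path <- system.file("extdata", "reference_coefficients.csv",
                      package = "squadrank")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Coefficient table across models
#'
#' A terms-by-models estimate matrix in the layout of a stacked ordinal
#' regression table.
#'
#' @param fits Named list of [rank_clm()] fits.
#' @return Data frame: one row per term, one column per model.
#' @export
coef_table <- function(fits) {
  terms <- unique(unlist(lapply(fits, function(f) names(coef(f)))))
  out <- data.frame(term = terms, stringsAsFactors = FALSE)
  for (nm in names(fits)) {
    b <- coef(fits[[nm]])
    out[[nm]] <- unname(b[match(terms, names(b))])
  }
  out
}
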