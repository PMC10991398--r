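---
title: "Modelling squad interdependence, risk, and match rank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling squad interdependence, risk, and match rank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squadrank)
```

## The scientific question

In squad-based battle-royale matches, 25 teams of four are dropped onto a
square map whose playable area shrinks over 30 minutes until one team
survives; the elimination order defines an ordinal performance measure
(final rank, 1 = winner). Because players choose freely how close to their
teammates they play, positional telemetry sampled every 10 s carries a
behavioral signal: how often a squad operates as one spatial unit
(*behavioral interdependence*), how tightly or loosely its members pair up
(*collaboration*), and how much it gambles on resource-rich, contested
locations (*risk taking*). squadrank turns raw telemetry into these
team-level features and models their relationship with final rank, with
particular attention to a curvilinear ("too much of a good thing")
interdependence effect moderated by player experience.

## Feature definitions

**Interdependence states.** At each sampled timepoint a team's alive
members are clustered with DBSCAN at `min_pts = 1` and a 100 m epsilon,
which on a four-player point set is exactly the connected components of
the graph joining members within 100 m (chaining included, no noise
points). One cluster is a `HIGH` state, all singletons `LOW`, anything in
between `MEDIUM`. States aggregate to time shares (`share_high`,
`share_med`, `share_low`), which sum to one; this continuous encoding is
the minimal aggregation that lets all three states enter a regression
simultaneously. Timepoints with fewer than two alive members are excluded:
interdependence is undefined for a singleton.

States are additionally not evaluated once the play-circle radius falls
below three epsilons (300 m). At that scale every surviving team is a
single cluster *by construction* — the area itself enforces proximity — so
endgame timepoints carry no interdependence signal and would
systematically inflate the HIGH share of long-surviving (well-ranked)
teams. This guard is the state-level analogue of the distance
normalization below.

**Collaboration.** All `choose(n, 2)` pair distances are computed per
timepoint. Because the shrinking area mechanically compresses distances
late in the match, each distance is divided by the remaining-time fraction
(floored at 0.1) before a `log1p` transform:
`log1p(d / max(0.1, (T - t)/T))`. `log1p` rather than `log` keeps
coincident players finite. The per-timepoint maximum (dispersion,
`collab_low`) and minimum (tightness, `collab_high`) average over the
match; `collab_high <= collab_low` always. The per-timepoint SD of
normalized pair distances (`sd_dist`) feeds the match-level dispersion
control.

**Risk.** A reference heatmap counts parachute landings per 10 x 10 m cell
(816 x 816 cells on the 8 km maps, 408 and 204 on the smaller ones) over a
held-out cohort of 50,000 landings, so a team's own landings never count
toward their own risk. A landing's risk is its cell count; the team's
high/low landing risk are the member extremes. A cell is "high-risk" when
its count exceeds the median over nonzero cells (zero cells are empty
wilderness and would drag any quantile to zero). Overtime risk accumulates
10 s per sampled point a member spends in high- (or low-) risk cells,
taking the member maxima. In models the overtime pair enters as the
high-risk *fraction* `t_high / (t_high + t_low)`: the raw seconds sum to a
team's survival time, which within a match is the rank itself, so only the
mix carries non-circular information. The cohort-level risk category
discretizes overtime risk at quantile thresholds (median by default, which
makes the middle class a measure-zero tie set; `q_low = 1/3, q_high = 2/3`
gives three populated classes).

## Cohort preparation

Records join behavior, risk, rank, and experience (mean member season
rank points) per team-match. The Z-score filter drops any row further than
3 SD from a screened variable's mean, single-pass (means and SDs from the
input table, no re-estimation after drops) — the simplest reading, and the
one under which a hand-checkable report is possible. Conjoint experience
(players recurring on a team with the same teammates) is computed as
inclusive dyad/triad/quartet percentages over distinct players.
Experience strata come from 1-D K-means (`k = 3`, 10 restarts, fixed
seed), relabelled LOW/MEDIUM/HIGH by ascending center — the
stratification route to simple slopes of an experience-moderated effect.
Stratification operates on team-level mean experience: the published
stratum sizes this mirrors sum to the *team* count, so team-rows must be
the unit despite the word "players".

## The ordinal model

`rank_clm()` fits the proportional-odds cumulative-logit model

$$P(\mathrm{rank} \le j \mid x) = \mathrm{logit}^{-1}(\theta_j - x'\beta),
\qquad j = 1, \dots, J-1,$$

by maximum likelihood: BFGS with analytic gradients over an unconstrained
parameterization (first threshold plus log-increments, so thresholds stay
ordered), followed by damped Newton steps on a finite-difference Hessian
until the gradient RMS falls below `1e-6` per unit of average
log-likelihood (fits failing that are flagged, never silently returned).
Standard errors come from the observed information mapped through the
reparameterization jacobian. Rank ascends with *worse* placement, so a
negative coefficient means a better finish. The logit link is the default
for cumulative-link models and matches odds-style interpretation; fit
quality is summarized by the maximum-likelihood pseudo-R-squared
`r2ML = 1 - exp((2/n)(logL_0 - logL))`, and multicollinearity by
variance-inflation factors `1/(1 - R2_k)`.

Robustness fits: `fit_quadratic()` adds mean-centered squares (centering
decouples curvature from trend; an additive shift of a share leaves the
quadratic coefficient unchanged), `fit_interaction()` adds products with
standardized experience, `fit_logistic_topk()` replaces the ordinal
response with `rank <= k` in a binomial GLM, and `fit_stratified()`
refits per experience stratum.

**Inference across teams in a match.** Final ranks within one match are a
permutation of `1..25`: rows from the same match are dependent by
construction. Cohort-level fits treat rows as independent (as large-scale
analyses of this design do), but for stratified curvature inference
`moderation_summary()` uses match-cluster-robust (sandwich) standard
errors — an inference correction that accounts for the within-match
dependence without modelling it, not a random-effects model.

**Survival-coupled covariates.** The collaboration features trend with
the length of a team's feature window (the time-remaining normalization
up-weights late samples, and eliminated teams stop sampling early), so in
simulated cohorts they partly proxy survival itself — conditioning on
them suppresses any planted curvature. Descriptive fits keep the full
battery (`default_rank_formula()`); parameter-recovery analyses use
`default_rank_formula(collab = FALSE)`. This distinction is a property of
measurement in this design, not of the estimator.

## The match simulator

The generator gives every downstream stage ground truth. Its defaults are
the study conditions: 100 players in 25 teams of four, 10 s sampling,
square maps from 2 to 8 km, a circle that holds 300 s, contracts at
22.8 m/s, pauses 200 s at geometrically halving trigger diameters (the
live game's trigger values are not public; halving is the free-parameter
choice), and closes before the 30-minute cap.

*Landings.* Each team draws an anchor from a five-hotspot mixture with
probability equal to its landing-risk preference (uniform over the map
otherwise); members scatter around the anchor with the team's cohesion
sigma.

*Movement.* Team centroids follow a Gaussian random walk (6,000 cm per
10 s), reflected at map edges and projected back inside 90% of the
current circle. Members alternate between a *together* regime (Gaussian
offsets around the centroid, SD = cohesion sigma in 1,000–20,000 cm,
truncated at 3 sigma) and persistent split episodes (~30 s) in which the
squad either breaks into two tight pairs or scatters members at the
team's split distance (1.5–5 epsilons). How *often* a squad clusters
(`p_together`, uniform on 0.05–0.80) and how *tight* it is when clustered
(cohesion) vary independently — as they do in real squads — which keeps
the interdependence shares identifiable next to the collaboration
features. Movement is not pathfinding: the analysis consumes only
distances and cell occupancy, so controllable dispersion suffices.

*Experience.* Team mean experience is drawn from a three-component
mixture (means 0.013 / 3.358 / 4.914, weights ~61/22/17%) mirroring the
strata of large ranked-squad cohorts; member rank points scatter around
the team mean.

*Elimination.* Whole teams (the unit of analysis) are eliminated by a
per-10 s logistic hazard
`p = logit^{-1}(alpha + ramp(t) - pi)`, where the performance propensity

$$\pi = b_H s_H + b_M s_M + b_L s_L + (q_H + m_E z)\, s_H^2
      + b^{cl} c_{low} + b^{ch} c_{high} + b^{r} r + u$$

is built from the team's *running* features (shares, collaboration,
high-risk time fraction, all cumulative to the current interval),
standardized experience $z$, and a Gaussian frailty $u$ (SD 0.7,
unobserved skill). Defaults plant the headline pattern: $b_H = 2.4$,
$q_H = -2.6$ and $m_E = 1.611$ make performance an inverted-U in the HIGH
share for low-experience teams (peak around share 0.35) that flattens to
near-linear at the high-experience stratum mean, where
$q_H + m_E z \approx 0$. No eliminations occur during the initial 300 s
hold (the landing/looting phase — which also guarantees every team a
30+ timepoint feature window), and the baseline ramps up by 4 log-odds
from 1,100 s so matches resolve through combat rather than timing out
(surviving-at-cap ranking by hazard would otherwise order the best teams
deterministically and distort top-end curvature). Ranks follow reverse
elimination order; simultaneous eliminations break by team id, exact
hazard ties at the cap break at random.

## What the simulator does and does not emulate

It reproduces the statistical skeleton the analysis rests on: sampling
cadence and truncation at elimination, landing hotspots, circle geometry,
independent variation of clustering time and tightness, a planted
experience-moderated curvilinear rank dependence, outlier "hackers"
(teleporting members, behind `outlier_team_rate`), and moderate
explanatory power in the recovery specification (the full descriptive
battery explains more, since its collaboration terms partly track
survival). It has no combat,
loot, terrain, or pathfinding; collaboration features react to regime
switching, not to tactics; and experience influences outcomes only
through the planted moderation. Passing recovery tests therefore shows
the *pipeline* is consistent and the *estimator* unbiased under the
stated generative law — not that real squads obey that law.

## Numerical and design choices

- Thresholds are kept ordered by construction (log-increment
  parameterization); starting values come from empirical cumulative
  logits.
- The null log-likelihood has the closed form
  $\sum_j n_j \log(n_j/n)$ (free thresholds saturate the marginal), used
  directly.
- Quadratic terms are centered before squaring; reported curvature is
  therefore the coefficient on $(s - \bar s)^2$ and the implied
  performance peak is $\bar s - \beta_{lin}/(2\beta_{quad})$. An
  inverted-U whose peak sits near the observed mean share has a *centered*
  linear coefficient near zero — the uncentered linear coefficient
  (negative, opposite the curvature) is the parameterization in which the
  classic "negative linear, positive quadratic" table pattern appears.
- `simulate_match()` derives per-match seeds from the cohort seed by
  modular arithmetic in double precision (R integers are 32-bit).
- Degenerate inputs fail loudly: rank-deficient designs name the
  collinear terms, zero-variance moderators and undersized strata error,
  separation in top-k fits is flagged.
- Problem sizes in the validation suite: recovery replicates use
  2,000-team cohorts (80 matches); the test suite runs 20 such replicates
  and the acceptance script 50; null-calibration replicates use direct
  cumulative-logit draws at n = 600 — calibration concerns the estimator,
  and simulating ordinal data directly from the model under test is the
  cleanest null.

## Known limitations

- The proportional-odds assumption is imposed, not tested; the agent-based
  elimination process does not generate exactly proportional odds, which
  is visible as a small common curvature in large-sample fits.
- Conjoint-experience percentages are inclusive (a quartet player counts
  as dyadic too); exclusive percentages are recoverable by differencing.
- The strategy proxy (exploration / ambidexterity / exploitation from the
  high-risk time ratio) is a coarse stand-in for constructs that have no
  operational definition in telemetry; it is off by default.
- Real telemetry ingested through `read_telemetry()` must use the
  package's JSON-Lines dialect; no client for any game API is provided.
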