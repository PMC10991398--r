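# squadrank

Team behavioral interdependence, collaboration, risk taking, and
performance in squad-based battle-royale matches, from positional
telemetry to ordinal regression.

In a battle-royale match, 25 squads of four are dropped onto a square map
whose playable circle shrinks until one squad survives; the elimination
order is an ordinal performance outcome (final rank, 1 = winner). Because
players decide freely how close to their teammates they operate,
location telemetry sampled every 10 s measures team behavior directly.
squadrank is for computational behavioral scientists who want to study
team dynamics in this setting: it provides

- a validated JSON-Lines telemetry dialect (`read_telemetry()`,
  `write_telemetry()`);
- behavior features: interdependence states from DBSCAN/`min_pts = 1`
  clustering of teammates at a 100 m epsilon (HIGH = one cluster,
  LOW = all singletons, MEDIUM = in between), aggregated to time shares,
  plus normalized log pair-distance collaboration measures
  (`behavior_features()`);
- risk features: landing counts on a 10 x 10 m reference heatmap, team
  landing-risk extremes, time in high-/low-risk cells, cohort risk
  categories (`risk_features()`, `build_heatmap()`);
- cohort assembly with single-pass Z > 3 outlier filtering, match-level
  controls, conjoint-experience diagnostics, and K-means experience
  strata (`prepare_cohort()`);
- the core estimator: a proportional-odds cumulative-logit model of
  final rank,

  P(rank <= j | x) = logit^-1(theta_j - x'beta),

  fitted by maximum likelihood (`rank_clm()`, with `summary`, `coef`,
  `vcov`, `predict`, `residuals`, `plot`, `simulate` methods), plus
  quadratic, interaction, stratified, and binary top-k robustness fits,
  maximum-likelihood pseudo-R² and VIF diagnostics, and
  match-cluster-robust standard errors (`vcov_cluster()`);
- an agent-based match simulator with a shrinking play circle and a
  planted, experience-moderated curvilinear performance effect, so the
  whole pipeline can be validated against ground truth
  (`sim_config()`, `simulate_cohort()`).

Rank ascends with worse placement, so a negative coefficient means a
better finish.

## Worked example

Simulate a small cohort, extract features, and fit the stratified
curvature summary:

```r
library(squadrank)

cfg  <- sim_config(seed = 7, n_matches = 80)   # 2,000 teams, 8 km map
coh  <- simulate_cohort(cfg)
prep <- prepare_cohort(coh)
prep$strata
#> <stratum_assignment>
#>   stratum   center size
#> 1     LOW 0.174474 1157
#> 2  MEDIUM 3.375086  432
#> 3    HIGH 4.965339  306

fit <- rank_clm(default_rank_formula(), prep$records)
fit$r2_ml
#> [1] 0.6041592

moderation_summary(prep$records, min_n = 30)
#>   stratum    n        lin      quad       se          z            p    ci_low
#> 1     LOW 1157  0.3975997  4.551797 1.027785  4.4287448 9.478310e-06  2.537376
#> 2  MEDIUM  432 -1.6444337  4.074958 1.403845  2.9027118 3.699469e-03  1.323472
#> 3    HIGH  306 -1.2295510 -1.681869 1.967718 -0.8547306 3.927003e-01 -5.538526
#>    ci_high        peak
#> 1 6.566218  0.20955439
#> 2 6.826445  0.45112738
#> 3 2.174788 -0.08999656
```

The stratum centers land on the experience mixture the simulator plants
(0.013 / 3.358 / 4.914, pulled slightly together by within-cluster
spread). The LOW-experience stratum shows a significant positive
quadratic on the rank scale with its implied performance peak at share
~0.21 — an inverted-U: inexperienced squads gain from clustering up to a
point and lose beyond it. The HIGH-experience stratum's quadratic
interval covers zero: experienced squads gain from interdependence
roughly linearly. Coefficients are on the latent cumulative-logit scale;
`predict(fit, type = "expected")` converts to expected rank. (The full
descriptive fit's r2ML of 0.60 includes the survival-coupled
collaboration terms; the stratified recovery fits exclude them — see the
methods vignette.)

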