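# Independent brute-force likelihood for a cumulative-logit model with one
# predictor and 3 response levels: coarse-to-fine grid over (theta1, delta,
# beta). Shares no code with the rank_clm optimizer.
grid_loglik_max <- function(y, x) {
  ll <- function(t1, dl, b) {
    th <- c(t1, t1 + dl)
    eta <- b * x
    up <- c(th, Inf)[y] - eta
    lo <- c(-Inf, th)[y] - eta
    sum(log(pmax(plogis(up) - plogis(lo), 1e-300)))
  }
  best <- c(0, 1, 0)
  width <- c(4, 4, 4)
  for (round_ in 1:6) {
    g1 <- seq(best[1] - width[1], best[1] + width[1], length.out = 11)
    g2 <- seq(max(0.01, best[2] - width[2]), best[2] + width[2],
              length.out = 11)
    g3 <- seq(best[3] - width[3], best[3] + width[3], length.out = 11)
    vals <- expand.grid(t1 = g1, dl = g2, b = g3)
    lls <- mapply(ll, vals$t1, vals$dl, vals$b)
    best <- as.numeric(vals[which.max(lls), ])
    width <- width / 4
  }
  ll(best[1], best[2], best[3])
}
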