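## Proportional-odds cumulative-link model for ordinal match rank.
##
## P(rank <= j | x) = logistic(theta_j - x'beta), j = 1..J-1, with strictly
## increasing thresholds theta and slopes beta shared across thresholds.
## Rank 1 is the winner, so a NEGATIVE coefficient means better placement.
## The likelihood is maximized by quasi-Newton (BFGS) with analytic
## gradients over an unconstrained parameterization (first threshold plus
## log-increments), which keeps the thresholds ordered by construction.

.clm_unpack <- function(par, J, p) {
  nth <- J - 1L
  z1 <- par[1L]
  theta <- if (nth > 1L) cumsum(c(z1, exp(par[2:nth]))) else z1
  beta <- if (p > 0L) par[nth + seq_len(p)] else numeric(0)
  list(theta = theta, beta = beta)
}

.clm_nll <- function(par, y, X, J) {
  p <- ncol(X)
  u <- .clm_unpack(par, J, p)
  eta <- if (p > 0L) drop(X %*% u$beta) else rep(0, length(y))
  upper <- c(u$theta, Inf)[y] - eta
  lower <- c(-Inf, u$theta)[y] - eta
  P <- pmax(stats::plogis(upper) - stats::plogis(lower), 1e-300)
  -sum(log(P))
}

.clm_grad <- function(par, y, X, J) {
  p <- ncol(X)
  nth <- J - 1L
  u <- .clm_unpack(par, J, p)
  eta <- if (p > 0L) drop(X %*% u$beta) else rep(0, length(y))
  upper <- c(u$theta, Inf)[y] - eta
  lower <- c(-Inf, u$theta)[y] - eta
  Fu <- stats::plogis(upper); Fl <- stats::plogis(lower)
  P <- pmax(Fu - Fl, 1e-300)
  fu <- stats::dlogis(upper); fu[!is.finite(upper)] <- 0
  fl <- stats::dlogis(lower); fl[!is.finite(lower)] <- 0
  g_theta <- numeric(nth)
  au <- fu / P; al <- fl / P
  for (j in seq_len(nth)) {
    g_theta[j] <- -(sum(au[y == j]) - sum(al[y == j + 1L]))
  }
  g_par <- numeric(length(par))
  g_par[1L] <- sum(g_theta)
  if (nth > 1L) {
    rev_cum <- rev(cumsum(rev(g_theta)))
    g_par[2:nth] <- exp(par[2:nth]) * rev_cum[2:nth]
  }
  if (p > 0L) {
    g_par[nth + seq_len(p)] <- -drop(crossprod(X, (fl - fu) / P))
  }
  g_par
}

#' Fit a proportional-odds cumulative-link model to match ranks
#'
#' Maximum-likelihood cumulative-logit regression
#' `P(rank <= j | x) = plogis(theta_j - x'beta)` of an ordinal response
#' (final match rank, 1 = winner, ascending = worse) on team features.
#' Under this orientation a negative coefficient is associated with a
#' higher (better) placement.
#'
#' @param formula Model formula; the response may be an integer rank or an
#'   ordered factor with at least 3 levels. No intercept is fitted (the
#'   thresholds absorb it).
#' @param data Data frame.
#' @param control List: `maxit` (default 500), `reltol` (default 1e-12),
#'   `grad_tol` (gradient-norm convergence check, default 1e-6 per
#'   parameter scale).
#' @return Object of class `rank_clm` with components `coefficients`,
#'   `thresholds` (strictly increasing), `vcov`, `logLik`, `logLik_null`,
#'   `n`, `levels`, `converged`, `r2_ml`, plus the pieces needed by the
#'   methods (`terms`, `xlevels`, model frame).
#' @seealso [r2_ml()], [vif()], [fit_stratified()], [fit_quadratic()],
#'   [fit_interaction()], [fit_logistic_topk()]
#' @examples
#' d <- data.frame(rank = rep(1:5, each = 20), x = rnorm(100))
#' f <- rank_clm(rank ~ x, d)
#' coef(f)
#' @export
rank_clm <- function(formula, data, control = list()) {
  ctl <- utils::modifyList(list(maxit = 500L, reltol = 1e-12,
                                grad_tol = 1e-6), control)
  mf <- stats::model.frame(formula, data, drop.unused.levels = TRUE,
                           na.action = stats::na.omit)
  yraw <- stats::model.response(mf)
  if (is.ordered(yraw)) {
    lev <- levels(yraw)
    y <- as.integer(yraw)
  } else {
    lev <- as.character(sort(unique(yraw)))
    y <- match(as.character(yraw), lev)
  }
  J <- length(lev)
  if (J < 3L) stop("rank_clm: response must take >= 3 ordered levels")
  mt <- attr(mf, "terms")
  X <- stats::model.matrix(mt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  p <- ncol(X)
  if (p > 0L) {
    zv <- apply(X, 2, stats::sd) == 0
    if (any(zv)) {
      stop("rank_clm: zero-variance term(s): ",
           paste(colnames(X)[zv], collapse = ", "))
    }
    qx <- qr(cbind(1, X))
    if (qx$rank < p + 1L) {
      drop_idx <- qx$pivot[(qx$rank + 1L):(p + 1L)] - 1L
      stop("rank_clm: design is rank-deficient; collinear term(s): ",
           paste(colnames(X)[drop_idx[drop_idx > 0]], collapse = ", "))
    }
  }
  n <- length(y)
  ## null log-likelihood: thresholds free, MLE = empirical category shares
  tab <- tabulate(y, nbins = J)
  logl_null <- sum(tab[tab > 0] * log(tab[tab > 0] / n))
  ## starting values from empirical cumulative logits
  cum <- cumsum(tab)[1:(J - 1L)] / n
  cum <- pmin(pmax(cum, 1 / (2 * n)), 1 - 1 / (2 * n))
  th0 <- stats::qlogis(cum)
  th0 <- cummax(th0 + seq_len(J - 1L) * 1e-9)
  par0 <- c(th0[1L],
            if (J > 2L) log(pmax(diff(th0), 1e-6)),
            rep(0, p))
  opt <- stats::optim(par0, .clm_nll, .clm_grad, y = y, X = X, J = J,
                      method = "BFGS",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  npar <- length(opt$par)
  fdhess <- function(par) {
    H <- matrix(NA_real_, npar, npar)
    h <- pmax(1e-6, 1e-6 * abs(par))
    for (k in seq_len(npar)) {
      pp <- par; pm <- par
      pp[k] <- pp[k] + h[k]; pm[k] <- pm[k] - h[k]
      H[, k] <- (.clm_grad(pp, y, X, J) - .clm_grad(pm, y, X, J)) / (2 * h[k])
    }
    (H + t(H)) / 2
  }
  ## Newton polish: BFGS with reltol stops with gradient norms around 1e-4;
  ## a few damped Newton steps push the gradient to machine-level zero.
  par <- opt$par
  val <- opt$value
  gtol <- ctl$grad_tol * max(1, abs(val) / n)
  H <- fdhess(par)
  for (it in 1:25) {
    gr <- .clm_grad(par, y, X, J)
    if (sqrt(mean(gr^2)) < gtol) break
    if (it %% 8 == 0L) H <- fdhess(par)
    step <- tryCatch(solve(H, gr), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      cand <- par - lam * step
      vc <- .clm_nll(cand, y, X, J)
      if (vc <= val + 1e-12) { par <- cand; val <- vc; break }
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    if (lam < 1e-8) break
  }
  if (any(par != opt$par)) H <- fdhess(par)
  opt$par <- par; opt$value <- val
  gr <- .clm_grad(opt$par, y, X, J)
  converged <- sqrt(mean(gr^2)) < gtol
  if (!converged) {
    warning("rank_clm: optimizer did not converge cleanly; fit is flagged")
  }
  u <- .clm_unpack(opt$par, J, p)
  ## observed information on the natural (theta, beta) scale: Hessian of the
  ## negative log-likelihood in the transformed space mapped through the
  ## (z1, log-diff) reparameterization jacobian (delta method)
  nth <- J - 1L
  ## jacobian d(theta, beta)/d(par)
  Jac <- diag(npar)
  if (nth > 1L) {
    for (j in 2:nth) for (k in 2:j) Jac[j, k] <- exp(opt$par[k])
    for (j in 1:nth) Jac[j, 1] <- 1
    Jac[1, 1] <- 1
    if (nth > 1L) for (j in 1:nth) for (k in 2:nth) {
      if (k > j) Jac[j, k] <- 0
    }
  }
  V_par <- tryCatch(solve(H), error = function(e) matrix(NA_real_, npar, npar))
  V <- Jac %*% V_par %*% t(Jac)
  nm <- c(paste0("theta_", 1:(J - 1L)), colnames(X))
  dimnames(V) <- list(nm, nm)
  beta <- setNames(u$beta, colnames(X))
  logl <- -opt$value
  fit <- structure(list(
    coefficients = beta,
    thresholds = setNames(u$theta, paste0("theta_", 1:(J - 1L))),
    vcov = V,
    logLik = logl,
    logLik_null = logl_null,
    n = n,
    levels = lev,
    converged = converged,
    r2_ml = r2_ml(logl_null, logl, n),
    terms = mt,
    formula = formula,
    xlevels = stats::.getXlevels(mt, mf),
    y = y,
    X = X,
    call = match.call()), class = "rank_clm")
  fit
}

#' Maximum-likelihood pseudo-R-squared
#'
#' `1 - exp((2/n) * (logL_null - logL_model))`, in `[0, 1)`; 0 when the
#' model adds nothing over the null, approaching 1 for a perfect fit.
#'
#' @param logl_null Null-model log-likelihood.
#' @param logl_model Fitted-model log-likelihood (`>= logl_null`).
#' @param n Number of observations.
#' @return A number in `[0, 1)`.
#' @export
r2_ml <- function(logl_null, logl_model, n) {
  if (n <= 0) stop("r2_ml: n must be positive")
  1 - exp((2 / n) * (logl_null - logl_model))
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` comes from regressing column `k`
#' on the remaining columns (with intercept). Perfectly collinear columns
#' report `Inf`.
#'
#' @param X Numeric matrix (>= 2 columns, each with positive variance).
#' @return Named vector of VIFs (each >= 1).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("vif: need >= 2 columns")
  if (any(apply(X, 2, stats::sd) == 0)) stop("vif: zero-variance column")
  out <- vapply(seq_len(ncol(X)), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, k] - mean(X[, k]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, colnames(X))
}

## ---- methods -------------------------------------------------------------

#' @export
print.rank_clm <- function(x, ...) {
  cat("Cumulative-link (proportional-odds) rank model\n")
  cat("  levels:", length(x$levels), " n:", x$n,
      " logLik:", format(x$logLik, digits = 6),
      " r2ML:", format(x$r2_ml, digits = 3), "\n")
  if (length(x$coefficients)) {
    cat("Coefficients (negative = better placement):\n")
    print(round(x$coefficients, 4))
  } else cat("(intercept-only model)\n")
  invisible(x)
}

#' @export
coef.rank_clm <- function(object, ...) object$coefficients

#' @export
vcov.rank_clm <- function(object, ...) {
  p <- length(object$coefficients)
  if (p == 0L) return(object$vcov)
  idx <- length(object$thresholds) + seq_len(p)
  object$vcov[idx, idx, drop = FALSE]
}

#' @export
logLik.rank_clm <- function(object, ...) {
  structure(object$logLik,
            df = length(object$thresholds) + length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
nobs.rank_clm <- function(object, ...) object$n

#' Summary of a rank_clm fit
#'
#' @param object A [rank_clm()] fit.
#' @param level Confidence level for Wald intervals (default 0.95).
#' @param ... Unused.
#' @return A `summary.rank_clm` with a coefficient table (estimate, SE,
#'   z, p, CI) and fit statistics.
#' @export
summary.rank_clm <- function(object, level = 0.95, ...) {
  b <- object$coefficients
  V <- vcov(object)
  se <- sqrt(diag(V))
  z <- b / se
  pval <- 2 * stats::pnorm(-abs(z))
  q <- stats::qnorm(1 - (1 - level) / 2)
  tab <- cbind(Estimate = b, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = pval, lwr = b - q * se, upr = b + q * se)
  structure(list(coefficients = tab, thresholds = object$thresholds,
                 logLik = object$logLik, logLik_null = object$logLik_null,
                 r2_ml = object$r2_ml, n = object$n,
                 converged = object$converged, level = level,
                 call = object$call),
            class = "summary.rank_clm")
}

#' @export
print.summary.rank_clm <- function(x, ...) {
  cat("Cumulative-link (proportional-odds) rank model\n")
  cat("n =", x$n, " logLik =", format(x$logLik, digits = 7),
      " null =", format(x$logLik_null, digits = 7),
      " r2ML =", format(x$r2_ml, digits = 4), "\n")
  if (!x$converged) cat("** fit flagged: optimizer did not converge **\n")
  if (nrow(x$coefficients)) {
    stars <- stats::symnum(x$coefficients[, "Pr(>|z|)"], corr = FALSE, na = FALSE,
                    cutpoints = c(0, 0.01, 0.05, 0.1, 1),
                    symbols = c("***", "**", "*", " "))
    tab <- data.frame(round(x$coefficients, 4), sig = format(stars))
    print(tab)
    cat("Signif.: *p<0.1 **p<0.05 ***p<0.01\n")
  }
  invisible(x)
}

#' Predict from a rank_clm fit
#'
#' @param object A [rank_clm()] fit.
#' @param newdata Data frame (default: training data).
#' @param type `"probs"` (n x J matrix of class probabilities),
#'   `"expected"` (expected rank `sum_j j P(rank = j)`), or `"class"`
#'   (modal rank level).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.rank_clm <- function(object, newdata = NULL,
                             type = c("probs", "expected", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- object$X
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  }
  eta <- if (length(object$coefficients))
    drop(X %*% object$coefficients) else rep(0, nrow(X))
  J <- length(object$levels)
  Fm <- vapply(object$thresholds, function(th) stats::plogis(th - eta),
               numeric(length(eta)))
  Fm <- cbind(matrix(Fm, ncol = J - 1L), 1)
  P <- cbind(Fm[, 1L, drop = FALSE],
             Fm[, -1L, drop = FALSE] - Fm[, -J, drop = FALSE])
  colnames(P) <- object$levels
  switch(type,
         probs = P,
         expected = drop(P %*% seq_len(J)),
         class = object$levels[max.col(P)])
}

#' @export
fitted.rank_clm <- function(object, ...) predict(object, type = "expected")

#' @export
residuals.rank_clm <- function(object, ...) {
  object$y - predict(object, type = "expected")
}

#' Simulate ranks from a fitted (or constructed) cumulative-logit model
#'
#' @param object A [rank_clm()] fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param newdata Optional data frame of covariates.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated rank indices
#'   (1-based level index).
#' @export
simulate.rank_clm <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  P <- predict(object, newdata = newdata, type = "probs")
  n <- nrow(P)
  out <- replicate(nsim, {
    u <- stats::runif(n)
    cum <- t(apply(P, 1, cumsum))
    as.integer(rowSums(u > cum) + 1L)
  })
  as.data.frame(matrix(out, nrow = n,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

#' Draw ordinal responses from a cumulative-logit law
#'
#' Ground-truth generator for calibration and parameter-recovery studies:
#' given a linear predictor and thresholds, draws
#' `P(y <= j) = plogis(theta_j - eta)`.
#'
#' @param eta Linear predictor vector.
#' @param thresholds Increasing threshold vector (length J - 1).
#' @return Integer responses in `1..J`.
#' @export
rclm_draw <- function(eta, thresholds) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("rclm_draw: thresholds must be strictly increasing")
  }
  n <- length(eta)
  Fm <- vapply(thresholds, function(th) stats::plogis(th - eta), numeric(n))
  Fm <- cbind(matrix(Fm, ncol = length(thresholds)), 1)
  u <- stats::runif(n)
  as.integer(rowSums(u > Fm) + 1L)
}

#' Match-cluster-robust covariance for a rank_clm fit
#'
#' Within a match the final ranks are a permutation of `1..n_teams`:
#' team-match rows from the same match are dependent by construction, so
#' model-based standard errors understate the sampling variability of
#' coefficients when cohorts contain many teams per match. This sandwich
#' estimator aggregates score contributions by cluster (match) with the
#' usual `G/(G-1)` small-sample factor; point estimates are untouched.
#'
#' @param fit A [rank_clm()] fit.
#' @param cluster Vector of cluster ids (e.g. `match_id`), one per row used
#'   in the fit.
#' @return Covariance matrix of the slope coefficients.
#' @export
vcov_cluster <- function(fit, cluster) {
  cluster <- as.character(cluster)
  if (length(cluster) != fit$n) {
    stop("vcov_cluster: cluster length ", length(cluster),
         " does not match n = ", fit$n)
  }
  y <- fit$y; X <- fit$X
  J <- length(fit$levels)
  theta <- fit$thresholds
  eta <- if (length(fit$coefficients)) drop(X %*% fit$coefficients) else
    rep(0, length(y))
  upper <- c(theta, Inf)[y] - eta
  lower <- c(-Inf, theta)[y] - eta
  Fu <- stats::plogis(upper); Fl <- stats::plogis(lower)
  P <- pmax(Fu - Fl, 1e-300)
  fu <- stats::dlogis(upper); fu[!is.finite(upper)] <- 0
  fl <- stats::dlogis(lower); fl[!is.finite(lower)] <- 0
  ## per-observation scores of the log-likelihood wrt (theta, beta)
  nth <- J - 1L
  n <- length(y)
  S <- matrix(0, n, nth + ncol(X))
  au <- fu / P; al <- fl / P
  for (j in seq_len(nth)) {
    S[y == j, j] <- au[y == j]
    S[y == j + 1L, j] <- S[y == j + 1L, j] - al[y == j + 1L]
  }
  if (ncol(X)) {
    S[, nth + seq_len(ncol(X))] <- X * ((fl - fu) / P)
  }
  Sg <- rowsum(S, cluster)
  meat <- crossprod(Sg)
  G <- nrow(Sg)
  V <- fit$vcov %*% meat %*% fit$vcov * G / (G - 1)
  dimnames(V) <- dimnames(fit$vcov)
  p <- length(fit$coefficients)
  idx <- nth + seq_len(p)
  V[idx, idx, drop = FALSE]
}

#' Plot predicted vs observed ranks
#'
#' Binned calibration of expected rank against observed rank.
#'
#' @param x A [rank_clm()] fit.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the per-observed-rank mean expected rank.
#' @export
plot.rank_clm <- function(x, ...) {
  pv <- predicted_vs_observed(x)
  graphics::plot(pv$summary$observed, pv$summary$mean_expected,
                 xlab = "observed rank", ylab = "mean expected rank",
                 main = "Predicted vs observed", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(pv$summary)
}

#' Predicted-vs-observed table for a rank model
#'
#' Per observation the observed rank and the model-expected rank
#' `sum_j j P(rank = j | x)`, plus a per-observed-rank calibration summary.
#'
#' @param fit A [rank_clm()] fit.
#' @param newdata Optional data (default: training data; must then contain
#'   the response).
#' @return List: `table` (`observed`, `expected` per row) and `summary`
#'   (`observed`, `mean_expected`, `n` per observed level).
#' @export
predicted_vs_observed <- function(fit, newdata = NULL) {
  if (is.null(newdata)) {
    obs <- fit$y
    expd <- predict(fit, type = "expected")
  } else {
    mf <- stats::model.frame(fit$terms, newdata, xlev = fit$xlevels)
    yraw <- stats::model.response(mf)
    obs <- if (is.ordered(yraw)) as.integer(yraw) else
      match(as.character(yraw), fit$levels)
    expd <- predict(fit, newdata = newdata, type = "expected")
  }
  tab <- data.frame(observed = obs, expected = expd)
  agg <- stats::aggregate(expected ~ observed, data = tab, FUN = mean)
  names(agg)[2] <- "mean_expected"
  agg$n <- as.integer(table(factor(obs, levels = sort(unique(obs)))))
  list(table = tab, summary = agg)
}
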