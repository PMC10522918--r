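# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and survival:: where the package
# already delegates to it).

# Product-limit estimator by direct product over distinct event times.
km_hand <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    d <- sum(time == ut[i] & event == 1)
    r <- sum(time >= ut[i])
    s <- s * (1 - d / r)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}

# Empirical ROC AUC (Mann-Whitney with ties at 1/2) of marker vs binary status.
empirical_auc <- function(marker, status) {
  pos <- marker[status == 1]
  neg <- marker[status == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Log-rank chi-square by direct O-E computation with hypergeometric variance
# (two groups, no ties assumed between groups at the same time are fine).
logrank_hand <- function(group, time, event) {
  g <- as.integer(factor(group)) - 1L  # 0/1
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (tt in ut) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g == 1L)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Efron partial log-likelihood for a single covariate (continuous or 0/1).
efron_loglik <- function(beta, x, time, event) {
  eta <- beta * x
  w <- exp(eta)
  ll <- 0
  for (tt in unique(time[event == 1])) {
    dead <- which(time == tt & event == 1)
    risk <- which(time >= tt)
    d <- length(dead)
    sum_risk <- sum(w[risk])
    sum_dead <- sum(w[dead])
    ll <- ll + sum(eta[dead])
    for (l in seq_len(d) - 1L)
      ll <- ll - log(sum_risk - (l / d) * sum_dead)
  }
  ll
}

# Grid-search maximizer of the Efron partial likelihood to +-tol.
efron_grid_beta <- function(x, time, event, lo = -5, hi = 5, tol = 1e-5) {
  f <- function(b) efron_loglik(b, x, time, event)
  stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)$maximum
}

# Exhaustive constrained-Youden oracle over midpoint cutoffs with the
# KM-weighted sensitivity/specificity definitions computed from scratch.
cutoff_oracle <- function(marker, time, event, horizon, min_group_frac) {
  km_at <- function(tt, ee, h) {
    ut <- sort(unique(tt[ee == 1 & tt <= h]))
    s <- 1
    for (u in ut) s <- s * (1 - sum(tt == u & ee == 1) / sum(tt >= u))
    s
  }
  n <- length(marker)
  s_all <- km_at(time, event, horizon)
  ux <- sort(unique(marker))
  cuts <- (ux[-1] + ux[-length(ux)]) / 2
  k_min <- ceiling(min_group_frac * n)
  best <- NULL
  for (cu in cuts) {
    hi <- marker > cu
    if (sum(hi) < k_min || sum(!hi) < k_min) next
    p <- mean(hi)
    sh <- km_at(time[hi], event[hi], horizon)
    sens <- min(max((1 - sh) * p / (1 - s_all), 0), 1)
    spec <- 1 - min(max(sh * p / s_all, 0), 1)
    j <- sens + spec - 1
    cand <- list(cutoff = cu, j = j)
    if (is.null(best) || j > best$j + 1e-9) best <- cand
    else if (abs(j - best$j) <= 1e-9 &&
             abs(cu - median(marker)) < abs(best$cutoff - median(marker)) - 1e-12)
      best <- cand
  }
  best
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
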