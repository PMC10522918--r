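#' Kaplan-Meier product-limit estimate
#'
#' Wraps `survival::survfit` for a single arm and returns the step function
#' together with risk/event tables and the median survival (smallest t with
#' S(t) <= 0.5, or `NA` when not reached).
#'
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicators.
#' @return Object of class `km_fit` with elements `time`, `surv`, `n_risk`,
#'   `n_event`, `n`, `median`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (any(time < 0)) stop("times must be >= 0")
  if (all(time == 0)) stop("no risk time")
  f <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- f$time[f$surv <= 0.5 + 1e-12]
  structure(list(time = f$time, surv = f$surv, n_risk = f$n.risk,
                 n_event = f$n.event, n = length(time),
                 median = if (length(med)) min(med) else NA_real_),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier step function
#' @param km A `km_fit`.
#' @param t Time points (S(0) = 1; right-continuous).
#' @return Survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    idx <- which(km$time <= tt)
    if (!length(idx)) 1 else km$surv[max(idx)]
  }, numeric(1))
}

# Fast KM survival at a single horizon for a membership subset of a cohort
# whose times are already sorted ascending. Risk sets put censored ties at
# the same time still at risk (standard product-limit convention).
.km_at_sorted <- function(tt, ev, h, keep = NULL) {
  if (!is.null(keep)) { tt <- tt[keep]; ev <- ev[keep] }
  n2 <- length(tt)
  if (!n2) return(NA_real_)
  is_ev <- ev == 1L & tt <= h
  if (!any(is_ev)) return(1)
  te <- tt[is_ev]
  u <- te[!duplicated(te)]
  d <- tabulate(match(te, u))
  r <- n2 - match(u, tt) + 1L
  prod(1 - d / r)
}

#' Log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' (via `survival::survdiff`), chi-square with (groups - 1) degrees of
#' freedom, two-sided p-value.
#'
#' @param group Group labels (>= 2 non-empty groups).
#' @param time,event Survival endpoint.
#' @return List with `chisq`, `df`, `p`, `n`, `obs`, `exp`.
#' @export
logrank_test <- function(group, time, event) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("log-rank requires >= 2 non-empty groups")
  if (sum(event) < 1) stop("log-rank requires >= 1 event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = as.vector(sd$n), obs = as.vector(sd$obs), exp = as.vector(sd$exp))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided comparison of two independent samples; returns the U statistic
#' for `x` and the p-value (exact for small untied samples, normal
#' approximation with continuity correction otherwise).
#'
#' @param x,y Numeric vectors (non-empty).
#' @return List with `u`, `p`, `n1`, `n2`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(u = unname(wt$statistic), p = wt$p.value,
       n1 = length(x), n2 = length(y))
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration, two-sided p-value, conditional
#' maximum-likelihood odds ratio.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List with `odds_ratio`, `p`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}
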