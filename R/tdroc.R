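# Censoring-aware time-dependent ROC (cumulative cases / dynamic controls).
#
# Cases at horizon h are subjects with an event by h; controls are subjects
# event-free past h. Censoring before h is handled by Kaplan-Meier weighting:
# for a cutoff c with high group {marker > c} of empirical mass p_c and KM
# survival S_c(h) within that group, and overall KM survival S(h),
#   sensitivity(c) = (1 - S_c(h)) p_c / (1 - S(h))
#   1 - specificity(c) = S_c(h) p_c / S(h).
# Raw KM-based estimates need not be monotone in c; an isotonic
# (least-squares monotone) adjustment along cutoffs is applied when violated.
# With no censoring before h this reduces exactly to the empirical ROC of
# marker vs binary status-at-horizon.

# Sorted-by-time context shared by every marker evaluated in one cohort.
.roc_ctx <- function(time, event, horizon) {
  stopifnot(horizon > 0)
  ord <- order(time)
  tt <- time[ord]
  ev <- as.integer(event[ord])
  s_all <- .km_at_sorted(tt, ev, horizon)
  list(ord = ord, tt = tt, ev = ev, horizon = horizon, s_all = s_all,
       n = length(tt))
}

# Core curve computation for one marker against a prepared context.
# Returns candidate cutoffs (midpoints of consecutive distinct marker
# values), clamped/repaired sensitivity and specificity, high-group sizes,
# and the trapezoidal AUC with (0,0)/(1,1) endpoints appended.
.td_roc_core <- function(marker, ctx) {
  ux <- sort(unique(marker))
  if (length(ux) < 2) stop("uninformative marker (constant)")
  if (!any(ctx$ev == 1L & ctx$tt <= ctx$horizon))
    stop("no estimable cases at horizon")
  if (!is.finite(ctx$s_all) || ctx$s_all <= 0)
    stop("no estimable controls at horizon")
  cuts <- (ux[-1] + ux[-length(ux)]) / 2
  x <- marker[ctx$ord]
  n <- ctx$n
  k <- length(cuts)
  sens <- fpr <- numeric(k)
  n_high <- integer(k)
  for (i in seq_len(k)) {
    m <- x > cuts[i]
    nh <- sum(m)
    n_high[i] <- nh
    p <- nh / n
    sh <- .km_at_sorted(ctx$tt, ctx$ev, ctx$horizon, m)
    sens[i] <- (1 - sh) * p / (1 - ctx$s_all)
    fpr[i] <- sh * p / ctx$s_all
  }
  sens <- pmin(pmax(sens, 0), 1)
  fpr <- pmin(pmax(fpr, 0), 1)
  # both must be nonincreasing in the cutoff; repair by isotonic fit
  repaired <- FALSE
  if (k > 1 && is.unsorted(rev(sens), strictly = FALSE)) {
    sens <- rev(stats::isoreg(seq_len(k), rev(sens))$yf)
    repaired <- TRUE
  }
  if (k > 1 && is.unsorted(rev(fpr), strictly = FALSE)) {
    fpr <- rev(stats::isoreg(seq_len(k), rev(fpr))$yf)
    repaired <- TRUE
  }
  fx <- c(0, rev(fpr), 1)
  sy <- c(0, rev(sens), 1)
  auc <- sum(diff(fx) * (sy[-1] + sy[-length(sy)]) / 2)
  list(cuts = cuts, sens = sens, spec = 1 - fpr, n_high = n_high,
       auc = auc, repaired = repaired)
}

#' Time-dependent ROC curve at a fixed horizon
#'
#' Cumulative/dynamic survival ROC with Kaplan-Meier handling of censoring
#' before the horizon (see the methods vignette for the estimator). Candidate
#' cutoffs are midpoints between consecutive distinct marker values; the high
#' group is `marker > cutoff`, so the curve is invariant to within-group
#' value jitter and to any strictly increasing marker transform.
#'
#' @param marker Numeric marker (e.g. one gene's expression); must not be
#'   constant.
#' @param time,event Right-censored endpoint.
#' @param horizon Evaluation time in the same units as `time`.
#' @return Object of class `td_roc`: `horizon`, `points` (data frame with
#'   `cutoff`, `sensitivity`, `specificity`, `n_high`, ordered by cutoff),
#'   `auc`, KM-weighted effective `n_cases`/`n_controls`, and `repaired`
#'   (whether the isotonic adjustment fired).
#' @export
td_roc <- function(marker, time, event, horizon) {
  stopifnot(length(marker) == length(time), length(time) == length(event))
  ctx <- .roc_ctx(time, event, horizon)
  core <- .td_roc_core(marker, ctx)
  structure(list(
    horizon = horizon,
    points = data.frame(cutoff = core$cuts, sensitivity = core$sens,
                        specificity = core$spec, n_high = core$n_high),
    auc = core$auc,
    n_cases = ctx$n * (1 - ctx$s_all),
    n_controls = ctx$n * ctx$s_all,
    repaired = core$repaired
  ), class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat("<td_roc> horizon ", x$horizon, ": AUC = ", round(x$auc, 4),
      " (", nrow(x$points), " cutoffs; effective cases ",
      round(x$n_cases, 1), ", controls ", round(x$n_controls, 1), ")\n",
      sep = "")
  invisible(x)
}

# Constrained Youden selection over a computed core curve.
# Returns NULL when no candidate cutoff keeps both groups at or above
# ceiling(min_group_frac * n).
.choose_cutoff <- function(core, n, min_group_frac, med) {
  k_min <- ceiling(min_group_frac * n)
  n_low <- n - core$n_high
  feasible <- core$n_high >= k_min & n_low >= k_min
  if (!any(feasible)) return(NULL)
  j <- core$sens + core$spec - 1
  j[!feasible] <- -Inf
  jmax <- max(j)
  tied <- which(j >= jmax - 1e-9)
  tie_broken <- length(tied) > 1
  if (tie_broken) {
    d <- abs(core$cuts[tied] - med)
    tied <- tied[d <= min(d) + 1e-12]
    idx <- tied[which.min(core$cuts[tied])]  # distance tie -> smaller cutoff
  } else idx <- tied
  list(cutoff = core$cuts[idx], youden = core$sens[idx] + core$spec[idx] - 1,
       sens = core$sens[idx], spec = core$spec[idx],
       group_sizes = c(n_low = n_low[idx], n_high = core$n_high[idx]),
       tie_broken = tie_broken, index = idx)
}

#' Optimal constrained dichotomization cutoff
#'
#' Among candidate cutoffs whose low and high groups both retain at least
#' `ceiling(min_group_frac * n)` samples, returns the cutoff maximizing
#' Youden's J (sensitivity + specificity - 1) at the horizon. Ties within
#' 1e-9 are broken toward the cutoff closest to the marker median; a
#' remaining distance tie takes the smaller cutoff.
#'
#' @inheritParams td_roc
#' @param min_group_frac Minimum group fraction in (0, 0.5].
#' @return Object of class `cutoff_choice`: `cutoff`, `youden`, `sensitivity`,
#'   `specificity`, `group_sizes` (low, high), `satisfied_constraint`,
#'   `tie_broken`.
#' @export
optimal_cutoff <- function(marker, time, event, horizon, min_group_frac = 0.20) {
  stopifnot(min_group_frac > 0, min_group_frac <= 0.5)
  ctx <- .roc_ctx(time, event, horizon)
  core <- .td_roc_core(marker, ctx)
  ch <- .choose_cutoff(core, ctx$n, min_group_frac, stats::median(marker))
  if (is.null(ch))
    stop("constraint infeasible: no cutoff keeps both groups at ",
         ceiling(min_group_frac * ctx$n), " samples")
  structure(list(cutoff = ch$cutoff, youden = ch$youden,
                 sensitivity = ch$sens, specificity = ch$spec,
                 group_sizes = ch$group_sizes, satisfied_constraint = TRUE,
                 tie_broken = ch$tie_broken),
            class = "cutoff_choice")
}

# Risk-oriented dichotomization of a marker: when the raw AUC is below 0.5
# (high marker protective), the cutoff search runs on the negated marker so
# Youden's J is meaningful; the returned indicator always flags the
# high-EXPRESSION group, and `flipped` records the orientation. Returns NULL
# fields with feasible = FALSE instead of erroring (batch screening must not
# abort on one degenerate marker).
.dichotomize_risk <- function(marker, ctx, min_group_frac, allow_flip = TRUE) {
  core_raw <- tryCatch(.td_roc_core(marker, ctx), error = function(e) e)
  if (inherits(core_raw, "error"))
    return(list(feasible = FALSE, reason = conditionMessage(core_raw)))
  flipped <- allow_flip && core_raw$auc < 0.5
  if (flipped) {
    core <- .td_roc_core(-marker, ctx)
    work <- -marker
  } else {
    core <- core_raw
    work <- marker
  }
  ch <- .choose_cutoff(core, ctx$n, min_group_frac, stats::median(work))
  if (is.null(ch))
    return(list(feasible = FALSE, reason = "constraint infeasible",
                auc_raw = core_raw$auc))
  cut_expr <- if (flipped) -ch$cutoff else ch$cutoff
  ind <- marker > cut_expr
  list(feasible = TRUE, cutoff = cut_expr, indicator = ind,
       flipped = flipped, auc_risk = core$auc, auc_raw = core_raw$auc,
       sens = ch$sens, spec = ch$spec, youden = ch$youden,
       group_sizes = ch$group_sizes, tie_broken = ch$tie_broken)
}
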