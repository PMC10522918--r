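#' Screening criteria for per-gene prognostic association
#'
#' A gene is called prognostic when, independently in every cohort, the
#' time-dependent AUC exceeds `auc_min` and both the univariate and the
#' covariate-adjusted Cox regressions on the dichotomized expression group are
#' significant at `alpha`, with the hazard direction agreeing across cohorts.
#' Dichotomization uses the constrained optimal cutoff: both groups must
#' retain at least `min_group_frac` of the cohort, and Youden ties are broken
#' toward the cutoff nearest the marker median.
#'
#' @param horizon_months ROC evaluation horizon in months (default 36; one
#'   fixed horizon is used for a whole run).
#' @param min_group_frac Minimum fraction of the cohort in each expression
#'   group, in (0, 0.5]; default 0.20.
#' @param alpha Two-sided significance level for the Cox regressions.
#' @param auc_min Minimum risk-direction AUC.
#' @param require_all_cohorts If `TRUE` (default), a gene must be evaluable
#'   and pass in every cohort.
#' @return List of class `screen_criteria`.
#' @export
screen_criteria <- function(horizon_months = 36, min_group_frac = 0.20,
                            alpha = 0.05, auc_min = 0.5,
                            require_all_cohorts = TRUE) {
  stopifnot(horizon_months > 0, min_group_frac > 0, min_group_frac <= 0.5,
            alpha > 0, alpha < 1, auc_min >= 0, auc_min < 1)
  structure(list(horizon_months = horizon_months,
                 min_group_frac = min_group_frac, alpha = alpha,
                 auc_min = auc_min,
                 require_all_cohorts = isTRUE(require_all_cohorts)),
            class = "screen_criteria")
}

#' Score selection thresholds
#'
#' A candidate weighted-sum score passes when, in every cohort, the
#' dichotomized score group has univariate HR > `uni_hr_min` (p < alpha),
#' covariate-adjusted HR > `multi_hr_min` (p < alpha), and AUC, sensitivity
#' and specificity at the chosen cutoff all exceed their minima.
#'
#' @param uni_hr_min,multi_hr_min Hazard-ratio minima (defaults 2 and 1.5).
#' @param auc_min,sens_min,spec_min Discrimination minima (defaults 0.5).
#' @return Named list of class `score_thresholds`.
#' @export
score_thresholds <- function(uni_hr_min = 2.0, multi_hr_min = 1.5,
                             auc_min = 0.5, sens_min = 0.5, spec_min = 0.5) {
  stopifnot(uni_hr_min > 0, multi_hr_min > 0)
  structure(list(uni_hr_min = uni_hr_min, multi_hr_min = multi_hr_min,
                 auc_min = auc_min, sens_min = sens_min, spec_min = spec_min),
            class = "score_thresholds")
}

#' Heterogeneity rule for fixed- vs random-effects pooling
#'
#' Fixed effects are used when Cochran's Q is non-significant
#' (`q_p >= q_p_threshold`) and Higgins' I-squared is at most `i2_threshold`
#' percent; otherwise DerSimonian-Laird random effects.
#'
#' @param q_p_threshold Q-test p-value threshold (default 0.05).
#' @param i2_threshold I-squared threshold in percent (default 50).
#' @return Named list of class `heterogeneity_rule`.
#' @export
heterogeneity_rule <- function(q_p_threshold = 0.05, i2_threshold = 50) {
  stopifnot(q_p_threshold > 0, i2_threshold >= 0)
  structure(list(q_p_threshold = q_p_threshold, i2_threshold = i2_threshold),
            class = "heterogeneity_rule")
}

#' Full run configuration
#'
#' Bundles the screening criteria, score-selection thresholds, normalized
#' score category cutoffs, heterogeneity rule, expression scale used for the
#' weighted sum, and RNG seed for a pipeline run.
#'
#' @param criteria [screen_criteria()].
#' @param thresholds [score_thresholds()].
#' @param category_cutoffs Two-element numeric `c(low_below, high_at_or_above)`
#'   applied to median-normalized scores; defaults `c(0.9, 1.1)` with
#'   half-open intervals (low < 0.9 <= intermediate < 1.1 <= high).
#' @param het_rule [heterogeneity_rule()].
#' @param expression_scale Transform applied to expression before the weighted
#'   sum: `"zscore"` (per-gene, per-cohort; default because cross-platform raw
#'   scales are incomparable), `"raw"`, or `"log2"` (log2(x + 1)).
#' @param rng_seed Integer seed recorded with the run.
#' @return List of class `run_config`.
#' @export
run_config <- function(criteria = screen_criteria(),
                       thresholds = score_thresholds(),
                       category_cutoffs = c(low_below = 0.9, high_at_or_above = 1.1),
                       het_rule = heterogeneity_rule(),
                       expression_scale = c("zscore", "raw", "log2"),
                       rng_seed = 1L) {
  expression_scale <- match.arg(expression_scale)
  stopifnot(length(category_cutoffs) == 2,
            category_cutoffs[1] < category_cutoffs[2],
            all(category_cutoffs > 0))
  structure(list(criteria = criteria, thresholds = thresholds,
                 category_cutoffs = category_cutoffs, het_rule = het_rule,
                 expression_scale = expression_scale,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}
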