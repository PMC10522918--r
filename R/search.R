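# Stage 3: enumerate every non-empty gene combination, build weighted-sum
# scores with the pooled coefficients, evaluate each per cohort against the
# selection thresholds, and pick the parsimonious winner.

#' Define a weighted-sum gene-expression score
#'
#' Score_s = sum_g w_g x_{g,s}, where x is expression after the declared
#' scale transform.
#'
#' @param genes Unique gene identifiers.
#' @param weights Numeric weights aligned to `genes` (typically pooled
#'   log-hazard coefficients).
#' @param scale Expression transform: `"zscore"`, `"raw"`, or `"log2"`.
#' @param score_id Optional identifier; defaults to the joined gene list.
#' @return Object of class `score_definition`.
#' @export
score_definition <- function(genes, weights, scale = "zscore", score_id = NULL) {
  stopifnot(length(genes) == length(weights), length(genes) >= 1)
  if (anyDuplicated(genes)) stop("score genes must be unique")
  if (any(!is.finite(weights))) stop("score weights must be finite")
  if (is.null(score_id)) score_id <- paste(genes, collapse = "+")
  structure(list(score_id = score_id, genes = as.character(genes),
                 weights = as.numeric(weights), scale = scale),
            class = "score_definition")
}

#' Enumerate all non-empty gene combinations
#'
#' All 2^k - 1 non-empty subsets of `genes`, in deterministic order: by
#' subset size, then lexicographically within size. Weights are attached
#' from the named `weights` vector when given.
#'
#' @param genes Character vector (1 to `max_genes` entries).
#' @param weights Optional named numeric vector of per-gene weights.
#' @param scale Expression scale recorded in each definition.
#' @param max_genes Hard cap on k (default 20); exceeding it errors with
#'   advice to override explicitly.
#' @return List of [score_definition()] objects of length 2^k - 1.
#' @export
enumerate_combinations <- function(genes, weights = NULL, scale = "zscore",
                                   max_genes = 20) {
  genes <- sort(unique(as.character(genes)), method = "radix")
  k <- length(genes)
  if (k < 1) stop("need at least one gene")
  if (k > max_genes)
    stop(k, " genes would produce 2^", k, " - 1 combinations; raise ",
         "`max_genes` explicitly to override")
  if (!is.null(weights)) {
    missing <- setdiff(genes, names(weights))
    if (length(missing))
      stop("no weight for gene(s): ", paste(missing, collapse = ", "))
  }
  defs <- vector("list", 2^k - 1)
  i <- 0L
  for (size in seq_len(k)) {
    combos <- utils::combn(genes, size, simplify = FALSE)
    for (cm in combos) {
      i <- i + 1L
      w <- if (is.null(weights)) rep(1, size) else unname(weights[cm])
      defs[[i]] <- score_definition(cm, w, scale = scale,
                                    score_id = sprintf("S%05d", i))
    }
  }
  defs
}

# Apply the declared expression transform to a genes-x-samples matrix.
.scale_expression <- function(x, scale) {
  switch(scale,
    raw = x,
    log2 = {
      if (any(x < -1)) stop("log2 scale requires expression >= -1")
      log2(x + 1)
    },
    zscore = {
      sds <- apply(x, 1, stats::sd)
      if (any(sds == 0))
        stop("constant expression for gene(s): ",
             paste(rownames(x)[sds == 0], collapse = ", "))
      (x - rowMeans(x)) / sds
    },
    stop("unknown expression scale: ", scale))
}

#' Compute per-sample score values
#'
#' @param expression Genes x samples matrix containing every definition gene
#'   (a missing gene is an error, never a silent zero-fill).
#' @param definition A [score_definition()].
#' @return Named numeric vector of per-sample scores.
#' @export
compute_score <- function(expression, definition) {
  stopifnot(inherits(definition, "score_definition"))
  missing <- setdiff(definition$genes, rownames(expression))
  if (length(missing))
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  x <- .scale_expression(expression[definition$genes, , drop = FALSE],
                         definition$scale)
  colSums(x * definition$weights)
}

# Per-cohort precomputation for batch evaluation: scaled expression
# restricted to the candidate genes, OS context, covariate table.
.search_prep <- function(cohorts, genes, criteria, scale) {
  lapply(cohorts, function(co) {
    missing <- setdiff(genes, rownames(co$expression))
    if (length(missing))
      stop("cohort ", co$cohort_id, " lacks gene(s): ",
           paste(missing, collapse = ", "))
    list(cohort_id = co$cohort_id,
         xs = .scale_expression(co$expression[genes, , drop = FALSE], scale),
         sc = .screen_ctx(co, criteria$horizon_months, "OS"))
  })
}

# Evaluate one weighted-sum score (already computed per cohort) against the
# thresholds; scores are taken as risk-oriented (high score = high risk), so
# a protective score simply fails the HR thresholds.
.evaluate_prepared <- function(scores_by_cohort, prep, thresholds, criteria) {
  C <- length(prep)
  per <- data.frame(cohort = vapply(prep, `[[`, "", "cohort_id"),
                    cutoff = NA_real_, auc = NA_real_, sens = NA_real_,
                    spec = NA_real_, uni_hr = NA_real_, uni_p = NA_real_,
                    multi_hr = NA_real_, multi_p = NA_real_,
                    evaluable = FALSE, stringsAsFactors = FALSE)
  for (ci in seq_len(C)) {
    sc <- prep[[ci]]$sc
    s <- scores_by_cohort[[ci]][sc$incl]
    d <- .dichotomize_risk(s, sc$ctx, criteria$min_group_frac,
                           allow_flip = FALSE)
    if (!d$feasible) next
    uni <- .cox_indicator(d$indicator, sc$time, sc$event)
    if (!uni$converged) next
    multi <- .cox_adjusted(d$indicator, sc$time, sc$event, sc$covs)
    per$cutoff[ci] <- d$cutoff
    per$auc[ci] <- d$auc_risk
    per$sens[ci] <- d$sens
    per$spec[ci] <- d$spec
    per$uni_hr[ci] <- uni$hr
    per$uni_p[ci] <- uni$p
    per$multi_hr[ci] <- multi$hr
    per$multi_p[ci] <- multi$p
    per$evaluable[ci] <- multi$converged
  }
  passes <- all(per$evaluable) &&
    all(per$uni_hr > thresholds$uni_hr_min & per$uni_p < criteria$alpha &
        per$multi_hr > thresholds$multi_hr_min & per$multi_p < criteria$alpha &
        per$auc > thresholds$auc_min & per$sens > thresholds$sens_min &
        per$spec > thresholds$spec_min)
  list(per_cohort = per, passes = isTRUE(passes),
       reason = if (!all(per$evaluable)) "cutoff or fit not evaluable in some cohort" else "")
}

#' Evaluate one candidate score across cohorts
#'
#' Per cohort: compute the score, find its own constrained optimal cutoff
#' (the same >= `min_group_frac` rule used for genes), fit univariate and
#' covariate-adjusted Cox models on the high/low score group, and read AUC,
#' sensitivity and specificity at the chosen cutoff. The score passes iff in
#' EVERY cohort: uni HR > `uni_hr_min` (p < alpha), multi HR > `multi_hr_min`
#' (p < alpha), and AUC/sensitivity/specificity exceed their minima. An
#' infeasible cutoff in any cohort yields `passes = FALSE` with a reason,
#' not an error.
#'
#' @param definition A [score_definition()].
#' @param cohorts List of `cohort_dataset`.
#' @param thresholds [score_thresholds()].
#' @param criteria [screen_criteria()] (horizon, alpha, group-size rule).
#' @return Object of class `score_evaluation`: `score_id`, `genes`,
#'   `n_genes`, `per_cohort` data frame, `passes`, `reason`.
#' @export
evaluate_score <- function(definition, cohorts,
                           thresholds = score_thresholds(),
                           criteria = screen_criteria()) {
  prep <- .search_prep(cohorts, definition$genes, criteria, definition$scale)
  scores <- lapply(prep, function(p)
    colSums(p$xs[definition$genes, , drop = FALSE] * definition$weights))
  ev <- .evaluate_prepared(scores, prep, thresholds, criteria)
  structure(list(score_id = definition$score_id, genes = definition$genes,
                 n_genes = length(definition$genes),
                 per_cohort = ev$per_cohort, passes = ev$passes,
                 reason = ev$reason),
            class = "score_evaluation")
}

#' Evaluate every enumerated combination
#'
#' Batch driver over [enumerate_combinations()]: per-cohort scaled expression
#' is computed once and every subset's score is a weighted column sum, so
#' results are deterministic regardless of execution order.
#'
#' @param pooled Data frame from [pool_screen()] (`gene`, `beta_pooled`).
#' @param cohorts List of `cohort_dataset`.
#' @param thresholds,criteria See [evaluate_score()].
#' @param scale Expression scale for the weighted sum.
#' @param max_genes Passed to [enumerate_combinations()].
#' @param verbose Progress messages.
#' @return List of `score_evaluation`, one per combination.
#' @export
search_scores <- function(pooled, cohorts, thresholds = score_thresholds(),
                          criteria = screen_criteria(), scale = "zscore",
                          max_genes = 20, verbose = TRUE) {
  weights <- stats::setNames(pooled$beta_pooled, pooled$gene)
  defs <- enumerate_combinations(pooled$gene, weights, scale = scale,
                                 max_genes = max_genes)
  prep <- .search_prep(cohorts, sort(pooled$gene, method = "radix"),
                       criteria, scale)
  out <- vector("list", length(defs))
  for (i in seq_along(defs)) {
    def <- defs[[i]]
    scores <- lapply(prep, function(p)
      colSums(p$xs[def$genes, , drop = FALSE] * def$weights))
    ev <- .evaluate_prepared(scores, prep, thresholds, criteria)
    out[[i]] <- structure(list(score_id = def$score_id, genes = def$genes,
                               n_genes = def$n_genes %||% length(def$genes),
                               per_cohort = ev$per_cohort, passes = ev$passes,
                               reason = ev$reason, definition = def),
                          class = "score_evaluation")
    if (verbose && i %% 500 == 0)
      message("evaluated ", i, "/", length(defs), " scores")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select passing scores
#' @param evaluations List of `score_evaluation`.
#' @return The subset with `passes = TRUE`.
#' @export
select_scores <- function(evaluations) {
  Filter(function(e) isTRUE(e$passes), evaluations)
}

#' Pick the parsimonious winner among passing scores
#'
#' Fewest genes wins; ties are broken by the largest minimum univariate HR
#' across cohorts, then by lexicographic gene list.
#'
#' @param passing List of passing `score_evaluation` (from [select_scores()]).
#' @return Object of class `parsimonious_choice`: `found` flag plus, when
#'   found, the winning `evaluation` and its gene set; otherwise an explicit
#'   "no score passed" result.
#' @export
pick_parsimonious <- function(passing) {
  if (!length(passing))
    return(structure(list(found = FALSE, reason = "no score passed"),
                     class = "parsimonious_choice"))
  sizes <- vapply(passing, `[[`, numeric(1), "n_genes")
  cand <- passing[sizes == min(sizes)]
  if (length(cand) > 1) {
    min_hr <- vapply(cand, function(e) min(e$per_cohort$uni_hr), numeric(1))
    cand <- cand[min_hr >= max(min_hr) - 1e-12]
  }
  if (length(cand) > 1) {
    keys <- vapply(cand, function(e) paste(e$genes, collapse = "|"), "")
    cand <- cand[order(keys, method = "radix")][1]
  }
  structure(list(found = TRUE, evaluation = cand[[1]],
                 genes = cand[[1]]$genes, score_id = cand[[1]]$score_id),
            class = "parsimonious_choice")
}

#' @export
print.parsimonious_choice <- function(x, ...) {
  if (!x$found) cat("<parsimonious_choice> no score passed\n")
  else cat("<parsimonious_choice>", x$score_id, "with",
           length(x$genes), "genes:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten score evaluations into a table
#' @param evaluations List of `score_evaluation`.
#' @return Data frame, one row per score x cohort.
#' @export
evaluations_table <- function(evaluations) {
  do.call(rbind, lapply(evaluations, function(e) {
    cbind(data.frame(score_id = e$score_id,
                     genes = paste(e$genes, collapse = "+"),
                     n_genes = e$n_genes, passes = e$passes,
                     stringsAsFactors = FALSE),
          e$per_cohort)
  }))
}

#' Jaccard index between two gene sets
#' @param a,b Character vectors.
#' @return |a intersect b| / |a union b|.
#' @export
jaccard_index <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}
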