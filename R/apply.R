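# Stage 4: normalization/categorization of the chosen score, integration
# with AJCC TNM staging, benchmarking of external signatures, and the
# cell-line drug-sensitivity correlation.

#' Normalize scores by cohort median and assign categories
#'
#' Per cohort, raw scores are divided by that cohort's own median so the
#' same category cutoffs apply to any cohort regardless of expression
#' platform. Categories use half-open intervals: low when
#' normalized < `cutoffs[1]`, intermediate when
#' `cutoffs[1] <= normalized < cutoffs[2]`, high when
#' `normalized >= cutoffs[2]` (defaults 0.9 and 1.1).
#'
#' @param scores Data frame with columns `cohort`, `sample_id`, `score`
#'   (raw scores on a positive scale; see Details).
#' @param cutoffs Two increasing positive numbers.
#' @return The input with `normalized` and `category`
#'   (factor low/intermediate/high) appended.
#' @details A cohort whose median score is zero or negative cannot be
#'   median-normalized (possible when weights produce sign-mixed scores);
#'   this errors with advice to shift/rescale, e.g. by computing the score
#'   on the raw expression scale.
#' @export
normalize_and_categorize <- function(scores, cutoffs = c(0.9, 1.1)) {
  stopifnot(all(c("cohort", "sample_id", "score") %in% names(scores)),
            length(cutoffs) == 2, cutoffs[1] < cutoffs[2])
  if (!nrow(scores)) stop("no scores to normalize")
  out <- lapply(split(scores, scores$cohort), function(df) {
    med <- stats::median(df$score)
    if (!is.finite(med) || med <= 0)
      stop("cohort ", df$cohort[1], " has non-positive median score (",
           signif(med, 4), "): median normalization is undefined; ",
           "shift or rescale the score (e.g. compute it on the raw ",
           "expression scale) before categorizing")
    df$normalized <- df$score / med
    df$category <- cut(df$normalized,
                       breaks = c(-Inf, cutoffs[1], cutoffs[2], Inf),
                       labels = c("low", "intermediate", "high"),
                       right = FALSE)
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default AJCC-stage x score-category risk map
#'
#' Encodes the integration narrative: early stages (I, IA, IB, II) are
#' favorable unless the score category is high (then intermediate); IIIA is
#' intermediate unless high (then adverse); IIIB is adverse; IV is adverse
#' unless high (then very-adverse). This is a configurable default, audited
#' by the per-group survival summary [integrate_tnm()] emits, not a fixed
#' truth.
#'
#' @param stages Stage labels to cover.
#' @return Data frame with columns `stage`, `category`, `group`.
#' @export
default_risk_map <- function(stages = c("I", "IA", "IB", "II", "III",
                                        "IIIA", "IIIB", "IV")) {
  cats <- c("low", "intermediate", "high")
  map <- expand.grid(stage = stages, category = cats,
                     stringsAsFactors = FALSE)
  assign_one <- function(stage, category) {
    if (stage %in% c("I", "IA", "IB", "II"))
      return(if (category == "high") "intermediate" else "favorable")
    if (stage %in% c("III", "IIIA"))
      return(if (category == "high") "adverse" else "intermediate")
    if (stage == "IIIB") return("adverse")
    if (category == "high") "very-adverse" else "adverse"
  }
  map$group <- mapply(assign_one, map$stage, map$category)
  map
}

#' Integrate TNM stage with score categories into combined risk groups
#'
#' Applies a (stage x category) -> group mapping table and emits per-group
#' Kaplan-Meier summaries plus pairwise log-rank p-values so any candidate
#' map can be audited against the data.
#'
#' @param stage Per-sample AJCC stage labels.
#' @param category Per-sample score categories (low/intermediate/high).
#' @param time,event OS endpoint.
#' @param map Mapping data frame (`stage`, `category`, `group`); every
#'   observed stage x category combination must be mapped.
#' @return List: `assignments` (per-sample group), `group_summary` (n,
#'   events, KM median per group, ordered by median), `pairwise` (log-rank
#'   p-values for each group pair).
#' @export
integrate_tnm <- function(stage, category, time, event,
                          map = default_risk_map()) {
  stage <- as.character(stage)
  category <- as.character(category)
  stopifnot(length(stage) == length(category),
            length(stage) == length(time))
  unmapped_stage <- setdiff(unique(stage), unique(map$stage))
  if (length(unmapped_stage))
    stop("stage label(s) missing from map: ",
         paste(unmapped_stage, collapse = ", "))
  key <- paste(stage, category, sep = "\r")
  mkey <- paste(map$stage, map$category, sep = "\r")
  idx <- match(key, mkey)
  if (anyNA(idx)) {
    bad <- unique(paste0(stage, " x ", category)[is.na(idx)])
    stop("unmapped stage x category cell(s): ", paste(bad, collapse = ", "))
  }
  group <- map$group[idx]
  groups <- unique(map$group)
  groups <- groups[groups %in% group]
  gs <- do.call(rbind, lapply(groups, function(g) {
    sel <- group == g
    km <- km_estimate(time[sel], event[sel])
    data.frame(group = g, n = sum(sel), events = sum(event[sel]),
               median_os = km$median, stringsAsFactors = FALSE)
  }))
  gs <- gs[order(is.na(gs$median_os), gs$median_os, decreasing = c(FALSE, TRUE),
                 method = "radix"), ]
  rownames(gs) <- NULL
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    sel <- group %in% pr
    p <- tryCatch(logrank_test(group[sel], time[sel], event[sel])$p,
                  error = function(e) NA_real_)
    data.frame(group1 = pr[1], group2 = pr[2], p = p,
               stringsAsFactors = FALSE)
  }))
  list(assignments = data.frame(stage = stage, category = category,
                                group = group, stringsAsFactors = FALSE),
       group_summary = gs, pairwise = pw)
}

#' Benchmark an external published signature by tertile stratification
#'
#' Computes the signature's weighted-sum score in each cohort, splits the
#' cohort into tertiles (sample-quantile type 7; boundary ties go to the
#' lower tertile), and fits a univariate Cox model of tertile 3 vs tertile 1
#' (middle tertile excluded). The signature is called robust iff HR > 1 with
#' p < `alpha` in every evaluable cohort.
#'
#' @param signature List with `signature_id`, `genes`, `weights` (and
#'   optionally `publication`).
#' @param cohorts List of `cohort_dataset`.
#' @param alpha Significance level.
#' @param min_coverage Minimum fraction of signature genes that must be
#'   present in a cohort (default 0.6); below it the cohort is marked
#'   not-evaluable. Present genes only are used (no zero-fill), with the
#'   coverage recorded.
#' @param scale Expression transform before weighting.
#' @return List: `table` (per cohort: coverage, n, HR, p, evaluable),
#'   `robust` verdict, `signature_id`.
#' @export
evaluate_external_signature <- function(signature, cohorts, alpha = 0.05,
                                        min_coverage = 0.6, scale = "zscore") {
  stopifnot(!is.null(signature$genes), !is.null(signature$weights),
            length(signature$genes) == length(signature$weights))
  sig_id <- signature$signature_id %||% "signature"
  rows <- lapply(cohorts, function(co) {
    present <- signature$genes %in% rownames(co$expression)
    coverage <- mean(present)
    row <- data.frame(signature_id = sig_id, cohort = co$cohort_id,
                      coverage = coverage, n = n_samples(co),
                      hr = NA_real_, p = NA_real_, evaluable = FALSE,
                      reason = "", stringsAsFactors = FALSE)
    if (coverage < min_coverage || !any(present)) {
      row$reason <- "insufficient gene coverage"
      return(row)
    }
    if (n_samples(co) < 9) {
      row$reason <- "fewer than 9 samples"
      return(row)
    }
    def <- score_definition(signature$genes[present],
                            signature$weights[present], scale = scale)
    s <- tryCatch(compute_score(co$expression, def), error = function(e) NULL)
    if (is.null(s)) { row$reason <- "score not computable"; return(row) }
    qs <- stats::quantile(s, c(1, 2) / 3, type = 7, names = FALSE)
    t1 <- s <= qs[1]
    t3 <- s > qs[2]
    sel <- t1 | t3
    if (sum(co$os_event[sel]) < 2) {
      row$reason <- "fewer than 2 events in tertiles 1 and 3"
      return(row)
    }
    fit <- .cox_indicator(t3[sel], co$os_time[sel], co$os_event[sel])
    if (!fit$converged) { row$reason <- "Cox fit failed"; return(row) }
    row$hr <- fit$hr
    row$p <- fit$p
    row$evaluable <- TRUE
    row
  })
  tab <- do.call(rbind, rows)
  robust <- any(tab$evaluable) &&
    all(tab$hr[tab$evaluable] > 1 & tab$p[tab$evaluable] < alpha)
  list(signature_id = sig_id, table = tab, robust = isTRUE(robust))
}

#' Score vs drug-sensitivity (IC50) correlation on a cell-line panel
#'
#' Spearman rank correlation of the per-line score against each drug's IC50;
#' a drug is a hit iff |rho| > `rho_min` and p < `alpha` (two-sided). Lines
#' missing a drug's IC50 are excluded pairwise; a drug with all-tied IC50 is
#' skipped with a warning.
#'
#' @param scores Named numeric vector of per-line scores.
#' @param ic50 Drugs x lines numeric matrix (colnames = line identifiers).
#' @param rho_min Absolute correlation threshold (default 0.25).
#' @param alpha Significance level (default 0.05).
#' @return Data frame: `drug`, `n`, `rho`, `p`, `hit`.
#' @export
drug_correlation <- function(scores, ic50, rho_min = 0.25, alpha = 0.05) {
  ic50 <- as.matrix(ic50)
  common <- intersect(names(scores), colnames(ic50))
  if (length(common) < 8)
    stop("need >= 8 cell lines with both score and IC50 (have ",
         length(common), ")")
  s <- scores[common]
  out <- lapply(rownames(ic50), function(dr) {
    y <- ic50[dr, common]
    ok <- !is.na(y)
    row <- data.frame(drug = dr, n = sum(ok), rho = NA_real_, p = NA_real_,
                      hit = FALSE, stringsAsFactors = FALSE)
    if (sum(ok) < 8) return(row)
    if (length(unique(y[ok])) < 2) {
      warning("drug ", dr, " has all-tied IC50; skipped")
      return(row)
    }
    ct <- suppressWarnings(stats::cor.test(s[ok], y[ok], method = "spearman",
                                           alternative = "two.sided"))
    row$rho <- unname(ct$estimate)
    row$p <- ct$p.value
    row$hit <- abs(row$rho) > rho_min && row$p < alpha
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
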