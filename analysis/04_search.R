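#!/usr/bin/env Rscript
# Step 4: exhaustive weighted-sum score search.
#
# Enumerates every non-empty combination of the pooled genes, builds each
# weighted-sum score on per-cohort z-scored expression, evaluates it in
# every cohort (own constrained optimal cutoff; uni HR > 2 and multi
# HR > 1.5 at p < 0.05; AUC, sensitivity, specificity > 0.5), and keeps
# the most parsimonious passing score.

suppressPackageStartupMessages({
  library(prognoscore)
  library(jsonlite)
})

manifest <- read_json("results/data/cohorts.json")
cohorts <- lapply(manifest, function(m) {
  spec <- cohort_spec(
    cohort_id = m$cohort_id, ep2_kind = m$ep2_kind,
    ep2_time_col = if (m$ep2_kind != "none") "ep2_time",
    ep2_event_col = if (m$ep2_kind != "none") "ep2_event",
    covariates = c(age = "continuous", sex = "categorical",
                   stage = "categorical"),
    available_covariates = unlist(m$available_covariates))
  read_cohort(m$expression, m$clinical, spec, verbose = FALSE)
})
pooled <- read_table("results/pooled_betas.tsv")

evaluations <- search_scores(pooled, cohorts,
                             thresholds = score_thresholds(),
                             criteria = screen_criteria())
tab <- evaluations_table(evaluations)
write_table(tab, "results/score_evaluations.tsv")

passing <- select_scores(evaluations)
winner <- pick_parsimonious(passing)
cat(length(passing), "of", length(evaluations), "scores pass all thresholds\n")
if (!winner$found) {
  cat("no score passed\n")
  quit(status = 0)
}
print(winner)
print(winner$evaluation$per_cohort, row.names = FALSE, digits = 3)
write_json(list(score_id = winner$score_id,
                genes = winner$genes,
                weights = winner$evaluation$definition$weights,
                scale = winner$evaluation$definition$scale,
                per_cohort = winner$evaluation$per_cohort),
           "results/winner.json", auto_unbox = TRUE, digits = NA)
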