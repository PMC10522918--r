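#!/usr/bin/env Rscript
# Step 1: generate the synthetic five-cohort study.
#
# Emulates the study conditions: cohorts of 345/297/433/93/192 patients with
# right-censored OS, a second endpoint (DFS/DFS/RFS) in cohorts 1, 2 and 4,
# cohort-specific covariate availability (cohort 3 lacks TNM stage), 200
# genes of which 7 adverse genes drive both endpoints (the signature to
# recover), 3 favorable genes drive OS only (the cross-endpoint filter
# should drop them), and the rest are correlated noise. Writes one
# expression + clinical TSV per cohort plus the ground truth.

suppressPackageStartupMessages({
  library(prognoscore)
  library(jsonlite)
})

seed <- 1L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)   # the study defaults
sim <- simulate_multicohort(cfg)

manifest <- list()
for (co in sim$cohorts) {
  ep <- file.path(out_dir, paste0(co$cohort_id, "_expression.tsv"))
  cp <- file.path(out_dir, paste0(co$cohort_id, "_clinical.tsv"))
  write_cohort(co, ep, cp)
  manifest[[co$cohort_id]] <- list(
    cohort_id = co$cohort_id, expression = ep, clinical = cp,
    ep2_kind = co$ep2_kind, n = n_samples(co),
    available_covariates = co$available_covariates)
  cat(sprintf("%s: n = %d, %d OS events (%.0f%% censored), endpoint2 = %s\n",
              co$cohort_id, n_samples(co), sum(co$os_event),
              100 * (1 - mean(co$os_event)), co$ep2_kind))
}
write_json(manifest, file.path(out_dir, "cohorts.json"), auto_unbox = TRUE)
write_json(list(planted = sim$truth$planted,
                realized_betas = sim$truth$realized_betas,
                covariate_effects = as.list(sim$truth$covariate_effects),
                seed = seed),
           file.path(out_dir, "ground_truth.json"),
           auto_unbox = TRUE, digits = NA)
cat("Planted:", nrow(sim$truth$planted), "genes (",
    sum(sim$truth$planted$affects_ep2), "dual-endpoint adverse,",
    sum(!sim$truth$planted$affects_ep2), "OS-only favorable)\n")
cat("Wrote cohort files and ground truth under", out_dir, "\n")
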