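# prognoscore

Discovery and application of weighted-sum prognostic gene-expression
signatures from multi-cohort survival studies.

Translational groups routinely ask whether a handful of genes can
stratify patients beyond anatomic staging. The statistically careful
version of that question needs: censoring-aware discrimination at a fixed
horizon, dichotomization rules that cannot overfit tiny groups,
replication across independent cohorts measured on different platforms,
and a principled way to combine per-cohort effect sizes into portable
weights. `prognoscore` packages that whole pipeline, for biostatisticians
and computational biologists who have per-cohort expression matrices and
clinical tables and want a reproducible, testable path from gene universe
to deployable risk score.

## The method

For each gene in each cohort, patients are split at the optimal cutoff of
the time-dependent (cumulative/dynamic, Kaplan–Meier-weighted) survival
ROC at a fixed horizon, subject to both groups keeping ≥ 20% of the
cohort, with Youden ties broken toward the median. A gene is prognostic
iff AUC > 0.5 and univariate **and** covariate-adjusted Cox regressions
give p < 0.05 **in every cohort**, with a consistent hazard direction,
and the association replicates on a second endpoint (DFS/RFS) where one
exists. Per-cohort univariate log-hazard coefficients β are then pooled by
fixed- or random-effects meta-analysis (Cochran's Q, Higgins' I²,
DerSimonian–Laird τ²), and every non-empty combination of the surviving
genes defines a candidate score

    Score = Gene₁·β₁ + Gene₂·β₂ + … + Geneᵢ·βᵢ

evaluated per cohort against: univariate HR > 2 (p < 0.05), adjusted
HR > 1.5 (p < 0.05), AUC, sensitivity and specificity > 0.5. The most
parsimonious passing score wins. Winning scores are median-normalized per
cohort and categorized (low < 0.9 ≤ intermediate < 1.1 ≤ high), combined
with AJCC TNM stage into auditable risk groups, benchmarked against
external published signatures by tertile Cox regression, and correlated
with drug IC50 panels (Spearman, hit iff |ρ| > 0.25 and p < 0.05).

A synthetic five-cohort generator with planted prognostic genes, planted
favorable OS-only genes, between-cohort effect heterogeneity and a
correlated second endpoint provides ground truth for every stage. See the
methods vignette (`vignettes/prognostic-score-discovery.Rmd`) for the
estimators, defaults and design decisions.

## Worked example

The `analysis/` scripts run the whole study on generated data:

```sh
Rscript analysis/01_simulate.R   # five cohorts, 200 genes, ground truth
Rscript analysis/02_screen.R    # per-gene dual-Cox screen + DFS/RFS filter
Rscript analysis/03_pool.R      # meta-analytic pooling of betas
Rscript analysis/04_search.R    # exhaustive combination search
Rscript analysis/05_apply.R     # normalize, TNM groups, benchmark, drugs
```

On the default study (cohorts of 345/297/433/93/192 patients, seven
planted dual-endpoint genes at +0.7 log-hazard per SD, three favorable
OS-only genes, seed 1), the screen prints

```
OS pass: 6 genes; final (OS + DFS/RFS): 5 genes
Final gene list: PRG03, PRG04, PRG05, PRG06, PRG07
Recovered 5 / 7 planted dual-endpoint genes; 0 false positives
```

— the two misses fail in the 93-patient cohort, where five-cohort
replication is hardest; no null gene survives. Pooling reports one gene
under random effects (I² = 69%), the rest fixed:

```
  gene  model   q_p   i2 beta_pooled se_pooled
 PRG03  fixed 0.253 25.3       0.537    0.0715
 PRG04 random 0.011 69.4       0.564    0.1348
 ...
```

The search evaluates all 31 combinations and keeps 11 passers; the
parsimonious winner is a three-gene score whose per-cohort univariate HRs
run 2.7–4.4 with AUC 0.71–0.85. Applying it, the combined TNM × score
risk groups in cohort 1 have KM median OS 40.8 / 16.5 / 8.8 / 1.9 months
(favorable / intermediate / adverse / very-adverse), the winner fed back
through the tertile benchmark is robust in all five cohorts
(T3-vs-T1 HR 3.1–8.9) while a random signature is not, and the two
planted drugs are recovered as sensitivity hits.

In-memory, the same run is:

```r
library(prognoscore)
sim <- simulate_multicohort(simulation_config(seed = 1))
res <- run_discovery_pipeline(sim$cohorts, run_config())
res$winner
```

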