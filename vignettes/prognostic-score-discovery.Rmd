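---
title: "Discovering multi-cohort prognostic gene-expression scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering multi-cohort prognostic gene-expression scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

A transcriptome-wide search for a prognostic signature asks: which genes are
reproducibly associated with survival across several independent patient
cohorts, and which weighted combination of them stratifies patients best?
`prognoscore` implements this as four explicit stages — screen, pool, search,
apply — each with a fixed statistical contract, plus a synthetic multi-cohort
generator so that every stage can be tested against planted ground truth.
The workflow in `analysis/01…05_*.R` runs the stages in order on a generated
five-cohort study.

## Stage 1 — per-gene screening

**Time-dependent ROC.** Expression markers are judged at a fixed horizon
$\tau$ (default 36 months) with the cumulative/dynamic survival ROC: cases
are subjects with an event by $\tau$, controls are subjects event-free past
$\tau$, and censoring before $\tau$ is handled by Kaplan–Meier weighting.
For a cutoff $c$, with $p_c = \Pr(X > c)$ estimated empirically,
$S_c(\tau)$ the KM survival at $\tau$ inside the high group and $S(\tau)$
the overall KM survival,

$$\widehat{\mathrm{se}}(c) = \frac{\{1 - S_c(\tau)\}\, p_c}{1 - S(\tau)},
\qquad
1 - \widehat{\mathrm{sp}}(c) = \frac{S_c(\tau)\, p_c}{S(\tau)}.$$

Candidate cutoffs are midpoints between consecutive distinct marker values
(high group strictly above the cutoff), which makes the curve invariant to
any strictly increasing transform of the marker and to within-group jitter.
The raw KM-weighted estimates need not be monotone along cutoffs; when a
violation occurs both coordinates are repaired by an isotonic
(least-squares monotone) fit and the event is flagged in the result. With no
censoring before the horizon the estimator reduces *exactly* to the
empirical ROC, which the tests exploit as an oracle. AUC is the trapezoidal
area with the $(0,0)$ and $(1,1)$ endpoints appended.

**Constrained optimal cutoff.** The screening cutoff maximizes Youden's
$J = \mathrm{se} + \mathrm{sp} - 1$ among cutoffs whose low and high groups
both keep at least $\lceil 0.20\,n \rceil$ samples (guarding against
overfitted extreme splits). Ties within $10^{-9}$ are broken toward the
cutoff closest to the marker median; a remaining distance tie takes the
smaller cutoff. Markers whose high values are *protective* (raw AUC below
0.5) are cut on the negated scale so that $J$ is meaningful; the recorded
direction (`adverse-high` / `favorable-high`) comes from the univariate
hazard ratio of the high-expression group.

**Dual Cox testing.** In each cohort independently the high/low indicator
enters (i) a univariate Cox model and (ii) a multivariate Cox model with
that cohort's available covariates (age continuous; sex, TNM stage
categorical in the generated data). Ties use the Efron approximation
(Breslow selectable); all p-values are two-sided Wald at $\alpha = 0.05$.
Covariates missing in more than 50% of a cohort are dropped from that
cohort's model; remaining missingness is handled complete-case *per model*,
so univariate screening keeps the full cohort. A gene passes OS when in
**every** cohort AUC > 0.5 and both Cox p-values are below 0.05, with one
consistent direction across cohorts. Direction consistency is required
because the final pooled weight is meaningless for a gene that is adverse
in one cohort and protective in another.

**Cross-endpoint filter.** OS survivors are re-tested — with freshly
optimized cutoffs — against the second endpoint (DFS or RFS) in the cohorts
that carry one, requiring the same direction. Genes that cannot predict the
second endpoint are dropped; in particular favorable-direction genes
without relapse signal never reach the score stage. When no cohort carries
a second endpoint the filter can only be skipped with a loud warning (or
forbidden outright).

No per-gene multiple-testing correction is applied: the error control is
replication — p < 0.05 *twice per cohort in five independent cohorts plus a
second endpoint* has a family-wise null rate far below one gene per
transcriptome, which the all-null calibration test verifies directly
(0 hits among 2,000 null genes across five cohorts).

## Stage 2 — coefficient pooling

Score weights must be computable from expression alone, so the
**univariate** dichotomized-group log-hazard coefficients are pooled (the
adjusted coefficients stay in the evidence table). Pooling is always on the
log-hazard scale. With weights $w_i = 1/\mathrm{se}_i^2$:

* Cochran's $Q = \sum_i w_i(\beta_i - \bar\beta_{\mathrm{FE}})^2$, df $= k-1$;
* Higgins' $I^2 = \max\{0, (Q - \mathrm{df})/Q\} \times 100$;
* fixed effects (inverse-variance mean) when $Q$ is non-significant
  (p ≥ 0.05) **and** $I^2 \le 50\%$; otherwise DerSimonian–Laird random
  effects with $\tau^2 = \max\{0, (Q-\mathrm{df})/(\sum w - \sum w^2/\sum w)\}$
  and weights $1/(\mathrm{se}_i^2 + \tau^2)$.

The 0.05 / 50% thresholds are configurable (`heterogeneity_rule()`) and
recorded with the run; the arithmetic is cross-checked against `metafor`
in the test suite. No Hartung–Knapp adjustment or REML $\tau^2$ is offered.

## Stage 3 — exhaustive score search

Every non-empty subset of the surviving genes defines a candidate score
$\mathrm{Score}_s = \sum_g \beta_g^{\mathrm{pooled}} \, x_{gs}$ ($2^k - 1$
subsets, enumerated by size then lexicographically; 11 genes give 2,047).
Because the discovery cohorts may come from incomparable platforms
(RNA-seq vs two microarray families), the default expression scale for the
weighted sum is per-cohort z-scores per gene; `raw` and `log2` are
selectable and are declared inside each `score_definition` so a score is
never applied on an undeclared scale. Each candidate is evaluated per
cohort with its **own** constrained optimal cutoff, and passes only if in
every cohort: univariate HR > 2 and adjusted HR > 1.5 (both p < 0.05), and
AUC, sensitivity and specificity all exceed 0.5 at the chosen cutoff. Among
passing scores the winner is the one with fewest genes; ties fall to the
largest minimum univariate HR across cohorts, then to the lexicographic
gene list, and an empty passing set is an explicit "no score passed"
result rather than an error. The Youden-optimal cutoff can legitimately sit
at an asymmetric operating point with sensitivity below 0.5; the
sensitivity/specificity floors are therefore real constraints, not
formalities.

## Stage 4 — application

* **Normalization.** Scores are divided by their own cohort's median
  (platform-free calibration) and categorized with half-open intervals:
  low < 0.9 ≤ intermediate < 1.1 ≤ high. Median normalization requires a
  positive cohort median; z-scored weighted sums are centered near zero, so
  this stage computes the score on the raw expression scale by default in
  the workflow scripts. The category boundaries are exact: a normalized
  score of 0.9 is intermediate and 1.1 is high.
* **TNM integration.** A total (stage × category) → risk-group map produces
  combined groups. The default map (early stages favorable unless
  score-high; IIIA intermediate unless high; IIIB adverse; IV adverse
  unless high, then very-adverse) is a declared interpretation, and
  `integrate_tnm()` always emits per-group KM medians plus pairwise
  log-rank p-values so any map can be audited. A degenerate stage-only map
  reproduces stage-only stratification bit-identically.
* **External signatures.** Published gene/weight lists are benchmarked
  uniformly: weighted sum, tertile split (type-7 quantiles, boundary ties
  to the lower tertile), univariate Cox of tertile 3 vs tertile 1 with the
  middle tertile excluded, robust iff HR > 1 with p < 0.05 in every
  evaluable cohort. Cohorts covering fewer than 60% of a signature's genes
  are marked not-evaluable; present genes are used as-is rather than
  zero-filled, because zero-filling silently moves tertile boundaries.
* **Drug sensitivity.** Per-drug Spearman correlation between cell-line
  scores and IC50, hit iff |rho| > 0.25 and p < 0.05, pairwise deletion of
  missing IC50, all-tied drugs skipped with a warning; at least eight lines
  are required.

## The synthetic-data generator

`simulate_multicohort()` emulates the study conditions: five cohorts of
345/297/433/93/192 patients; expression standard normal around per-gene
baseline means drawn from Uniform(6, 10) (log2-intensity-like, so raw-scale
scores have positive medians); null genes in exchangeable correlation
blocks (rho 0.3, block size 10); OS from a Weibull proportional-hazards
model (shape 1.2 — visibly non-exponential KM curves; cohort-specific
scales 65/75/70/55/50 months so median OS differs by cohort) with linear
predictor = planted gene effects on mean-centered expression + covariate
effects (0.25 per age decade, 0.15 male, 0.40 per ordinal stage step);
censoring Uniform(0, 120 months) capped administratively at 120, giving
roughly one-third censoring — chosen for estimability of 3-year AUC, not to
match any particular cohort. Cohorts 1, 2 and 4 carry a second endpoint
(DFS/DFS/RFS) generated through a Gaussian copula on the OS latent uniform
(rank correlation 0.8, a free parameter — real DFS/OS dependence is not
identified here) on a 0.7-accelerated time scale, driven only by planted
genes flagged `affects_ep2`. Planted betas receive a per-cohort
Normal(0, tau) perturbation; the default tau = 0.2 makes planted genes show
moderate heterogeneity (I² around 50% at typical coefficient SEs of about
0.2), so both the fixed- and random-effects pooling branches are exercised.
The default planted set is seven adverse dual-endpoint genes at +0.7 per
SD (the signature to recover) and three favorable OS-only genes at −0.5
(which the cross-endpoint filter must drop). Cohort 3 lacks the stage
covariate, emulating heterogeneous clinical annotation.

What the generator does **not** emulate: platform-specific microarray
noise, probe saturation, batch effects, missing expression values,
tumor-vs-normal contrasts, or informative censoring. Passing recovery
tests therefore demonstrate the statistical machinery under clean
proportional-hazards data, not robustness to real-world measurement
artifacts. An important emergent feature it *does* reproduce: with several
planted genes, each gene's marginal dichotomized hazard ratio is attenuated
(the other genes act as frailty), so per-gene HRs land in the 1.3–2.5
range typical of published screens even though the conditional effects are
larger.

## Numerical choices and degenerate inputs

* Cox ties: Efron (Breslow selectable). Non-convergence is reported via a
  flag, never silently; monotone likelihood (complete separation) is
  flagged and coefficients are capped at magnitude 20. Constant covariates
  after complete-case filtering are an error naming the column.
* Constant markers, horizons with no estimable cases or controls, and
  cutoffs that cannot satisfy the 20% rule are explicit errors in the
  single-marker API; the batch screen records such genes as not-evaluable
  (which can never pass) instead of aborting.
* A missing gene in `compute_score()` is an error, never a silent
  zero-fill.
* Gene order is fixed lexicographically (C locale); all batch results are
  deterministic and independent of sample order, which the suite checks by
  permuting a cohort's columns.

## Problem sizes used by the tests and scripts

The test suite screens 2,000 null genes across the five default cohorts
for the null-calibration check and about 200 genes for recovery runs; the
parameter-recovery pipeline uses five cohorts of 250–450 patients with
seven planted genes at +0.7 per SD among 200 genes. The acceptance script
reruns the discovery pipeline at those sizes, a 300-gene five-cohort null
calibration, and a 16-line, 22-drug cell-line panel. These sizes were
chosen so each property is measured at the scale where it is informative
while the whole suite stays quick to run.

## Known limitations

* The screen's error control is replication, not per-gene correction; with
  fewer than about four cohorts the family-wise null rate grows quickly
  (the two-cohort null run lets occasional null genes through).
* Sensitivity/specificity are read at the constrained Youden cutoff; no
  alternative operating-point policies are implemented.
* No penalized-regression or cross-validated alternative to the exhaustive
  threshold search; the subset cap is 20 genes (2^20 − 1 candidates) and
  must be raised explicitly.
* Incident/dynamic ROC variants, time-varying covariates, frailty terms,
  probe-to-gene collapsing, and any enrichment or deconvolution analyses
  are out of scope.
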