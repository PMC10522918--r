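# Synthetic multi-cohort expression + survival generator with planted
# prognostic genes, so every pipeline stage has a ground-truth recovery
# test; plus a toy cell-line expression + drug-IC50 panel.

#' Configuration for the multi-cohort generator
#'
#' Defaults emulate a five-cohort gastric-cancer-style study: cohort sizes
#' 345/297/433/93/192, right-censored OS everywhere, a second endpoint
#' (DFS/RFS) in the first, second and fourth cohorts, cohort-specific
#' covariate availability, and between-cohort heterogeneity of the planted
#' gene effects.
#'
#' @param n_cohorts Number of cohorts.
#' @param cohort_sizes Samples per cohort (each >= 30).
#' @param n_genes Total genes in the universe (planted genes included).
#' @param planted_genes Data frame with `gene`, `beta` (log-hazard per SD of
#'   expression) and `affects_ep2` (logical: does the gene drive the second
#'   endpoint too). Empty data frame = all-null universe.
#' @param block_rho,block_size Exchangeable correlation and block size for
#'   the null-gene correlation blocks (planted genes are independent).
#' @param weibull_shape Baseline Weibull shape (1.2: mildly increasing
#'   hazard, visibly non-exponential KM curves).
#' @param weibull_scale Per-cohort Weibull scale in months (recycled).
#' @param censor_upper Per-cohort upper bound of the uniform censoring draw,
#'   months (recycled).
#' @param admin_cap Administrative censoring cap, months.
#' @param covariate_effects Named log-hazards: `age_per_decade`, `sex_male`,
#'   `stage_step` (per ordinal stage step I < II < IIIA < IIIB < IV).
#' @param between_cohort_sd SD of the per-cohort perturbation added to each
#'   planted beta (between-cohort heterogeneity tau).
#' @param ep2_cohorts Indices of cohorts carrying a second endpoint.
#' @param ep2_kinds Endpoint kind per `ep2_cohorts` entry (`"DFS"`/`"RFS"`).
#' @param ep2_rank_corr Gaussian-copula rank correlation between the latent
#'   OS and second-endpoint event processes (default 0.8).
#' @param ep2_scale_factor Second-endpoint Weibull scale as a fraction of
#'   the OS scale (< 1: relapses come earlier than deaths).
#' @param expr_mean_range Range of per-gene baseline means (log2-intensity
#'   like, so raw-scale scores have positive medians).
#' @param stage_available Logical per cohort: is TNM stage recorded
#'   (emulates cohorts that lack staging columns).
#' @param seed Integer RNG seed; identical configs are bit-reproducible.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_cohorts = 5,
                              cohort_sizes = c(345, 297, 433, 93, 192),
                              n_genes = 200,
                              planted_genes = default_planted_genes(),
                              block_rho = 0.3, block_size = 10,
                              weibull_shape = 1.2,
                              weibull_scale = c(65, 75, 70, 55, 50),
                              censor_upper = 120, admin_cap = 120,
                              covariate_effects = c(age_per_decade = 0.25,
                                                    sex_male = 0.15,
                                                    stage_step = 0.40),
                              between_cohort_sd = 0.2,
                              ep2_cohorts = c(1, 2, 4),
                              ep2_kinds = c("DFS", "DFS", "RFS"),
                              ep2_rank_corr = 0.8,
                              ep2_scale_factor = 0.7,
                              expr_mean_range = c(6, 10),
                              stage_available = NULL,
                              seed = 1L) {
  stopifnot(length(cohort_sizes) == n_cohorts, all(cohort_sizes >= 30),
            block_rho >= 0, block_rho < 1, between_cohort_sd >= 0,
            all(censor_upper > 0), ep2_rank_corr >= 0, ep2_rank_corr <= 1,
            length(ep2_kinds) == length(ep2_cohorts),
            all(ep2_cohorts %in% seq_len(n_cohorts)))
  planted_genes <- as.data.frame(planted_genes)
  if (nrow(planted_genes)) {
    stopifnot(all(c("gene", "beta") %in% names(planted_genes)))
    if (is.null(planted_genes$affects_ep2)) planted_genes$affects_ep2 <- TRUE
    if (anyDuplicated(planted_genes$gene)) stop("duplicated planted genes")
    if (nrow(planted_genes) > n_genes)
      stop("more planted genes than n_genes")
  }
  if (is.null(stage_available)) {
    stage_available <- rep(TRUE, n_cohorts)
    if (n_cohorts >= 3) stage_available[3] <- FALSE
  }
  structure(list(n_cohorts = n_cohorts, cohort_sizes = cohort_sizes,
                 n_genes = n_genes, planted_genes = planted_genes,
                 block_rho = block_rho, block_size = block_size,
                 weibull_shape = weibull_shape,
                 weibull_scale = rep_len(weibull_scale, n_cohorts),
                 censor_upper = rep_len(censor_upper, n_cohorts),
                 admin_cap = admin_cap,
                 covariate_effects = covariate_effects,
                 between_cohort_sd = between_cohort_sd,
                 ep2_cohorts = ep2_cohorts, ep2_kinds = ep2_kinds,
                 ep2_rank_corr = ep2_rank_corr,
                 ep2_scale_factor = ep2_scale_factor,
                 expr_mean_range = expr_mean_range,
                 stage_available = rep_len(stage_available, n_cohorts),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default planted gene set
#'
#' Seven adverse genes driving both endpoints (the signature the pipeline
#' should recover) plus three favorable OS-only genes (which the
#' cross-endpoint filter should drop).
#'
#' @param beta_adverse Log-hazard per SD for the seven dual-endpoint genes.
#' @param beta_favorable Log-hazard per SD for the three OS-only genes
#'   (negative = high expression protective).
#' @return Data frame `gene`, `beta`, `affects_ep2`.
#' @export
default_planted_genes <- function(beta_adverse = 0.7, beta_favorable = -0.5) {
  data.frame(
    gene = c(sprintf("PRG%02d", 1:7), sprintf("FAV%02d", 1:3)),
    beta = c(rep(beta_adverse, 7), rep(beta_favorable, 3)),
    affects_ep2 = c(rep(TRUE, 7), rep(FALSE, 3)),
    stringsAsFactors = FALSE)
}

.stage_levels <- c("I", "II", "IIIA", "IIIB", "IV")

#' Generate multi-cohort expression + survival data with known ground truth
#'
#' Expression is standard normal around per-gene baseline means, with
#' exchangeable correlation blocks among null genes. OS follows a Weibull
#' proportional-hazards model whose linear predictor is the sum of the
#' per-cohort realized planted-gene effects (beta + between-cohort
#' perturbation, applied to mean-centered expression) and the covariate
#' effects; observed time = min(event time, uniform censoring draw,
#' administrative cap). Designated cohorts carry a second endpoint generated
#' from a Gaussian copula on the OS latent uniform (rank correlation
#' `ep2_rank_corr`), driven only by the planted genes with
#' `affects_ep2 = TRUE`, on an accelerated time scale.
#'
#' @param config A [simulation_config()].
#' @return List with `cohorts` (list of [cohort_dataset()]) and `truth`
#'   (planted table, per-cohort realized betas, covariate effects, and
#'   per-cohort latent event times before censoring).
#' @export
simulate_multicohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  pg <- config$planted_genes
  n_planted <- nrow(pg)
  null_ids <- sprintf("G%04d", seq_len(config$n_genes - n_planted))
  genes <- sort(c(if (n_planted) pg$gene, null_ids), method = "radix")
  if (n_planted && !all(pg$gene %in% genes))
    stop("planted gene id absent from gene universe")
  mu <- stats::runif(length(genes), config$expr_mean_range[1],
                     config$expr_mean_range[2])
  names(mu) <- genes
  is_null <- !(genes %in% pg$gene)
  null_genes <- genes[is_null]
  block_of <- ceiling(seq_along(null_genes) / config$block_size)

  realized <- matrix(0, nrow = config$n_cohorts, ncol = n_planted,
                     dimnames = list(NULL, pg$gene))
  cohorts <- vector("list", config$n_cohorts)
  latent <- vector("list", config$n_cohorts)
  ce <- config$covariate_effects

  for (i in seq_len(config$n_cohorts)) {
    n <- config$cohort_sizes[i]
    sid <- sprintf("C%d_S%03d", i, seq_len(n))

    expr <- matrix(0, nrow = length(genes), ncol = n,
                   dimnames = list(genes, sid))
    r <- sqrt(config$block_rho)
    for (b in unique(block_of)) {
      gset <- null_genes[block_of == b]
      zb <- stats::rnorm(n)
      eps <- matrix(stats::rnorm(length(gset) * n), nrow = length(gset))
      expr[gset, ] <- r * rep(zb, each = length(gset)) +
        sqrt(1 - config$block_rho) * eps
    }
    if (n_planted)
      expr[pg$gene, ] <- matrix(stats::rnorm(n_planted * n), nrow = n_planted)
    centered <- expr
    expr <- expr + mu[genes]

    age <- round(stats::rnorm(n, 63, 10))
    sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.35, 0.65))
    stage <- sample(.stage_levels, n, replace = TRUE,
                    prob = c(0.15, 0.20, 0.35, 0.10, 0.20))
    lp_cov <- ce[["age_per_decade"]] * (age - 63) / 10 +
      ce[["sex_male"]] * (sex == "M") +
      ce[["stage_step"]] * (match(stage, .stage_levels) - 1)

    if (n_planted) {
      beta_i <- pg$beta + stats::rnorm(n_planted, 0, config$between_cohort_sd)
      realized[i, ] <- beta_i
      lp_gene <- drop(crossprod(centered[pg$gene, , drop = FALSE], beta_i))
    } else lp_gene <- numeric(n)
    lp <- lp_gene + lp_cov

    u <- stats::runif(n)
    t_event <- config$weibull_scale[i] *
      (-log(u) / exp(lp))^(1 / config$weibull_shape)
    c_time <- pmin(stats::runif(n, 0, config$censor_upper[i]),
                   config$admin_cap)
    os_time <- pmin(t_event, c_time)
    os_event <- as.integer(t_event <= c_time)

    ep2_kind <- "none"
    ep2_time <- ep2_event <- NULL
    t2_event <- NULL
    if (i %in% config$ep2_cohorts) {
      ep2_kind <- config$ep2_kinds[match(i, config$ep2_cohorts)]
      z1 <- stats::qnorm(u)
      z2 <- config$ep2_rank_corr * z1 +
        sqrt(1 - config$ep2_rank_corr^2) * stats::rnorm(n)
      u2 <- stats::pnorm(z2)
      if (n_planted) {
        b2 <- beta_i * pg$affects_ep2
        lp2 <- drop(crossprod(centered[pg$gene, , drop = FALSE], b2)) + lp_cov
      } else lp2 <- lp_cov
      t2_event <- config$ep2_scale_factor * config$weibull_scale[i] *
        (-log(u2) / exp(lp2))^(1 / config$weibull_shape)
      c2 <- pmin(stats::runif(n, 0, config$censor_upper[i]), config$admin_cap)
      ep2_time <- pmin(t2_event, c2)
      ep2_event <- as.integer(t2_event <= c2)
    }

    covs <- data.frame(age = as.numeric(age), sex = factor(sex),
                       stage = factor(stage, levels = .stage_levels),
                       row.names = sid)
    avail <- c("age", "sex", if (config$stage_available[i]) "stage")

    cohorts[[i]] <- cohort_dataset(
      cohort_id = sprintf("SIM%d", i), expression = expr,
      os_time = os_time, os_event = os_event,
      ep2_kind = ep2_kind, ep2_time = ep2_time, ep2_event = ep2_event,
      covariates = covs, available_covariates = avail)
    latent[[i]] <- list(os = t_event, ep2 = t2_event)
  }

  list(cohorts = cohorts,
       truth = list(planted = pg, realized_betas = realized,
                    covariate_effects = ce, latent_times = latent,
                    seed = config$seed))
}

#' Configuration for the toy cell-line drug panel
#'
#' @param n_lines Cell lines (>= 8; rank correlation is unstable below).
#' @param n_genes Genes in the line expression matrix.
#' @param signature List with `genes` and `weights` defining the score whose
#'   drug associations are planted; defaults to the seven default planted
#'   genes with unit weights.
#' @param planted_drugs Data frame `drug`, `rho` (target Spearman
#'   correlation between score and IC50; negative = high score lines are
#'   more sensitive). `|rho| = 1` gives an exactly monotone, noise-free
#'   relation.
#' @param n_null_drugs Independent null drugs appended.
#' @param seed RNG seed.
#' @return List of class `cellline_config`.
#' @export
cellline_config <- function(n_lines = 16, n_genes = 50,
                            signature = NULL,
                            planted_drugs = data.frame(
                              drug = c("DRUG_P1", "DRUG_P2"),
                              rho = c(-0.9, -0.9)),
                            n_null_drugs = 20, seed = 1L) {
  if (n_lines < 8) stop("need >= 8 cell lines (rank correlation unstable)")
  if (is.null(signature))
    signature <- list(genes = sprintf("PRG%02d", 1:7), weights = rep(1, 7))
  planted_drugs <- as.data.frame(planted_drugs)
  if (nrow(planted_drugs) < 1)
    stop("need >= 1 drug with a planted score-IC50 correlation")
  stopifnot(all(abs(planted_drugs$rho) <= 1))
  structure(list(n_lines = n_lines, n_genes = n_genes, signature = signature,
                 planted_drugs = planted_drugs, n_null_drugs = n_null_drugs,
                 seed = as.integer(seed)),
            class = "cellline_config")
}

#' Generate a toy cell-line expression + drug-IC50 panel
#'
#' Expression is standard normal around gene baseline means. Planted drugs'
#' log-IC50 is a linear-in-score Gaussian-copula draw targeting the
#' configured correlation (`|rho| = 1` is the noise-free monotone limit);
#' null drugs are independent noise.
#'
#' @param config A [cellline_config()].
#' @return List: `expression` (genes x lines), `ic50` (drugs x lines),
#'   `score` (per line, from the configured signature), `truth`.
#' @export
simulate_celllines <- function(config = cellline_config()) {
  stopifnot(inherits(config, "cellline_config"))
  set.seed(config$seed)
  sig <- config$signature
  extra <- max(0, config$n_genes - length(sig$genes))
  genes <- sort(c(sig$genes, sprintf("CLG%03d", seq_len(extra))),
                method = "radix")
  lines <- sprintf("LINE%02d", seq_len(config$n_lines))
  mu <- stats::runif(length(genes), 6, 10)
  expr <- matrix(stats::rnorm(length(genes) * config$n_lines), ncol = config$n_lines,
                 dimnames = list(genes, lines)) + mu
  def <- score_definition(sig$genes, sig$weights, scale = "zscore")
  score <- compute_score(expr, def)

  zs <- as.numeric(scale(score))
  pd <- config$planted_drugs
  ic50 <- matrix(NA_real_, nrow = nrow(pd) + config$n_null_drugs,
                 ncol = config$n_lines,
                 dimnames = list(c(pd$drug,
                                   sprintf("DRUG_N%02d", seq_len(config$n_null_drugs))),
                                 lines))
  for (j in seq_len(nrow(pd))) {
    a <- pd$rho[j]
    ic50[pd$drug[j], ] <- a * zs + sqrt(1 - a^2) * stats::rnorm(config$n_lines)
  }
  if (config$n_null_drugs)
    ic50[nrow(pd) + seq_len(config$n_null_drugs), ] <-
      matrix(stats::rnorm(config$n_null_drugs * config$n_lines),
             nrow = config$n_null_drugs)

  list(expression = expr, ic50 = ic50, score = score,
       truth = list(planted_drugs = pd, signature = sig, seed = config$seed))
}
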