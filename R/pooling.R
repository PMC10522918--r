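# Stage 2: meta-analytic pooling of per-cohort Cox log-hazard coefficients.
# Pooling is always on the log-hazard scale, never on the HR scale.

#' Cochran's Q heterogeneity test
#'
#' Q = sum of w_i (beta_i - beta_fixed)^2 with inverse-variance weights
#' w_i = 1/se_i^2 and beta_fixed the inverse-variance weighted mean;
#' p from a chi-square with k - 1 degrees of freedom.
#'
#' @param betas Per-study log-hazard coefficients (k >= 2).
#' @param ses Positive standard errors.
#' @return List with `q`, `df`, `p`, `beta_fixed`.
#' @export
cochran_q <- function(betas, ses) {
  stopifnot(length(betas) == length(ses))
  if (length(betas) < 2) stop("Cochran's Q requires >= 2 studies")
  if (any(!is.finite(ses)) || any(ses <= 0)) stop("all ses must be > 0")
  w <- 1 / ses^2
  bf <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - bf)^2)
  df <- length(betas) - 1
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE),
       beta_fixed = bf)
}

#' Higgins' I-squared
#'
#' Percentage of total variation across studies attributable to
#' heterogeneity: max(0, (Q - df)/Q) * 100, and 0 when Q = 0.
#'
#' @param q Cochran's Q (>= 0).
#' @param df Degrees of freedom (>= 1).
#' @return Percentage in [0, 100).
#' @export
i_squared <- function(q, df) {
  stopifnot(q >= 0, df >= 1)
  if (q <= 0) return(0)
  max(0, (q - df) / q) * 100
}

#' Pool per-cohort coefficients by fixed or random effects
#'
#' The effects model follows the heterogeneity rule: fixed-effects
#' inverse-variance pooling when Q is non-significant
#' (`q_p >= rule$q_p_threshold`) and I-squared is at most
#' `rule$i2_threshold`; otherwise DerSimonian-Laird random effects with
#' tau^2 = max(0, (Q - df) / (sum w - sum w^2 / sum w)) and weights
#' 1/(se^2 + tau^2). The pooled standard error is 1/sqrt(sum weights).
#'
#' @inheritParams cochran_q
#' @param rule [heterogeneity_rule()].
#' @param gene Optional identifier carried through.
#' @param model `"auto"` (default: follow the heterogeneity rule), or force
#'   `"fixed"`/`"random"`.
#' @return Object of class `pooled_coefficient`: inputs, `q`, `q_df`, `q_p`,
#'   `i2` (percent), `tau2`, `model` (`"fixed"`/`"random"`), `beta_pooled`,
#'   `se_pooled`, `ci95`.
#' @export
pool_beta <- function(betas, ses, rule = heterogeneity_rule(),
                      gene = NA_character_,
                      model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  cq <- cochran_q(betas, ses)
  i2 <- i_squared(cq$q, cq$df)
  w <- 1 / ses^2
  use_fixed <- switch(model,
                      auto = cq$p >= rule$q_p_threshold && i2 <= rule$i2_threshold,
                      fixed = TRUE,
                      random = FALSE)
  if (use_fixed) {
    model <- "fixed"
    tau2 <- 0
    wts <- w
  } else {
    model <- "random"
    tau2 <- max(0, (cq$q - cq$df) / (sum(w) - sum(w^2) / sum(w)))
    wts <- 1 / (ses^2 + tau2)
  }
  beta_pooled <- sum(wts * betas) / sum(wts)
  se_pooled <- 1 / sqrt(sum(wts))
  structure(list(gene = gene, betas = betas, ses = ses,
                 q = cq$q, q_df = cq$df, q_p = cq$p, i2 = i2, tau2 = tau2,
                 model = model, beta_pooled = beta_pooled,
                 se_pooled = se_pooled,
                 ci95 = c(lower = beta_pooled - 1.96 * se_pooled,
                          upper = beta_pooled + 1.96 * se_pooled)),
            class = "pooled_coefficient")
}

#' @export
print.pooled_coefficient <- function(x, ...) {
  cat("<pooled_coefficient>", if (!is.na(x$gene)) x$gene else "",
      sprintf("beta = %.4f (se %.4f, %s effects); Q = %.3f (p = %.3g), I2 = %.1f%%\n",
              x$beta_pooled, x$se_pooled, x$model, x$q, x$q_p, x$i2))
  invisible(x)
}

#' Pool the screened univariate coefficients for a gene list
#'
#' For each gene, pools the per-cohort UNIVARIATE dichotomized-group OS
#' log-hazard coefficients (the weights of the score formula must be
#' computable from expression alone, so the covariate-adjusted coefficients
#' are retained in the evidence table but not pooled).
#'
#' @param screen A `gene_screen` (after [screen_all()]).
#' @param genes Genes to pool (default: the screen's `final_genes`).
#' @param rule [heterogeneity_rule()].
#' @return Data frame: `gene`, `k`, `q`, `q_p`, `i2`, `tau2`, `model`,
#'   `beta_pooled`, `se_pooled`.
#' @export
pool_screen <- function(screen, genes = screen$final_genes,
                        rule = heterogeneity_rule()) {
  stopifnot(inherits(screen, "gene_screen"))
  if (!length(genes))
    return(data.frame(gene = character(), k = integer(), q = numeric(),
                      q_p = numeric(), i2 = numeric(), tau2 = numeric(),
                      model = character(), beta_pooled = numeric(),
                      se_pooled = numeric(), stringsAsFactors = FALSE))
  ev <- screen$evidence[screen$evidence$endpoint == "OS", ]
  out <- lapply(sort(genes, method = "radix"), function(g) {
    rows <- ev[ev$gene == g & ev$evaluable, ]
    pb <- pool_beta(rows$uni_beta, rows$uni_se, rule, gene = g)
    data.frame(gene = g, k = nrow(rows), q = pb$q, q_p = pb$q_p, i2 = pb$i2,
               tau2 = pb$tau2, model = pb$model, beta_pooled = pb$beta_pooled,
               se_pooled = pb$se_pooled, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
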