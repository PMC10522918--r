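#' Cox proportional-hazards fit with a fixed reporting contract
#'
#' Partial-likelihood maximization via `survival::coxph` with Efron handling
#' of tied event times (Breslow selectable). Categorical covariates are
#' expanded against a reference level (first by sorted order). Samples with a
#' missing value in any design column are excluded (complete-case per model);
#' Wald standard errors come from the observed information.
#'
#' Non-convergence is reported through `converged = FALSE`, never silently.
#' Monotone likelihood (complete separation) is flagged and the offending
#' coefficients capped at magnitude 20.
#'
#' @param design Data frame of covariates (numeric = continuous,
#'   factor/character/logical = categorical).
#' @param time,event Right-censored endpoint aligned with `design` rows.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_fit`: named `beta`, `se`, `hr`, `p`, `z`,
#'   `ci95` (HR-scale matrix), `n_used`, `n_events`, `converged`, `monotone`.
#' @export
fit_cox <- function(design, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  design <- as.data.frame(design)
  stopifnot(nrow(design) == length(time), length(time) == length(event))
  if (sum(event, na.rm = TRUE) < 1) stop("Cox fit requires at least one event")

  dat <- cbind(.t = time, .e = event, design)
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  for (nm in names(design)) {
    v <- dat[[nm]]
    if (is.character(v) || is.logical(v)) v <- dat[[nm]] <- factor(v)
    if (is.factor(v)) {
      dat[[nm]] <- droplevels(v)
      if (nlevels(dat[[nm]]) < 2)
        stop("constant covariate after complete-case filtering: ", nm)
    } else if (length(unique(v)) < 2) {
      stop("constant covariate after complete-case filtering: ", nm)
    }
  }
  if (sum(dat$.e) < 1) stop("no events remain after complete-case filtering")

  fml <- stats::as.formula(paste(
    "survival::Surv(.t, .e) ~",
    paste(sprintf("`%s`", names(design)), collapse = " + ")))
  converged <- TRUE
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties, model = FALSE),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("did not converge|Ran out of iterations", msg))
        converged <<- FALSE
      if (grepl("infinite|converge", msg) && grepl("beta|coefficient", msg))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    })

  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  big <- which(abs(beta) > 20)
  if (length(big)) {
    monotone <- TRUE
    beta[big] <- sign(beta[big]) * 20
  }
  n_events <- sum(dat$.e)
  if (n_events < 10 * length(beta))
    warning("fewer than 10 events per coefficient (", n_events, " events, ",
            length(beta), " coefficients); estimates may be unstable")
  z <- beta / se
  structure(list(
    beta = beta, se = se, hr = exp(beta), z = z,
    p = 2 * stats::pnorm(-abs(z)),
    ci95 = cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se)),
    n_used = nrow(dat), n_events = n_events,
    converged = converged, monotone = monotone
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> n =", x$n_used, "(", x$n_events, "events );",
      if (!x$converged) "NOT converged;" else NULL,
      if (x$monotone) "monotone likelihood flagged;" else NULL, "\n")
  print(data.frame(beta = x$beta, se = x$se, HR = x$hr, p = x$p))
  invisible(x)
}

# Lean univariate fit on a 0/1 indicator for batch screening. Returns NA
# statistics (rather than erroring) when the fit is degenerate.
.cox_indicator <- function(ind, time, event, ties = "efron") {
  out <- list(beta = NA_real_, se = NA_real_, hr = NA_real_, p = NA_real_,
              converged = FALSE)
  if (length(unique(ind)) < 2 || sum(event) < 1) return(out)
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(time, event) ~ ind, ties = ties, model = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  b <- unname(stats::coef(fit)[1])
  s <- sqrt(stats::vcov(fit)[1, 1])
  if (!is.finite(b) || !is.finite(s)) return(out)
  if (abs(b) > 20) b <- sign(b) * 20
  list(beta = b, se = s, hr = exp(b), p = 2 * stats::pnorm(-abs(b / s)),
       converged = TRUE)
}

# Covariate-adjusted fit on indicator + cohort covariates; reports the
# indicator coefficient. Covariates that are constant after complete-case
# restriction are dropped (recorded in `dropped`). NA statistics on failure.
.cox_adjusted <- function(ind, time, event, covariates, ties = "efron") {
  out <- list(beta = NA_real_, se = NA_real_, hr = NA_real_, p = NA_real_,
              converged = FALSE, dropped = character())
  dat <- data.frame(.t = time, .e = event, grp = as.numeric(ind))
  if (!is.null(covariates) && ncol(covariates))
    dat <- cbind(dat, covariates)
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  if (sum(dat$.e) < 1 || length(unique(dat$grp)) < 2) return(out)
  keep <- "grp"
  dropped <- character()
  for (nm in setdiff(names(dat), c(".t", ".e", "grp"))) {
    v <- dat[[nm]]
    if (is.character(v) || is.logical(v)) v <- factor(v)
    if (is.factor(v)) {
      v <- droplevels(v)
      dat[[nm]] <- v
      if (nlevels(v) < 2) { dropped <- c(dropped, nm); next }
    } else if (length(unique(v)) < 2) { dropped <- c(dropped, nm); next }
    keep <- c(keep, nm)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(.t, .e) ~", paste(sprintf("`%s`", keep), collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(survival::coxph(fml, data = dat, ties = ties,
                                     model = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) { out$dropped <- dropped; return(out) }
  b <- unname(stats::coef(fit)["grp"])
  vc <- stats::vcov(fit)
  s <- sqrt(vc["grp", "grp"])
  if (!is.finite(b) || !is.finite(s)) { out$dropped <- dropped; return(out) }
  if (abs(b) > 20) b <- sign(b) * 20
  list(beta = b, se = s, hr = exp(b), p = 2 * stats::pnorm(-abs(b / s)),
       converged = TRUE, dropped = dropped)
}
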