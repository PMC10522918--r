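# Stage 1: per-gene dichotomization, dual Cox testing, multi-cohort
# consistency, and the OS -> DFS/RFS cross-endpoint filter.

# Prepared per-cohort evaluation context for one endpoint: samples with the
# endpoint observed, time-sorted ROC context, and the usable covariate table
# (available covariates minus those missing in > 50% of the cohort's
# endpoint samples).
.screen_ctx <- function(cohort, horizon, endpoint = c("OS", "EP2")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "OS") {
    incl <- rep(TRUE, n_samples(cohort))
    time <- cohort$os_time
    event <- cohort$os_event
  } else {
    if (cohort$ep2_kind == "none") return(NULL)
    incl <- !is.na(cohort$ep2_time) & !is.na(cohort$ep2_event)
    time <- cohort$ep2_time[incl]
    event <- cohort$ep2_event[incl]
  }
  covs <- cohort$covariates[incl, cohort$available_covariates, drop = FALSE]
  dropped <- character()
  if (ncol(covs)) {
    miss <- vapply(covs, function(v) mean(is.na(v)), numeric(1))
    dropped <- names(covs)[miss > 0.5]
    covs <- covs[, miss <= 0.5, drop = FALSE]
  }
  list(cohort_id = cohort$cohort_id, endpoint = endpoint,
       incl = which(incl), time = time, event = event,
       ctx = .roc_ctx(time, event, horizon), covs = covs,
       dropped_covariates = dropped)
}

# Evaluate one gene (marker restricted to context samples) in one cohort.
.screen_one <- function(marker_full, sc, criteria) {
  na_row <- list(n = length(sc$incl), cutoff = NA_real_, auc = NA_real_,
                 auc_raw = NA_real_, sens = NA_real_, spec = NA_real_,
                 uni_beta = NA_real_, uni_se = NA_real_, uni_hr = NA_real_,
                 uni_p = NA_real_, multi_beta = NA_real_, multi_se = NA_real_,
                 multi_hr = NA_real_, multi_p = NA_real_,
                 direction = NA_character_, evaluable = FALSE, reason = "")
  marker <- marker_full[sc$incl]
  d <- .dichotomize_risk(marker, sc$ctx, criteria$min_group_frac)
  if (!d$feasible) {
    na_row$reason <- d$reason
    if (!is.null(d$auc_raw)) na_row$auc_raw <- d$auc_raw
    return(na_row)
  }
  uni <- .cox_indicator(d$indicator, sc$time, sc$event)
  if (!uni$converged) {
    na_row$reason <- "univariate Cox fit failed"
    return(na_row)
  }
  multi <- .cox_adjusted(d$indicator, sc$time, sc$event, sc$covs)
  list(n = length(marker), cutoff = d$cutoff, auc = d$auc_risk,
       auc_raw = d$auc_raw, sens = d$sens, spec = d$spec,
       uni_beta = uni$beta, uni_se = uni$se, uni_hr = uni$hr, uni_p = uni$p,
       multi_beta = multi$beta, multi_se = multi$se, multi_hr = multi$hr,
       multi_p = multi$p,
       direction = if (uni$hr > 1) "adverse-high" else "favorable-high",
       evaluable = TRUE,
       reason = if (!multi$converged) "adjusted Cox fit failed" else "")
}

.row_fields <- c("n", "cutoff", "auc", "auc_raw", "sens", "spec",
                 "uni_beta", "uni_se", "uni_hr", "uni_p",
                 "multi_beta", "multi_se", "multi_hr", "multi_p",
                 "direction", "evaluable", "reason")

# Gene-level pass verdict over a block of per-cohort rows (one endpoint):
# every cohort evaluable with significant uni+multi Cox, AUC above the
# floor, and one consistent hazard direction.
.block_pass <- function(rows, criteria) {
  ev <- rows$evaluable & !is.na(rows$multi_p)
  if (criteria$require_all_cohorts && !all(ev)) return(FALSE)
  if (!any(ev)) return(FALSE)
  ok <- rows$auc[ev] > criteria$auc_min &
    rows$uni_p[ev] < criteria$alpha & rows$multi_p[ev] < criteria$alpha
  all(ok) && length(unique(rows$direction[ev])) == 1
}

#' Screen one gene for prognostic association across cohorts
#'
#' In each cohort independently: dichotomize expression at the constrained
#' optimal cutoff for the configured horizon (risk-oriented: markers whose
#' high values are protective are cut on the negated scale), fit a univariate
#' Cox model on the high/low indicator and a multivariate Cox model adding
#' the cohort's available covariates, and record AUC, coefficients and
#' directions. The OS pass verdict requires AUC > `auc_min` and both Cox
#' p-values < `alpha` in every cohort plus a consistent direction.
#'
#' @param cohorts List of [cohort_dataset()] objects.
#' @param gene Gene identifier present in every cohort.
#' @param criteria [screen_criteria()].
#' @return List with `evidence` (one row per cohort), `os_pass`, `direction`.
#' @export
screen_gene <- function(cohorts, gene, criteria = screen_criteria()) {
  res <- screen_all(cohorts, criteria, genes = gene, verbose = FALSE)
  list(evidence = res$evidence, os_pass = res$summary$os_pass[1],
       direction = res$summary$direction[1])
}

#' Screen every common gene across cohorts
#'
#' Maps the per-gene screen over all genes shared by every cohort, in
#' deterministic lexicographic (C-locale) order, and assembles the full
#' evidence table plus per-gene OS pass verdicts.
#'
#' @inheritParams screen_gene
#' @param genes Optional subset of genes to screen; default all common genes.
#' @param verbose Progress messages every 250 genes.
#' @return Object of class `gene_screen`: `evidence` (gene x cohort rows for
#'   OS), `summary` (per gene: `direction`, `os_pass`, `ep2_pass`,
#'   `final_pass`; the latter two are `NA` until [cross_endpoint_filter()]
#'   runs), `criteria`, `cohort_ids`.
#' @export
screen_all <- function(cohorts, criteria = screen_criteria(), genes = NULL,
                       verbose = TRUE) {
  stopifnot(length(cohorts) >= 1)
  common <- Reduce(intersect, lapply(cohorts, function(co) rownames(co$expression)))
  if (is.null(genes)) genes <- common
  else {
    missing <- setdiff(genes, common)
    if (length(missing))
      stop("genes absent from some cohort: ", paste(missing, collapse = ", "))
  }
  if (!length(genes)) stop("empty common gene set")
  genes <- sort(genes, method = "radix")
  cids <- vapply(cohorts, `[[`, "", "cohort_id")
  G <- length(genes); C <- length(cohorts)

  sctx <- lapply(cohorts, .screen_ctx, horizon = criteria$horizon_months,
                 endpoint = "OS")
  rows <- vector("list", G * C)
  for (g in seq_len(G)) {
    for (ci in seq_len(C)) {
      marker <- cohorts[[ci]]$expression[genes[g], ]
      rows[[(g - 1L) * C + ci]] <- .screen_one(marker, sctx[[ci]], criteria)
    }
    if (verbose && g %% 250 == 0)
      message("screened ", g, "/", G, " genes")
  }
  evidence <- data.frame(
    gene = rep(genes, each = C), cohort = rep(cids, G),
    endpoint = "OS", stringsAsFactors = FALSE)
  for (f in .row_fields)
    evidence[[f]] <- unlist(lapply(rows, `[[`, f), use.names = FALSE)

  os_pass <- logical(G)
  direction <- character(G)
  for (g in seq_len(G)) {
    blk <- evidence[((g - 1L) * C + 1L):(g * C), ]
    os_pass[g] <- .block_pass(blk, criteria)
    dirs <- unique(blk$direction[blk$evaluable])
    direction[g] <- if (length(dirs) == 1) dirs else NA_character_
  }
  summary <- data.frame(gene = genes, direction = direction,
                        os_pass = os_pass, ep2_pass = NA, final_pass = NA,
                        stringsAsFactors = FALSE)
  structure(list(evidence = evidence, summary = summary,
                 criteria = criteria, cohort_ids = cids),
            class = "gene_screen")
}

#' @export
print.gene_screen <- function(x, ...) {
  cat("<gene_screen> ", nrow(x$summary), " genes x ",
      length(x$cohort_ids), " cohorts; ", sum(x$summary$os_pass),
      " pass OS", sep = "")
  if (!all(is.na(x$summary$final_pass)))
    cat("; ", sum(x$summary$final_pass, na.rm = TRUE), " pass OS + second endpoint",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Cross-endpoint (OS to DFS/RFS) filter
#'
#' Re-runs the dichotomized dual-Cox + AUC test of OS-passing genes against
#' the second endpoint in the cohorts that carry one (cutoffs re-optimized
#' per endpoint). A gene survives only if it also passes in every
#' endpoint-carrying cohort with the same hazard direction as its OS
#' consensus; in particular, favorable-direction genes without a
#' second-endpoint signal are dropped.
#'
#' @param screen A `gene_screen` from [screen_all()].
#' @param cohorts The cohort list the screen was run on.
#' @param allow_skip When no cohort carries a second endpoint: if `TRUE`
#'   (default) the filter is skipped with a loud warning and OS passes stand;
#'   if `FALSE` this is an error.
#' @return The `gene_screen` with `ep2_pass`/`final_pass` filled in, EP2
#'   evidence rows appended, and `final_genes` (sorted character vector).
#' @export
cross_endpoint_filter <- function(screen, cohorts, allow_skip = TRUE) {
  stopifnot(inherits(screen, "gene_screen"))
  criteria <- screen$criteria
  has_ep2 <- vapply(cohorts, function(co) co$ep2_kind != "none", logical(1))
  if (!any(has_ep2)) {
    if (!allow_skip) stop("no cohort carries a second endpoint")
    warning("no cohort carries a second endpoint: cross-endpoint filter ",
            "SKIPPED; final gene list rests on OS alone", call. = FALSE)
    screen$summary$ep2_pass <- NA
    screen$summary$final_pass <- screen$summary$os_pass
    screen$final_genes <- sort(screen$summary$gene[screen$summary$os_pass],
                               method = "radix")
    return(screen)
  }
  ep2_cohorts <- cohorts[has_ep2]
  sctx <- lapply(ep2_cohorts, .screen_ctx, horizon = criteria$horizon_months,
                 endpoint = "EP2")
  cand <- screen$summary$gene[screen$summary$os_pass]
  C2 <- length(ep2_cohorts)
  rows <- vector("list", length(cand) * C2)
  ep2_pass <- rep(NA, nrow(screen$summary))
  for (i in seq_along(cand)) {
    for (ci in seq_len(C2)) {
      marker <- ep2_cohorts[[ci]]$expression[cand[i], ]
      rows[[(i - 1L) * C2 + ci]] <- .screen_one(marker, sctx[[ci]], criteria)
    }
    blk_idx <- ((i - 1L) * C2 + 1L):(i * C2)
    blk <- rows[blk_idx]
    blk_df <- data.frame(
      evaluable = vapply(blk, `[[`, logical(1), "evaluable"),
      multi_p = vapply(blk, `[[`, numeric(1), "multi_p"),
      uni_p = vapply(blk, `[[`, numeric(1), "uni_p"),
      auc = vapply(blk, `[[`, numeric(1), "auc"),
      direction = vapply(blk, `[[`, character(1), "direction"))
    gidx <- match(cand[i], screen$summary$gene)
    os_dir <- screen$summary$direction[gidx]
    ep2_pass[gidx] <- .block_pass(blk_df, criteria) &&
      all(blk_df$direction[blk_df$evaluable] == os_dir)
  }
  if (length(cand)) {
    ep2_evidence <- data.frame(
      gene = rep(cand, each = C2),
      cohort = rep(vapply(ep2_cohorts, `[[`, "", "cohort_id"), length(cand)),
      endpoint = rep(vapply(ep2_cohorts, `[[`, "", "ep2_kind"), length(cand)),
      stringsAsFactors = FALSE)
    for (f in .row_fields)
      ep2_evidence[[f]] <- unlist(lapply(rows, `[[`, f), use.names = FALSE)
    screen$evidence <- rbind(screen$evidence, ep2_evidence)
  }
  screen$summary$ep2_pass <- ep2_pass
  screen$summary$final_pass <- screen$summary$os_pass &
    !is.na(ep2_pass) & ep2_pass
  screen$final_genes <- sort(screen$summary$gene[screen$summary$final_pass],
                             method = "radix")
  screen
}
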