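#' Construct a validated cohort dataset
#'
#' Bundles one cohort's gene-expression matrix (genes x samples) with its
#' right-censored overall-survival endpoint, an optional second endpoint
#' (disease-free or relapse-free survival), and a per-sample covariate table.
#' Every downstream stage (screening, score evaluation, staging integration)
#' operates on this container.
#'
#' @param cohort_id Short identifier, e.g. `"TCGA"`.
#' @param expression Numeric matrix, rows = unique gene identifiers, columns =
#'   unique sample identifiers. Values must be finite.
#' @param os_time,os_event Overall survival: non-negative follow-up time in
#'   months and event indicator (1 = death, 0 = censored), one per sample, in
#'   expression column order.
#' @param ep2_kind One of `"none"`, `"DFS"`, `"RFS"`. When not `"none"`,
#'   `ep2_time`/`ep2_event` must be supplied.
#' @param ep2_time,ep2_event Second endpoint, same contract as OS. `NA` entries
#'   are allowed for samples without second-endpoint follow-up.
#' @param covariates Data frame of per-sample covariates (rownames or order
#'   matching samples). Columns must be numeric (continuous) or
#'   factor/character (categorical). May be missing (`NA`) per sample.
#' @param available_covariates Character vector of covariate names usable for
#'   multivariate adjustment in this cohort; must be a subset of
#'   `names(covariates)`.
#'
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(cohort_id, expression, os_time, os_event,
                           ep2_kind = c("none", "DFS", "RFS"),
                           ep2_time = NULL, ep2_event = NULL,
                           covariates = NULL, available_covariates = character()) {
  ep2_kind <- match.arg(ep2_kind)
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  n <- ncol(expression)

  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("expression matrix must have gene rownames and sample colnames")
  dup_g <- unique(rownames(expression)[duplicated(rownames(expression))])
  if (length(dup_g))
    stop("duplicated gene identifiers: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(expression)[duplicated(colnames(expression))])
  if (length(dup_s))
    stop("duplicated sample identifiers: ", paste(dup_s, collapse = ", "))
  if (any(!is.finite(expression)))
    stop("expression contains non-finite values")

  check_endpoint <- function(time, event, label, allow_na = FALSE) {
    if (length(time) != n || length(event) != n)
      stop(label, " time/event must have one entry per sample")
    ok <- if (allow_na) !is.na(time) & !is.na(event) else rep(TRUE, n)
    if (!allow_na && (anyNA(time) || anyNA(event)))
      stop(label, " time/event must not contain NA")
    if (any(time[ok] < 0)) stop(label, " times must be >= 0")
    if (!all(event[ok] %in% c(0, 1))) stop(label, " events must be 0/1")
  }
  check_endpoint(os_time, os_event, "OS")
  if (ep2_kind != "none") {
    if (is.null(ep2_time) || is.null(ep2_event))
      stop("ep2_kind = ", ep2_kind, " requires ep2_time and ep2_event")
    check_endpoint(ep2_time, ep2_event, ep2_kind, allow_na = TRUE)
  } else {
    ep2_time <- ep2_event <- NULL
  }

  if (is.null(covariates)) covariates <- data.frame(row.names = colnames(expression))
  if (nrow(covariates) != n)
    stop("covariates must have one row per sample")
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  rownames(covariates) <- colnames(expression)
  bad <- setdiff(available_covariates, names(covariates))
  if (length(bad))
    stop("available_covariates not present in covariate table: ",
         paste(bad, collapse = ", "))
  for (cv in available_covariates) {
    v <- covariates[[cv]]
    if (!is.numeric(v)) {
      lev <- unique(v[!is.na(v)])
      if (length(lev) < 2)
        stop("categorical covariate '", cv, "' has fewer than 2 observed levels")
    }
  }

  structure(list(
    cohort_id = as.character(cohort_id),
    expression = expression,
    os_time = as.numeric(os_time),
    os_event = as.integer(os_event),
    ep2_kind = ep2_kind,
    ep2_time = if (!is.null(ep2_time)) as.numeric(ep2_time),
    ep2_event = if (!is.null(ep2_event)) as.integer(ep2_event),
    covariates = covariates,
    available_covariates = as.character(available_covariates)
  ), class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset> ", x$cohort_id, ": ",
      nrow(x$expression), " genes x ", ncol(x$expression), " samples; ",
      sum(x$os_event), " OS events", sep = "")
  if (x$ep2_kind != "none")
    cat("; second endpoint ", x$ep2_kind,
        " (", sum(!is.na(x$ep2_time)), " samples)", sep = "")
  if (length(x$available_covariates))
    cat("\n  covariates: ", paste(x$available_covariates, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Number of samples in a cohort
#' @param cohort A `cohort_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(cohort) ncol(cohort$expression)

#' Column-mapping specification for reading cohort files
#'
#' Declares how the on-disk clinical table maps onto the cohort data model:
#' which columns carry the sample identifier, the OS and (optional) second
#' endpoint, and which remaining columns are covariates with their declared
#' type.
#'
#' @param cohort_id Cohort identifier stored in the resulting dataset.
#' @param sample_col Name of the sample-identifier column in the clinical file.
#' @param os_time_col,os_event_col OS time/event column names.
#' @param ep2_kind `"none"`, `"DFS"` or `"RFS"`.
#' @param ep2_time_col,ep2_event_col Second-endpoint columns (required when
#'   `ep2_kind != "none"`).
#' @param covariates Named character vector mapping covariate column name to
#'   `"continuous"` or `"categorical"`.
#' @param available_covariates Covariates usable for multivariate adjustment in
#'   this cohort; defaults to all declared covariates.
#' @param time_unit `"months"` (stored as-is) or `"days"` (divided by 30.44 at
#'   load, logged).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(cohort_id = "cohort",
                        sample_col = "sample_id",
                        os_time_col = "os_time", os_event_col = "os_event",
                        ep2_kind = c("none", "DFS", "RFS"),
                        ep2_time_col = NULL, ep2_event_col = NULL,
                        covariates = character(),
                        available_covariates = names(covariates),
                        time_unit = c("months", "days")) {
  ep2_kind <- match.arg(ep2_kind)
  time_unit <- match.arg(time_unit)
  if (ep2_kind != "none" && (is.null(ep2_time_col) || is.null(ep2_event_col)))
    stop("ep2_kind = ", ep2_kind, " requires ep2_time_col and ep2_event_col")
  bad <- setdiff(covariates, c("continuous", "categorical"))
  if (length(bad)) stop("covariate types must be 'continuous' or 'categorical'")
  structure(list(cohort_id = cohort_id, sample_col = sample_col,
                 os_time_col = os_time_col, os_event_col = os_event_col,
                 ep2_kind = ep2_kind, ep2_time_col = ep2_time_col,
                 ep2_event_col = ep2_event_col, covariates = covariates,
                 available_covariates = available_covariates,
                 time_unit = time_unit),
            class = "cohort_spec")
}

#' Read one cohort from expression + clinical files
#'
#' Expression: tab-separated, first column gene identifier, header row of
#' sample identifiers (genes x samples, the GEO series-matrix convention).
#' Clinical: tab-separated, one row per sample, columns mapped by `spec`.
#' The returned dataset is restricted to samples present in both files; drops
#' are logged via `message()`. Missing covariate values are preserved as `NA`
#' (samples are excluded from multivariate fits only, complete-case per model).
#'
#' @param expression_path,clinical_path File paths.
#' @param spec A [cohort_spec()].
#' @param verbose Emit messages about dropped samples and unit conversion.
#' @return A [cohort_dataset()].
#' @export
read_cohort <- function(expression_path, clinical_path, spec = cohort_spec(),
                        verbose = TRUE) {
  raw <- utils::read.delim(expression_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression file needs a gene column plus >=1 sample")
  genes <- as.character(raw[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicated gene identifiers in ", expression_path, ": ",
         paste(dup, collapse = ", "))
  mat <- raw[, -1, drop = FALSE]
  for (j in seq_along(mat)) {
    v <- mat[[j]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad))
        stop("non-numeric expression value at row ", bad[1] + 1L,
             " (gene ", genes[bad[1]], "), column ", colnames(mat)[j])
      mat[[j]] <- conv
    }
  }
  expr <- as.matrix(mat)
  rownames(expr) <- genes

  clin <- utils::read.delim(clinical_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  need <- c(spec$sample_col, spec$os_time_col, spec$os_event_col,
            spec$ep2_time_col, spec$ep2_event_col, names(spec$covariates))
  miss <- setdiff(need, names(clin))
  if (length(miss))
    stop("clinical file lacks mapped columns: ", paste(miss, collapse = ", "))
  sid <- as.character(clin[[spec$sample_col]])
  dup <- unique(sid[duplicated(sid)])
  if (length(dup))
    stop("duplicated sample identifiers in ", clinical_path, ": ",
         paste(dup, collapse = ", "))

  common <- intersect(colnames(expr), sid)
  if (!length(common)) stop("zero overlapping samples between files")
  drop_e <- setdiff(colnames(expr), common)
  drop_c <- setdiff(sid, common)
  if (verbose && (length(drop_e) || length(drop_c)))
    message(spec$cohort_id, ": dropped ", length(drop_e),
            " expression-only and ", length(drop_c),
            " clinical-only samples; ", length(common), " retained")
  expr <- expr[, common, drop = FALSE]
  clin <- clin[match(common, sid), , drop = FALSE]

  tconv <- if (spec$time_unit == "days") 1 / 30.44 else 1
  if (verbose && spec$time_unit == "days")
    message(spec$cohort_id, ": converting times from days to months (/30.44)")

  cov_tab <- data.frame(row.names = common)
  for (cv in names(spec$covariates)) {
    v <- clin[[cv]]
    cov_tab[[cv]] <- if (spec$covariates[[cv]] == "continuous")
      as.numeric(v) else factor(v)
  }

  ep2_time <- ep2_event <- NULL
  if (spec$ep2_kind != "none") {
    ep2_time <- as.numeric(clin[[spec$ep2_time_col]]) * tconv
    ep2_event <- as.integer(clin[[spec$ep2_event_col]])
  }

  cohort_dataset(
    cohort_id = spec$cohort_id, expression = expr,
    os_time = as.numeric(clin[[spec$os_time_col]]) * tconv,
    os_event = as.integer(clin[[spec$os_event_col]]),
    ep2_kind = spec$ep2_kind, ep2_time = ep2_time, ep2_event = ep2_event,
    covariates = cov_tab, available_covariates = spec$available_covariates
  )
}

#' Write a cohort back to expression + clinical TSV files
#'
#' Inverse of [read_cohort()] under the default column mapping; used by the
#' data generator to materialize synthetic cohorts.
#'
#' @param cohort A `cohort_dataset`.
#' @param expression_path,clinical_path Output file paths.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, expression_path, clinical_path) {
  edf <- data.frame(gene_id = rownames(cohort$expression),
                    cohort$expression, check.names = FALSE)
  write_table(edf, expression_path)
  clin <- data.frame(sample_id = colnames(cohort$expression),
                     os_time = cohort$os_time, os_event = cohort$os_event,
                     check.names = FALSE)
  if (cohort$ep2_kind != "none") {
    clin$ep2_time <- cohort$ep2_time
    clin$ep2_event <- cohort$ep2_event
  }
  if (ncol(cohort$covariates))
    clin <- cbind(clin, cohort$covariates)
  write_table(clin, clinical_path)
  invisible(cohort)
}

#' Write a result table as TSV
#'
#' Deterministic column order (as given), tab-separated, no quoting or row
#' names; round-trips through `read.delim` up to numeric formatting at 15
#' significant digits. An empty data frame yields a header-only file.
#'
#' @param records Data frame (possibly zero rows).
#' @param path Output path; the directory must exist.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  records <- as.data.frame(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV result table written by [write_table()]
#' @param path File path.
#' @return Data frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
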