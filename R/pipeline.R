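#' Run the full discovery pipeline: screen, pool, search
#'
#' Convenience driver chaining [screen_all()], [cross_endpoint_filter()],
#' [pool_screen()], [search_scores()], [select_scores()] and
#' [pick_parsimonious()] under one [run_config()].
#'
#' @param cohorts List of [cohort_dataset()].
#' @param config A [run_config()].
#' @param genes Optional gene subset to screen.
#' @param max_genes Cap forwarded to the combination enumeration.
#' @param verbose Progress messages.
#' @return List of class `discovery_result`: `screen` (with
#'   `final_genes`), `pooled`, `evaluations`, `passing`, `winner`
#'   (a `parsimonious_choice`), `config`.
#' @export
run_discovery_pipeline <- function(cohorts, config = run_config(),
                                   genes = NULL, max_genes = 20,
                                   verbose = TRUE) {
  criteria <- config$criteria
  screen <- screen_all(cohorts, criteria, genes = genes, verbose = verbose)
  screen <- cross_endpoint_filter(screen, cohorts)
  if (verbose)
    message(length(screen$final_genes), " gene(s) pass OS + second endpoint")
  if (!length(screen$final_genes)) {
    return(structure(list(screen = screen, pooled = NULL,
                          evaluations = list(), passing = list(),
                          winner = pick_parsimonious(list()),
                          config = config),
                     class = "discovery_result"))
  }
  pooled <- pool_screen(screen, rule = config$het_rule)
  evaluations <- search_scores(pooled, cohorts,
                               thresholds = config$thresholds,
                               criteria = criteria,
                               scale = config$expression_scale,
                               max_genes = max_genes, verbose = verbose)
  passing <- select_scores(evaluations)
  if (verbose)
    message(length(passing), " of ", length(evaluations),
            " candidate scores pass all thresholds")
  winner <- pick_parsimonious(passing)
  structure(list(screen = screen, pooled = pooled,
                 evaluations = evaluations, passing = passing,
                 winner = winner, config = config),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("<discovery_result>\n")
  print(x$screen)
  if (!is.null(x$pooled))
    cat(nrow(x$pooled), "pooled coefficients;",
        length(x$passing), "of", length(x$evaluations), "scores pass\n")
  print(x$winner)
  invisible(x)
}
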