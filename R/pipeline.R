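#' Run the full study analysis
#'
#' Orchestrates the pipeline stages on a loaded (or simulated) study: CPV
#' matrix and pooled scores, outcome scoring, CPV-outcome association,
#' coefficient-of-variation comparator, covariate correlations, and — when
#' expression data are present — the gene correlation screen and pathway
#' enrichment. The combinatorial session-timing study is optional (it
#' evaluates 968 patterns by default).
#'
#' @param study A list with elements `sessions`, `shedding`, `symptoms`, and
#'   optionally `covariates`, `expression`, `pathways` — as produced by
#'   [simulate_study()] or assembled from the readers.
#' @param alpha FDR level for the gene screen and enrichment, default 0.05.
#' @param variable_subset Optional restriction of the NCPT variables used for
#'   the CPV.
#' @param include_screening Include the screening session in the CPV?
#'   Default `FALSE`.
#' @param screen_variables NCPT variables to screen against expression;
#'   default the study's planted screen variable if known, else
#'   `"digSym-correct"`.
#' @param run_patterns Also run the combinatorial session-timing study?
#'   Default `FALSE`.
#' @param lopo_rule,threshold Pattern-screen settings, see
#'   [evaluate_pattern()].
#' @return A list of class `cpv_analysis`: `cpv` (matrix object), `scores`,
#'   `outcomes`, `associations`, `comparator` (CoV association), `covariates`
#'   (correlation table or `NULL`), `gene_screens` (named list of screen
#'   tibbles), `enrichment` (named list), `patterns`, `report`, and
#'   `manifest` (seed-independent input fingerprint, stage timings,
#'   warnings).
#' @export
run_study_analysis <- function(study, alpha = 0.05, variable_subset = NULL,
                               include_screening = FALSE,
                               screen_variables = NULL,
                               run_patterns = FALSE, lopo_rule = "min",
                               threshold = 0.69) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  warnings_log <- character(0)
  wcollect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  tick <- function(stage) {
    now <- proc.time()[["elapsed"]]
    timings <<- c(timings, stats::setNames(now - t0, stage))
    t0 <<- now
  }

  outcomes <- wcollect(outcome_table(study$shedding, study$symptoms))
  tick("outcomes")
  cpv <- wcollect(cpv_matrix(study$sessions, outcomes = outcomes,
                             variable_subset = variable_subset,
                             include_screening = include_screening))
  scores <- wcollect(cpv_score(study$sessions,
                               variable_subset = variable_subset,
                               include_screening = include_screening))
  tick("cpv")
  associations <- associate_outcomes(scores, outcomes, score_col = "cpv")
  comparator_scores <- wcollect(cov_score(study$sessions,
                                          variable_subset = variable_subset,
                                          include_screening = include_screening))
  comparator <- associate_outcomes(comparator_scores, outcomes,
                                   score_col = "cov")
  tick("association")

  covariates <- NULL
  if (!is.null(study$covariates)) {
    covariates <- wcollect(covariate_correlations(scores, study$covariates))
  }

  gene_screens <- NULL
  enrichment <- NULL
  if (!is.null(study$expression)) {
    if (is.null(screen_variables)) {
      screen_variables <- study$truth$screen_variable %||% "digSym-correct"
    }
    gene_screens <- lapply(stats::setNames(nm = screen_variables),
                           function(v) {
      wcollect(gene_screen(study$sessions, study$expression, v,
                           alpha = alpha))
    })
    if (!is.null(study$pathways)) {
      enrichment <- lapply(gene_screens, function(gs) {
        sig <- gs$gene[gs$significant]
        if (length(sig) == 0) return(NULL)
        pathway_enrichment(sig, study$pathways, background = gs$gene)
      })
    }
    tick("genes")
  }

  patterns <- NULL
  report <- NULL
  if (run_patterns) {
    patterns <- evaluate_patterns(enumerate_patterns(), study$sessions,
                                  outcomes, threshold = threshold,
                                  lopo_rule = lopo_rule)
    report <- pattern_report(patterns)
    tick("patterns")
  }

  manifest <- list(
    inputs = list(
      n_participants = length(unique(study$sessions$participant_id)),
      n_sessions = nrow(dplyr::distinct(study$sessions,
                                        .data$participant_id,
                                        .data$session_index)),
      n_genes = if (is.null(study$expression)) 0L else nrow(study$expression)
    ),
    options = list(alpha = alpha, include_screening = include_screening,
                   variable_subset = variable_subset,
                   lopo_rule = lopo_rule, threshold = threshold),
    hash = rlang::hash(list(study[c("sessions", "shedding", "symptoms")],
                            alpha, include_screening, variable_subset)),
    timings = timings,
    warnings = warnings_log
  )

  structure(list(cpv = cpv, scores = scores, outcomes = outcomes,
                 associations = associations, comparator = comparator,
                 covariates = covariates, gene_screens = gene_screens,
                 enrichment = enrichment, patterns = patterns,
                 report = report, manifest = manifest),
            class = "cpv_analysis")
}

#' @export
print.cpv_analysis <- function(x, ...) {
  cat("CPV study analysis\n")
  cat("  participants:", x$manifest$inputs$n_participants, "\n")
  shed <- x$associations[x$associations$outcome == "total_shedding", ]
  cat(sprintf("  CPV vs shedding: rho = %.3f (p = %.2g), R2 = %.3f, AUC = %.3f\n",
              shed$rho, shed$p_value, shed$r2, shed$auc))
  sym <- x$associations[x$associations$outcome == "total_symptom", ]
  cat(sprintf("  CPV vs symptoms: rho = %.3f (p = %.2g)\n",
              sym$rho, sym$p_value))
  if (!is.null(x$gene_screens)) {
    for (v in names(x$gene_screens)) {
      cat("  gene screen [", v, "]: ",
          sum(x$gene_screens[[v]]$significant), " significant at FDR\n",
          sep = "")
    }
  }
  invisible(x)
}

#' Write the analysis outputs as CSV files
#'
#' @param analysis A `cpv_analysis` list ([run_study_analysis()]).
#' @param dir Output directory, created if absent.
#' @return Character vector of files written, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  files <- c(files, write_cpv_matrix(analysis$cpv,
                                     file.path(dir, "cpv_matrix.csv")))
  files <- c(files, write_outcomes(analysis$outcomes,
                                   file.path(dir, "outcomes.csv")))
  readr::write_csv(analysis$associations, file.path(dir, "associations.csv"))
  files <- c(files, file.path(dir, "associations.csv"))
  if (!is.null(analysis$covariates)) {
    readr::write_csv(analysis$covariates,
                     file.path(dir, "covariate_correlations.csv"))
    files <- c(files, file.path(dir, "covariate_correlations.csv"))
  }
  if (!is.null(analysis$gene_screens)) {
    for (v in names(analysis$gene_screens)) {
      f <- file.path(dir, paste0("gene_screen_", gsub("[^A-Za-z0-9]", "_", v),
                                 ".csv"))
      readr::write_csv(analysis$gene_screens[[v]], f)
      files <- c(files, f)
      enr <- analysis$enrichment[[v]]
      if (!is.null(enr)) {
        f <- file.path(dir, paste0("enrichment_",
                                   gsub("[^A-Za-z0-9]", "_", v), ".csv"))
        readr::write_csv(enr, f)
        files <- c(files, f)
      }
    }
  }
  if (!is.null(analysis$patterns)) {
    readr::write_csv(analysis$patterns, file.path(dir, "patterns.csv"))
    readr::write_csv(analysis$report$frequencies,
                     file.path(dir, "frequencies.csv"))
    files <- c(files, file.path(dir, c("patterns.csv", "frequencies.csv")))
  }
  invisible(files)
}
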