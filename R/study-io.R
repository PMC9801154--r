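#' Read cognitive-test sessions
#'
#' Reads a comma-separated session table with one header row and columns
#' `participant_id`, `session_index`, `time_h`, plus one column per NCPT
#' variable. Session index 0 denotes the screening session (its `time_h` may
#' be negative, hours being counted from the start of the baseline period).
#' Cells that fail numeric parsing become missing values; their count is
#' reported via a warning and attached as the `n_parse_failures` attribute.
#'
#' @param path Path to a sessions CSV file.
#' @param catalog NCPT variable catalog, default [ncpt_catalog()]. Variable
#'   columns not present in the catalog raise an error naming them.
#' @return A tibble in long format with columns `participant_id`,
#'   `session_index`, `time_h`, `variable`, `value`, sorted by
#'   (participant, session index). One row per session and variable.
#' @export
read_sessions <- function(path, catalog = ncpt_catalog()) {
  wide <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      session_index = readr::col_integer(),
      time_h = readr::col_double(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  required <- c("participant_id", "session_index", "time_h")
  if (!all(required %in% names(wide))) {
    stop("sessions file must have columns: ", paste(required, collapse = ", "))
  }
  var_cols <- setdiff(names(wide), required)
  unknown <- setdiff(var_cols, catalog$variable)
  if (length(unknown) > 0) {
    stop("unknown NCPT variable column(s): ", paste(unknown, collapse = ", "))
  }
  n_bad <- nrow(readr::problems(wide))
  if (n_bad > 0) {
    warning(n_bad, " cell(s) failed numeric parsing and were set to missing")
  }
  dup <- duplicated(wide[, c("participant_id", "session_index")])
  if (any(dup)) {
    keys <- unique(paste(wide$participant_id[dup], wide$session_index[dup],
                         sep = ":"))
    stop("duplicated (participant, session_index): ",
         paste(keys, collapse = ", "))
  }
  long <- tidyr::pivot_longer(wide, cols = dplyr::all_of(var_cols),
                              names_to = "variable", values_to = "value")
  long <- dplyr::arrange(long, .data$participant_id, .data$session_index)
  n_missing <- sum(is.na(long$value))
  if (n_missing > 0) {
    warning(n_missing, " missing NCPT value(s) in ", basename(path))
  }
  bad_time <- long |>
    dplyr::distinct(.data$participant_id, .data$session_index, .data$time_h) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(ok = all(diff(.data$time_h) > 0), .groups = "drop")
  if (any(!bad_time$ok)) {
    stop("time_h not strictly increasing with session_index for: ",
         paste(bad_time$participant_id[!bad_time$ok], collapse = ", "))
  }
  attr(long, "n_parse_failures") <- n_bad
  attr(long, "n_missing") <- n_missing
  long
}

#' Write cognitive-test sessions
#'
#' Inverse of [read_sessions()]: pivots the long session table back to the
#' wide CSV dialect (one column per NCPT variable).
#'
#' @param sessions Long session tibble as returned by [read_sessions()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  wide <- tidyr::pivot_wider(sessions, names_from = "variable",
                             values_from = "value")
  wide <- dplyr::arrange(wide, .data$participant_id, .data$session_index)
  readr::write_csv(wide, path)
  invisible(path)
}

#' Read daily viral-shedding titers
#'
#' Columns: `participant_id`, `study_day`, `titer` (log10 TCID50/ml, must be
#' nonnegative). One record per participant-day; post-inoculation days only.
#'
#' @param path Path to a shedding CSV file.
#' @return Tibble with those three columns, sorted.
#' @export
read_shedding <- function(path) {
  x <- readr::read_csv(path, col_types = "cid", progress = FALSE)
  stopifnot(all(c("participant_id", "study_day", "titer") %in% names(x)))
  dup <- duplicated(x[, c("participant_id", "study_day")])
  if (any(dup)) stop("duplicated (participant, study_day) in shedding table")
  if (any(x$titer < 0, na.rm = TRUE)) stop("negative shedding titer")
  dplyr::arrange(x, .data$participant_id, .data$study_day)
}

#' @rdname read_shedding
#' @param shedding Shedding tibble.
#' @export
write_shedding <- function(shedding, path) {
  readr::write_csv(shedding, path)
  invisible(path)
}

#' Read the symptom diary
#'
#' Columns: `participant_id`, `study_day`, `entry_index`, plus the 8 symptom
#' columns of [symptom_names()], each an integer rank in 0..3
#' ("no symptoms" to "bothersome and cannot do daily activities").
#'
#' @param path Path to a symptoms CSV file.
#' @return Tibble, one row per diary entry.
#' @export
read_symptoms <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      .default = readr::col_integer()
    ),
    progress = FALSE
  )
  need <- c("participant_id", "study_day", "entry_index", symptom_names())
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("symptoms file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ranks <- as.matrix(x[, symptom_names()])
  bad <- which(ranks < 0L | ranks > 3L, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, "row"]
    stop("symptom rank outside 0..3 for participant ", x$participant_id[i],
         " on study day ", x$study_day[i])
  }
  dplyr::arrange(x, .data$participant_id, .data$study_day, .data$entry_index)
}

#' @rdname read_symptoms
#' @param symptoms Symptom diary tibble.
#' @export
write_symptoms <- function(symptoms, path) {
  readr::write_csv(symptoms, path)
  invisible(path)
}

#' Read participant covariates
#'
#' Columns: `participant_id` plus any subset of [covariate_registry()].
#' Columns outside the registry raise an error naming them.
#'
#' @param path Path to a covariates CSV file.
#' @return Tibble, one row per participant.
#' @export
read_covariates <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(participant_id = readr::col_character(),
                            .default = readr::col_double()),
    progress = FALSE
  )
  stopifnot("participant_id" %in% names(x))
  unknown <- setdiff(names(x), c("participant_id", covariate_registry()))
  if (length(unknown) > 0) {
    stop("unregistered covariate column(s): ", paste(unknown, collapse = ", "))
  }
  dplyr::arrange(x, .data$participant_id)
}

#' @rdname read_covariates
#' @param covariates Covariate tibble.
#' @export
write_covariates <- function(covariates, path) {
  readr::write_csv(covariates, path)
  invisible(path)
}

#' Read a gene-expression matrix
#'
#' CSV with a `gene` column followed by one column per sample, sample names
#' encoded as `participant:session_index` (e.g. `P03:4`). Values are
#' TPM-normalized abundances, used as provided.
#'
#' @param path Path to an expression CSV file.
#' @return Numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(gene = readr::col_character(),
                            .default = readr::col_double()),
    progress = FALSE
  )
  stopifnot(names(x)[1] == "gene")
  m <- as.matrix(x[, -1])
  rownames(m) <- x$gene
  if (anyDuplicated(colnames(m))) stop("duplicated sample names")
  m
}

#' @rdname read_expression
#' @param expression Expression matrix (genes x samples).
#' @export
write_expression <- function(expression, path) {
  df <- tibble::as_tibble(expression, rownames = "gene")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read pathway gene sets (GMT)
#'
#' Standard tab-separated GMT: set name, description, member gene symbols.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_pathways <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_pathways
#' @param pathways Named list of character vectors.
#' @export
write_pathways <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, "na", pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a loaded study
#'
#' Report-only structural check of a loaded study: per-participant session
#' counts, participants with fewer than 3 usable baseline (non-screening)
#' sessions — for whom the CPV is incomputable — and participants missing the
#' screening session. A session is usable if at least one NCPT value is
#' non-missing.
#'
#' @param sessions Long session tibble ([read_sessions()]).
#' @param shedding Shedding tibble ([read_shedding()]), optional.
#' @param symptoms Symptom tibble ([read_symptoms()]), optional.
#' @return A list of class `cpv_validation` with elements `session_counts`
#'   (tibble: participant, total and baseline session counts),
#'   `incomputable` and `missing_screening` (character vectors), and
#'   `missing_outcomes` (participants with sessions but no shedding or
#'   symptom records, when those tables are given).
#' @export
validate_study <- function(sessions, shedding = NULL, symptoms = NULL) {
  usable <- sessions |>
    dplyr::group_by(.data$participant_id, .data$session_index) |>
    dplyr::summarise(usable = any(!is.na(.data$value)), .groups = "drop")
  counts <- usable |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_sessions = sum(.data$usable),
      n_baseline = sum(.data$usable & .data$session_index > 0L),
      has_screening = any(.data$usable & .data$session_index == 0L),
      .groups = "drop"
    )
  missing_outcomes <- character(0)
  for (tab in list(shedding, symptoms)) {
    if (!is.null(tab)) {
      missing_outcomes <- union(
        missing_outcomes,
        setdiff(counts$participant_id, unique(tab$participant_id))
      )
    }
  }
  structure(
    list(
      session_counts = counts[, c("participant_id", "n_sessions", "n_baseline")],
      incomputable = counts$participant_id[counts$n_baseline < 3L],
      missing_screening = counts$participant_id[!counts$has_screening],
      missing_outcomes = sort(missing_outcomes)
    ),
    class = "cpv_validation"
  )
}

#' @export
print.cpv_validation <- function(x, ...) {
  cat("Study validation report\n")
  cat("  participants:", nrow(x$session_counts), "\n")
  cat("  baseline sessions per participant:",
      paste(range(x$session_counts$n_baseline), collapse = "-"), "\n")
  cat("  CPV-incomputable (<3 baseline sessions):",
      if (length(x$incomputable)) paste(x$incomputable, collapse = ", ")
      else "none", "\n")
  cat("  missing screening session:",
      if (length(x$missing_screening))
        paste(x$missing_screening, collapse = ", ") else "none", "\n")
  if (length(x$missing_outcomes)) {
    cat("  missing outcome records:",
        paste(x$missing_outcomes, collapse = ", "), "\n")
  }
  invisible(x)
}
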