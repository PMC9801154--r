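#' Univariate CPV scores for every participant and NCPT variable
#'
#' Applies [cpv_univariate()] to each (participant, variable) baseline series,
#' sessions ordered by time. The screening session (index 0) is excluded by
#' default, matching the score's operational definition.
#'
#' @param sessions Long session tibble ([read_sessions()]).
#' @param variable_subset Optional character vector restricting the NCPT
#'   variables used; default all variables present.
#' @param include_screening Include the screening session (index 0)?
#'   Default `FALSE`.
#' @param shape Beta shape convention passed to [cpv_univariate()].
#' @return Tibble with columns `participant_id`, `variable`, `T`, `cpv`,
#'   `n_used`, `status`, `capped`.
#' @export
cpv_table <- function(sessions, variable_subset = NULL,
                      include_screening = FALSE, shape = "halved") {
  x <- sessions
  if (!include_screening) {
    x <- dplyr::filter(x, .data$session_index > 0L)
  }
  if (!is.null(variable_subset)) {
    missing_vars <- setdiff(variable_subset, unique(x$variable))
    if (length(missing_vars) > 0) {
      stop("variable(s) not present in sessions: ",
           paste(missing_vars, collapse = ", "))
    }
    x <- dplyr::filter(x, .data$variable %in% variable_subset)
  }
  x |>
    dplyr::arrange(.data$participant_id, .data$variable, .data$time_h) |>
    dplyr::group_by(.data$participant_id, .data$variable) |>
    dplyr::summarise(
      res = list(cpv_univariate(.data$value, shape = shape)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      T = purrr::map_dbl(.data$res, "T"),
      cpv = purrr::map_dbl(.data$res, "cpv"),
      n_used = purrr::map_int(.data$res, "n_used"),
      status = purrr::map_chr(.data$res, "status"),
      capped = purrr::map_lgl(.data$res, "capped")
    ) |>
    dplyr::select(-"res")
}

#' Max-pooled participant CPV score
#'
#' The CPV score of a participant is the maximum of their univariate CPV
#' scores over the chosen NCPT variables. Participants with no computable
#' variable (fewer than 3 retained baseline sessions everywhere) are dropped
#' with a warning.
#'
#' @inheritParams cpv_table
#' @return Tibble with columns `participant_id`, `cpv` (the pooled score) and
#'   `argmax_variable` (the variable attaining the maximum, first in catalog
#'   order on ties).
#' @export
cpv_score <- function(sessions, variable_subset = NULL,
                      include_screening = FALSE, shape = "halved") {
  tab <- cpv_table(sessions, variable_subset = variable_subset,
                   include_screening = include_screening, shape = shape)
  ok <- dplyr::filter(tab, !is.na(.data$cpv))
  dropped <- setdiff(unique(tab$participant_id), unique(ok$participant_id))
  if (length(dropped) > 0) {
    warning("participant(s) with no computable CPV dropped: ",
            paste(dropped, collapse = ", "))
  }
  ok |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      argmax_variable = .data$variable[which.max(.data$cpv)],
      cpv = max(.data$cpv),
      .groups = "drop"
    ) |>
    dplyr::select("participant_id", "cpv", "argmax_variable")
}

#' Participants-by-variables CPV matrix
#'
#' Builds the full matrix of univariate CPV scores plus the max-pooled
#' per-participant score. When an outcome table is supplied, participants are
#' ordered by decreasing total shedding and variables by decreasing maximum
#' univariate CPV — the heatmap ordering; scores themselves are independent of
#' input row order.
#'
#' @inheritParams cpv_table
#' @param outcomes Optional outcome tibble ([outcome_table()]) used only to
#'   order participants.
#' @return An object of class `cpv_matrix`: a list with `scores` (numeric
#'   matrix, participants x variables), `max_pooled` (named vector),
#'   `participants`, `variables` and `dropped` (participants with no
#'   computable score).
#' @export
cpv_matrix <- function(sessions, outcomes = NULL, variable_subset = NULL,
                       include_screening = FALSE, shape = "halved") {
  tab <- cpv_table(sessions, variable_subset = variable_subset,
                   include_screening = include_screening, shape = shape)
  wide <- tidyr::pivot_wider(tab[, c("participant_id", "variable", "cpv")],
                             names_from = "variable", values_from = "cpv")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$participant_id
  pooled <- apply(m, 1, function(r) if (all(is.na(r))) NA_real_
                  else max(r, na.rm = TRUE))
  dropped <- rownames(m)[is.na(pooled)]
  if (length(dropped) > 0) {
    warning("participant(s) with no computable CPV: ",
            paste(dropped, collapse = ", "))
    m <- m[!rownames(m) %in% dropped, , drop = FALSE]
    pooled <- pooled[!names(pooled) %in% dropped]
  }
  p_order <- rownames(m)
  if (!is.null(outcomes)) {
    ord <- outcomes[order(-outcomes$total_shedding), "participant_id",
                    drop = TRUE]
    p_order <- c(intersect(ord, p_order), setdiff(p_order, ord))
  }
  v_order <- colnames(m)[order(-apply(m, 2, max, na.rm = TRUE))]
  m <- m[p_order, v_order, drop = FALSE]
  structure(
    list(scores = m, max_pooled = pooled[p_order],
         participants = p_order, variables = v_order, dropped = dropped),
    class = "cpv_matrix"
  )
}

#' @export
print.cpv_matrix <- function(x, ...) {
  cat("CPV matrix:", length(x$participants), "participants x",
      length(x$variables), "variables\n")
  cat("max-pooled scores:\n")
  print(round(x$max_pooled, 3))
  invisible(x)
}

#' Tidy a CPV matrix
#'
#' @param x A `cpv_matrix` object.
#' @param ... Unused.
#' @return Tibble with columns `participant_id`, `variable`, `cpv`, `pooled`
#'   (logical; pooled rows carry variable `"(max)"`). Row order follows the
#'   matrix (heatmap) ordering.
#' @export
as_tibble.cpv_matrix <- function(x, ...) {
  per_var <- tibble::tibble(
    participant_id = rep(x$participants, times = length(x$variables)),
    variable = rep(x$variables, each = length(x$participants)),
    cpv = as.vector(x$scores),
    pooled = FALSE
  )
  pooled <- tibble::tibble(
    participant_id = x$participants,
    variable = "(max)",
    cpv = unname(x$max_pooled),
    pooled = TRUE
  )
  dplyr::bind_rows(per_var, pooled)
}

#' @rdname as_tibble.cpv_matrix
#' @param path Output CSV path.
#' @export
write_cpv_matrix <- function(x, path) {
  readr::write_csv(as_tibble.cpv_matrix(x), path)
  invisible(path)
}
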