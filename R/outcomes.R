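#' Total post-exposure viral shedding per participant
#'
#' The total shedding of a participant is the arithmetic sum of all daily
#' log10 TCID50/ml titers collected over the post-inoculation period
#' (study days 5 through 8).
#'
#' @param shedding Shedding tibble ([read_shedding()]).
#' @param days Post-inoculation days to sum over, default `5:8`. Records on
#'   other days are ignored.
#' @return Tibble with columns `participant_id`, `total_shedding`.
#' @export
total_shedding <- function(shedding, days = 5:8) {
  x <- dplyr::filter(shedding, .data$study_day %in% days)
  if (nrow(x) == 0) stop("no post-inoculation shedding records in days ",
                         paste(range(days), collapse = "-"))
  dplyr::summarise(dplyr::group_by(x, .data$participant_id),
                   total_shedding = sum(.data$titer), .groups = "drop")
}

#' Modified Jackson symptom score of one diary entry
#'
#' Sum of the 8 upper-respiratory symptom ranks (each 0-3), range 0-24.
#'
#' @param ranks Numeric vector of 8 integer ranks in 0..3, ordered as
#'   [symptom_names()].
#' @return Integer in 0..24.
#' @export
#' @examples
#' jackson_score(c(1, 0, 2, 0, 1, 0, 0, 3))  # 7
jackson_score <- function(ranks) {
  if (length(ranks) != 8L) stop("a diary entry has exactly 8 symptom ranks")
  if (any(is.na(ranks)) || any(ranks < 0 | ranks > 3) ||
      any(ranks != round(ranks))) {
    stop("symptom ranks must be integers in 0..3")
  }
  as.integer(sum(ranks))
}

#' Total symptom score per participant
#'
#' Diary entries (up to three per day) are first summed into modified Jackson
#' scores, averaged within each study day, and the daily averages are summed
#' over the post-inoculation period (5 days). A day with no entries
#' contributes 0, with a warning, so totals stay comparable across
#' participants.
#'
#' @param symptoms Symptom diary tibble ([read_symptoms()]).
#' @param days Post-inoculation days, default `4:8` (inoculation day through
#'   study end).
#' @return Tibble with columns `participant_id`, `total_symptom`.
#' @export
total_symptom <- function(symptoms, days = 4:8) {
  x <- dplyr::filter(symptoms, .data$study_day %in% days)
  x$jackson <- apply(as.matrix(x[, symptom_names()]), 1, jackson_score)
  daily <- x |>
    dplyr::group_by(.data$participant_id, .data$study_day) |>
    dplyr::summarise(day_mean = mean(.data$jackson), .groups = "drop")
  n_missing <- daily |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(miss = length(days) - dplyr::n(), .groups = "drop")
  if (any(n_missing$miss > 0)) {
    warning("participant-day(s) with no diary entries contribute 0: ",
            sum(n_missing$miss), " day(s)")
  }
  daily |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(total_symptom = sum(.data$day_mean), .groups = "drop")
}

#' High/low shedder labels by median split
#'
#' Labels a participant `high` if their total shedding strictly exceeds the
#' population median (midpoint of the two central values for even cohorts),
#' else `low`. A total exactly equal to the median is labeled `low` with a
#' warning, so the rule is deterministic.
#'
#' @param totals Numeric vector of per-participant total shedding (>= 2
#'   values).
#' @return Character vector of `"low"`/`"high"`, same length and names.
#' @export
shedder_labels <- function(totals) {
  if (length(totals) < 2L) stop("need at least 2 participants to split")
  med <- stats::median(totals)
  if (any(totals == med)) {
    warning(sum(totals == med),
            " total(s) exactly at the median labeled 'low'")
  }
  out <- ifelse(totals > med, "high", "low")
  names(out) <- names(totals)
  out
}

#' Per-participant outcome table
#'
#' Combines total shedding, total symptom score, and the high/low shedder
#' label into one table.
#'
#' @param shedding Shedding tibble ([read_shedding()]).
#' @param symptoms Symptom diary tibble ([read_symptoms()]).
#' @param shedding_days,symptom_days Post-inoculation day windows; see
#'   [total_shedding()] and [total_symptom()].
#' @return Tibble with columns `participant_id`, `total_shedding`,
#'   `total_symptom`, `label`.
#' @export
outcome_table <- function(shedding, symptoms, shedding_days = 5:8,
                          symptom_days = 4:8) {
  shed <- total_shedding(shedding, days = shedding_days)
  sym <- total_symptom(symptoms, days = symptom_days)
  out <- dplyr::full_join(shed, sym, by = "participant_id")
  out$label <- shedder_labels(out$total_shedding)
  dplyr::arrange(out, .data$participant_id)
}

#' @rdname outcome_table
#' @param outcomes Outcome tibble.
#' @param path Output CSV path.
#' @export
write_outcomes <- function(outcomes, path) {
  readr::write_csv(outcomes, path)
  invisible(path)
}
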