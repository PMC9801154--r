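#' Leave-one-session-out univariate CPV
#'
#' Sensitivity of a univariate CPV score to single-session perturbation: the
#' score is recomputed once per session with that session left out of the
#' ordered series (screening excluded upstream). Requires at least 4 sessions
#' so every leave-one-out series retains 3.
#'
#' @param x Numeric vector of baseline session values in time order.
#' @param shape Beta shape convention, see [cpv_univariate()].
#' @return A list with `full` (the full-series CPV) and `loo` (numeric vector
#'   of leave-one-out CPV values, one per session in order).
#' @export
loo_session_cpv <- function(x, shape = "halved") {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4L) stop("leave-one-session-out needs at least 4 sessions")
  loo <- vapply(seq_len(n), function(i) cpv_univariate(x[-i], shape = shape)$cpv,
                numeric(1))
  list(full = cpv_univariate(x, shape = shape)$cpv, loo = loo)
}

#' Leave-one-session-out CPV for every participant and variable
#'
#' Tidy wrapper over [loo_session_cpv()] producing the data behind the
#' session-perturbation boxplots: one row per (participant, variable,
#' left-out session). Participants with fewer than 4 baseline sessions for a
#' variable are skipped.
#'
#' @inheritParams cpv_table
#' @return Tibble with columns `participant_id`, `variable`,
#'   `left_out_index` (the session index removed), `cpv`, `full_cpv`.
#' @export
loo_session_table <- function(sessions, variable_subset = NULL,
                              include_screening = FALSE, shape = "halved") {
  x <- sessions
  if (!include_screening) x <- dplyr::filter(x, .data$session_index > 0L)
  if (!is.null(variable_subset)) {
    x <- dplyr::filter(x, .data$variable %in% variable_subset)
  }
  x |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::arrange(.data$participant_id, .data$variable, .data$time_h) |>
    dplyr::group_by(.data$participant_id, .data$variable) |>
    dplyr::filter(dplyr::n() >= 4L) |>
    dplyr::reframe({
      res <- loo_session_cpv(.data$value, shape = shape)
      idx <- .data$session_index
      tibble::tibble(left_out_index = idx, cpv = res$loo,
                     full_cpv = res$full)
    })
}

#' Enumerate session-timing patterns
#'
#' All subsets of the 10 baseline session slots (slot 1 = screening, slot 10
#' = last session before exposure) with between `t_min` and `t_max` members.
#' The default range 3..10 yields 968 patterns.
#'
#' @param t_min,t_max Minimum and maximum number of sessions in a pattern.
#' @param n_slots Number of session slots, default 10.
#' @return List of integer vectors of included slots.
#' @export
enumerate_patterns <- function(t_min = 3, t_max = 10, n_slots = 10) {
  stopifnot(t_min >= 1, t_max <= n_slots, t_min <= t_max)
  out <- list()
  for (k in seq(t_min, t_max)) {
    out <- c(out, utils::combn(n_slots, k, simplify = FALSE))
  }
  out
}

#' @keywords internal
pattern_key <- function(pattern, n_slots = 10) {
  paste(as.integer(seq_len(n_slots) %in% pattern), collapse = "")
}

# Precompute per (participant, variable) session series keyed by slot so
# pattern evaluation avoids repeated data-frame grouping.
.pattern_prep <- function(sessions) {
  x <- sessions |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::arrange(.data$participant_id, .data$variable, .data$session_index)
  sp <- split(x, x$participant_id)
  vals <- lapply(sp, function(px) {
    lapply(split(px, px$variable), function(vx) {
      stats::setNames(vx$value, vx$session_index + 1L)
    })
  })
  list(participants = names(vals), vals = vals)
}

.evaluate_pattern_prepped <- function(pattern, prep, outcomes,
                                      threshold = 0.69,
                                      lopo_rule = c("min", "mean"),
                                      shape = "halved") {
  lopo_rule <- match.arg(lopo_rule)
  slots <- as.character(pattern)
  cpv <- vapply(prep$vals, function(pv) {
    scores <- vapply(pv, function(v) {
      x <- v[names(v) %in% slots]
      if (length(x) < 3L) NA_real_ else cpv_univariate(x, shape = shape)$cpv
    }, numeric(1))
    # participant retained only if >= 3 sessions fall in the pattern
    n_sess <- max(vapply(pv, function(v) sum(names(v) %in% slots), integer(1)))
    if (n_sess < 3L || all(is.na(scores))) NA_real_
    else max(scores, na.rm = TRUE)
  }, numeric(1))
  keep <- !is.na(cpv)
  size <- length(pattern)
  base <- tibble::tibble(
    pattern = pattern_key(pattern), T = size,
    n_participants = sum(keep),
    rho = NA_real_, r2 = NA_real_, auc = NA_real_, lopo_rho = NA_real_,
    passes_screen = FALSE, evaluable = FALSE
  )
  if (sum(keep) < 4L) {
    return(base)
  }
  ids <- prep$participants[keep]
  oc <- outcomes[match(ids, outcomes$participant_id), ]
  s <- unname(cpv[keep])
  y <- oc$total_shedding
  if (stats::sd(s) == 0 || stats::sd(y) == 0) {
    return(base)
  }
  rho <- stats::cor(s, y)
  lopo <- vapply(seq_along(s), function(i) stats::cor(s[-i], y[-i]),
                 numeric(1))
  lopo_stat <- if (lopo_rule == "min") min(lopo) else mean(lopo)
  base$rho <- rho
  base$r2 <- rho^2
  base$auc <- rank_auc(s, oc$label)
  base$lopo_rho <- lopo_stat
  base$passes_screen <- lopo_stat >= threshold
  base$evaluable <- TRUE
  base
}

#' Evaluate one session-timing pattern
#'
#' Recomputes the max-pooled CPV of every participant using only the sessions
#' falling in the pattern's slots (slot 1 is the screening session, so a
#' pattern containing slot 1 includes it), then measures the association with
#' total shedding: Pearson correlation, `R^2`, rank AUC against the high/low
#' labels, and the leave-one-participant-out (LOPO) screening statistic. A
#' participant retaining fewer than 3 sessions is dropped for that pattern;
#' a pattern retaining fewer than 4 participants is marked unevaluable.
#'
#' @param pattern Integer vector of included slots (subset of 1..10).
#' @param sessions Long session tibble including the screening session.
#' @param outcomes Outcome tibble ([outcome_table()]).
#' @param threshold LOPO screening threshold on the Pearson correlation,
#'   default 0.69 (the lower endpoint of the full-cohort 95% CI).
#' @param lopo_rule `"min"` (default: every LOPO correlation must clear the
#'   threshold) or `"mean"`.
#' @param shape Beta shape convention, see [cpv_univariate()].
#' @return One-row tibble: `pattern` (bitmask string over slots 1..10), `T`
#'   (pattern size), `n_participants`, `rho`, `r2`, `auc`, `lopo_rho`,
#'   `passes_screen`, `evaluable`.
#' @export
evaluate_pattern <- function(pattern, sessions, outcomes, threshold = 0.69,
                             lopo_rule = "min", shape = "halved") {
  prep <- .pattern_prep(sessions)
  .evaluate_pattern_prepped(pattern, prep, outcomes, threshold = threshold,
                            lopo_rule = lopo_rule, shape = shape)
}

#' Evaluate many session-timing patterns
#'
#' Runs [evaluate_pattern()] over a list of patterns (typically
#' [enumerate_patterns()]) with the per-study preparation done once.
#'
#' @inheritParams evaluate_pattern
#' @param patterns List of integer slot vectors.
#' @return Tibble with one row per pattern, columns as in
#'   [evaluate_pattern()].
#' @export
evaluate_patterns <- function(patterns, sessions, outcomes, threshold = 0.69,
                              lopo_rule = "min", shape = "halved") {
  prep <- .pattern_prep(sessions)
  purrr::map_dfr(patterns, .evaluate_pattern_prepped, prep = prep,
                 outcomes = outcomes, threshold = threshold,
                 lopo_rule = lopo_rule, shape = shape)
}

#' Rank passing patterns and tabulate slot-inclusion frequencies
#'
#' Ranks the patterns that pass the LOPO screen by decreasing correlation
#' (ties broken by smaller pattern size, then lexicographic pattern string),
#' keeps the top `k`, and tabulates how often each session slot appears among
#' them.
#'
#' @param results Tibble from [evaluate_patterns()].
#' @param k Number of top patterns to report, default 15.
#' @return List with `top` (tibble of up to `k` rows), `frequencies` (tibble:
#'   `slot`, `count`, `freq` relative to reported patterns) and `n_passing`.
#' @export
pattern_report <- function(results, k = 15) {
  passing <- dplyr::filter(results, .data$passes_screen)
  passing <- passing[order(-passing$rho, passing$T, passing$pattern), ]
  if (nrow(passing) < k) {
    message("only ", nrow(passing), " pattern(s) pass the screen")
  }
  top <- utils::head(passing, k)
  n_slots <- nchar(results$pattern[1])
  inc <- vapply(seq_len(n_slots), function(s) {
    sum(substr(top$pattern, s, s) == "1")
  }, integer(1))
  freqs <- tibble::tibble(slot = seq_len(n_slots), count = inc,
                          freq = if (nrow(top) > 0) inc / nrow(top) else 0)
  list(top = top, frequencies = freqs, n_passing = nrow(passing))
}
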