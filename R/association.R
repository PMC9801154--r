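#' Pearson correlation with Fisher z-transform inference
#'
#' Sample Pearson correlation with a two-sided p-value and 95% confidence
#' interval from the Fisher z-transform, `z = atanh(rho)` with standard error
#' `1/sqrt(n-3)`.
#'
#' @param x,y Numeric vectors of equal length, `n >= 4` complete pairs.
#' @return One-row tibble with `rho`, `p_value`, `ci_lo`, `ci_hi`, `n`. If
#'   either variable has zero variance the correlation is undefined: `rho` is
#'   `NA` and a warning is raised.
#' @export
pearson_test <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_, n = n))
  }
  rho <- stats::cor(x, y)
  se <- 1 / sqrt(n - 3)
  if (abs(rho) >= 1) {
    p <- 0
    ci <- c(rho, rho)
  } else {
    z <- atanh(rho)
    p <- 2 * stats::pnorm(-abs(z) / se)
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  tibble::tibble(rho = rho, p_value = p, ci_lo = ci[1], ci_hi = ci[2], n = n)
}

#' Coefficient of determination of a one-predictor linear model
#'
#' Least-squares fit of `y` on `x`; returns `R^2 = 1 - SS_resid / SS_total`,
#' which for a single predictor equals the squared Pearson correlation.
#'
#' @param x Predictor vector.
#' @param y Outcome vector.
#' @return Scalar in `[0, 1]`, or `NA` with a warning if the outcome has zero
#'   variance.
#' @export
linear_r2 <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (stats::sd(y) == 0) {
    warning("zero outcome variance: R^2 undefined")
    return(NA_real_)
  }
  fit <- stats::lm(y ~ x)
  unname(summary(fit)$r.squared)
}

#' Rank AUC of a score against binary labels
#'
#' Area under the ROC curve computed as the Mann-Whitney U probability that a
#' randomly chosen high-label score exceeds a randomly chosen low-label score
#' (ties count one half). This equals the AUC of any strictly monotone
#' transform of the score — in particular of a univariate logistic regression
#' fit — so no iterative model fit is needed, and perfect separation poses no
#' numerical difficulty.
#'
#' @param score Numeric scores.
#' @param labels Labels with exactly two classes; `"high"`/`"low"` character,
#'   a factor, or logical (`TRUE` = positive). For character labels,
#'   `"high"` is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(score, labels) {
  if (is.logical(labels)) {
    pos <- labels
  } else {
    labels <- as.character(labels)
    classes <- sort(unique(labels))
    if (length(classes) != 2L) stop("labels must have exactly two classes")
    positive <- if ("high" %in% classes) "high" else classes[2]
    pos <- labels == positive
  }
  if (all(pos) || !any(pos)) stop("labels must have exactly two classes")
  r <- rank(score)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Coefficient-of-variation comparator score
#'
#' The standard linear comparator to the CPV: per NCPT variable the
#' coefficient of variation `sd / |mean|` over the baseline sessions, pooled
#' across variables by the maximum (structurally parallel to the CPV
#' pooling). Variables with zero mean are skipped with a warning.
#'
#' @inheritParams cpv_table
#' @return Tibble with columns `participant_id`, `cov` (the pooled CoV
#'   score).
#' @export
cov_score <- function(sessions, variable_subset = NULL,
                      include_screening = FALSE) {
  x <- sessions
  if (!include_screening) x <- dplyr::filter(x, .data$session_index > 0L)
  if (!is.null(variable_subset)) {
    x <- dplyr::filter(x, .data$variable %in% variable_subset)
  }
  per_var <- x |>
    dplyr::group_by(.data$participant_id, .data$variable) |>
    dplyr::summarise(m = mean(.data$value, na.rm = TRUE),
                     s = stats::sd(.data$value, na.rm = TRUE),
                     .groups = "drop")
  zero <- per_var$m == 0
  if (any(zero, na.rm = TRUE)) {
    warning(sum(zero, na.rm = TRUE), " zero-mean variable series skipped")
    per_var <- per_var[!zero, ]
  }
  per_var |>
    dplyr::mutate(cv = .data$s / abs(.data$m)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(cov = max(.data$cv, na.rm = TRUE), .groups = "drop")
}

#' Associate a participant score with study outcomes
#'
#' Computes the three association measures between a per-participant score
#' (CPV or a comparator) and an outcome: Pearson correlation with Fisher-z
#' inference, one-predictor linear-model `R^2`, and the rank AUC against the
#' high/low shedder labels.
#'
#' @param scores Tibble with `participant_id` and a score column.
#' @param outcomes Outcome tibble ([outcome_table()]).
#' @param score_col Name of the score column, default the first non-id
#'   column.
#' @return One-row tibble per outcome measure (`total_shedding`,
#'   `total_symptom`) with `rho`, `p_value`, `ci_lo`, `ci_hi`, `r2`, and for
#'   shedding the `auc`, plus `n`.
#' @export
associate_outcomes <- function(scores, outcomes, score_col = NULL) {
  if (is.null(score_col)) {
    score_col <- setdiff(names(scores), "participant_id")[1]
  }
  j <- dplyr::inner_join(scores, outcomes, by = "participant_id")
  s <- j[[score_col]]
  res <- purrr::map_dfr(c("total_shedding", "total_symptom"), function(oc) {
    pt <- pearson_test(s, j[[oc]])
    pt$outcome <- oc
    pt$r2 <- linear_r2(s, j[[oc]])
    pt$auc <- if (oc == "total_shedding") rank_auc(s, j$label) else NA_real_
    pt
  })
  res[, c("outcome", "rho", "p_value", "ci_lo", "ci_hi", "r2", "auc", "n")]
}

#' Correlate participant CPV scores with baseline covariates
#'
#' Pearson tests ([pearson_test()]) of the pooled CPV score against each
#' covariate present in the covariate table; covariates with undefined
#' correlation are reported with `NA` rather than dropped.
#'
#' @param cpv_scores Tibble from [cpv_score()] (columns `participant_id`,
#'   `cpv`).
#' @param covariates Covariate tibble ([read_covariates()]).
#' @return Tidy tibble with one row per covariate: `covariate`, `rho`,
#'   `p_value`, `ci_lo`, `ci_hi`, `n`.
#' @export
covariate_correlations <- function(cpv_scores, covariates) {
  j <- dplyr::inner_join(cpv_scores, covariates, by = "participant_id")
  if (nrow(j) < 4L) stop("fewer than 4 shared participants")
  covs <- intersect(covariate_registry(), names(covariates))
  purrr::map_dfr(covs, function(cv) {
    res <- tryCatch(pearson_test(j$cpv, j[[cv]]),
                    warning = function(w) {
                      tibble::tibble(rho = NA_real_, p_value = NA_real_,
                                     ci_lo = NA_real_, ci_hi = NA_real_,
                                     n = nrow(j))
                    })
    dplyr::bind_cols(tibble::tibble(covariate = cv), res)
  })
}
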