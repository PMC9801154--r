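#' Configuration for the synthetic challenge study generator
#'
#' Defaults emulate the structure of the real cohort: 18 participants, a
#' screening session several days before baseline plus 9 baseline sessions
#' (three per day at 8 h intervals over 3 days, exposure after hour 80), 18
#' NCPT variables, 4 post-inoculation shedding days and 5 symptom-diary days,
#' and a gene-expression matrix sampled at every baseline session.
#'
#' The planted cognitive signal is drift, not dispersion: for each
#' participant one affected NCPT variable receives successive increments with
#' nonzero mean of magnitude `drift_effect * s_i` (in units of the session
#' noise level), the drift direction drawn once per participant. This is
#' exactly the mean-shift-in-differences structure the variability index
#' rewards. The
#' remaining variables are level plus i.i.d. noise, and the control variable
#' (`trail-layoutNum`) is a fresh random draw each session.
#'
#' @param n_participants Cohort size, default 18.
#' @param session_times_h Baseline session times in hours, default three per
#'   day over 3 days.
#' @param screening_time_h Screening session time, default -96 (several days
#'   before baseline).
#' @param drift_effect Mean per-step drift of the affected variable per unit
#'   susceptibility, in units of the per-session noise standard deviation.
#'   Default 6.
#' @param noise_frac Within-participant measurement noise as a fraction of
#'   the variable scale, default 0.04.
#' @param sign_flip_prob Probability that the drift sign flips between
#'   consecutive baseline days, default 0 (sign fixed per participant;
#'   opposing signs cancel the mean successive difference the index
#'   detects).
#' @param signal_variables Variables eligible to carry the planted drift;
#'   default the six clinically prominent measures.
#' @param shedding_days,symptom_days Post-inoculation day windows.
#' @param shed_base,shed_slope,shed_noise_sd Planted total shedding is
#'   `shed_base + shed_slope * s_i` plus Gaussian noise.
#' @param link_rho Target correlation between total symptom score and total
#'   shedding, default 0.8; `sym_noise_sd` is its calibration knob.
#' @param sym_noise_sd Noise on the latent symptom severity.
#' @param n_genes,n_planted_genes Expression panel size and number of planted
#'   genes.
#' @param screen_variable NCPT variable the planted genes track.
#' @param expr_beta,expr_noise_sd Planted gene = affine in the standardized
#'   NCPT series with slope `expr_beta` plus noise `expr_noise_sd`.
#' @param n_pathways,pathway_size,planted_overlap Pathway gene sets: one
#'   planted pathway shares `planted_overlap` genes with the planted set.
#' @param seed Default seed used by [simulate_study()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 18,
                       session_times_h = c(4, 12, 20, 28, 36, 44, 52, 60, 68),
                       screening_time_h = -96,
                       drift_effect = 6,
                       noise_frac = 0.04,
                       sign_flip_prob = 0,
                       signal_variables = c("digSym-time", "digSym-correct",
                                            "reaction-time",
                                            "posner-tutorialTime",
                                            "trail-time",
                                            "trail-tutorialTime"),
                       shedding_days = 5:8,
                       symptom_days = 4:8,
                       shed_base = 1.5, shed_slope = 9, shed_noise_sd = 0.4,
                       link_rho = 0.8, sym_noise_sd = 0.25,
                       n_genes = 300, n_planted_genes = 25,
                       screen_variable = "digSym-correct",
                       expr_beta = 0.8, expr_noise_sd = 0.8,
                       n_pathways = 20, pathway_size = 30,
                       planted_overlap = 15,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_participants >= 2, cfg$drift_effect >= 0,
            cfg$noise_frac > 0, cfg$n_planted_genes <= cfg$n_genes,
            cfg$planted_overlap <= cfg$n_planted_genes,
            cfg$planted_overlap <= cfg$pathway_size,
            cfg$screen_variable %in% ncpt_catalog()$variable)
  structure(cfg, class = "sim_config")
}

# per-role magnitude and between-participant spread of NCPT baselines
.ncpt_scales <- function() {
  tibble::tibble(
    role = c("time", "correct", "congruency", "control"),
    mu = c(30, 40, 5, NA),
    between_sd = c(5, 6, 1, NA),
    scale = c(30, 40, 5, NA)
  )
}

#' Generate a synthetic viral challenge study
#'
#' Draws a complete study-shaped data set with planted structure and records
#' the ground truth needed to score recovery. Per-participant susceptibility
#' `s_i` is drawn as a balanced two-group mixture (half low, half high),
#' mirroring the clear low/high shedder separation of the cohort the
#' generator emulates. Susceptibility drives, with independent noise: the
#' planted cognitive drift (one affected variable per participant), total
#' viral shedding, symptom severity (calibrated so symptom and shedding
#' totals correlate near `link_rho`), and the stress/fatigue/sleep
#' covariates; a morningness covariate is included as an independent negative
#' control. Planted genes are affine in the chosen NCPT variable's session
#' values; one pathway overlaps the planted genes.
#'
#' All randomness flows from `seed` through a single `set.seed()` call, so a
#' fixed seed reproduces the study exactly.
#'
#' @param config A [sim_config()] list.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list of class `cpv_study` with elements `sessions`, `shedding`,
#'   `symptoms`, `covariates`, `expression`, `pathways`, `truth` (ground
#'   truth: `s`, `affected_variable`, `planted_shedding`, `severity`,
#'   `planted_genes`, `planted_pathway`, `screen_variable`) and `config`.
#' @export
simulate_study <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config
  np <- cfg$n_participants
  ids <- sprintf("P%02d", seq_len(np))
  catalog <- ncpt_catalog()
  scales <- .ncpt_scales()

  # susceptibility: balanced low/high mixture, shuffled over participants
  n_low <- floor(np / 2)
  s <- sample(c(stats::runif(n_low, 0.05, 0.30),
                stats::runif(np - n_low, 0.70, 0.95)))
  names(s) <- ids
  affected <- stats::setNames(
    sample(cfg$signal_variables, np, replace = TRUE), ids)

  times <- cfg$session_times_h
  n_base <- length(times)
  day_of <- findInterval(times, seq(0, max(times) + 24, by = 24))

  sessions <- vector("list", np)
  for (i in seq_len(np)) {
    # drift direction: one random sign per participant, optionally flipped
    # between days; flips dilute the planted mean shift (the index detects
    # the mean successive difference, and opposing signs cancel), so the
    # default keeps the sign fixed over the short 3-day baseline
    day_sign <- rep(sample(c(-1, 1), 1), max(day_of))
    if (cfg$sign_flip_prob > 0 && max(day_of) > 1) {
      flips <- stats::runif(max(day_of) - 1) < cfg$sign_flip_prob
      day_sign <- day_sign[1] * cumprod(c(1, ifelse(flips, -1, 1)))
    }
    vals <- matrix(NA_real_, nrow = n_base + 1, ncol = nrow(catalog))
    for (v in seq_len(nrow(catalog))) {
      var <- catalog$variable[v]
      role <- catalog$role[v]
      if (role == "control") {
        vals[, v] <- as.numeric(sample(1:20, n_base + 1, replace = TRUE))
      } else {
        sc <- scales[scales$role == role, ]
        level <- stats::rnorm(1, sc$mu, sc$between_sd)
        noise <- stats::rnorm(n_base + 1, 0, cfg$noise_frac * sc$scale)
        trend <- rep(0, n_base)
        if (var == affected[i]) {
          # per-step drift in units of the session noise sd
          delta <- day_sign[day_of] * cfg$drift_effect * s[i] *
            cfg$noise_frac * sc$scale
          trend <- cumsum(delta)
        }
        vals[, v] <- level + c(0, trend) + noise
      }
    }
    sessions[[i]] <- tibble::tibble(
      participant_id = ids[i],
      session_index = rep(0:n_base, times = nrow(catalog)),
      time_h = rep(c(cfg$screening_time_h, times), times = nrow(catalog)),
      variable = rep(catalog$variable, each = n_base + 1),
      value = as.vector(vals)
    )
  }
  sessions <- dplyr::bind_rows(sessions) |>
    dplyr::arrange(.data$participant_id, .data$session_index, .data$variable)

  # shedding: planted total monotone in s, split over post-inoculation days
  planted_total <- cfg$shed_base + cfg$shed_slope * s
  obs_total <- pmax(planted_total + stats::rnorm(np, 0, cfg$shed_noise_sd),
                    0.1)
  shedding <- purrr::map_dfr(seq_len(np), function(i) {
    w <- stats::rgamma(length(cfg$shedding_days), shape = 2)
    w <- w / sum(w)
    tibble::tibble(participant_id = ids[i], study_day = cfg$shedding_days,
                   titer = round(obs_total[i] * w, 4))
  })

  # symptoms: latent severity in [0,1] drives binomial ranks
  severity <- pmin(pmax(s + stats::rnorm(np, 0, cfg$sym_noise_sd), 0), 1)
  n_days <- length(cfg$symptom_days)
  n_entries <- np * n_days * 3L
  symptoms <- tibble::tibble(
    participant_id = rep(ids, each = n_days * 3L),
    study_day = rep(rep(cfg$symptom_days, each = 3L), times = np),
    entry_index = rep(1:3, times = np * n_days)
  )
  p_entry <- 0.02 + 0.2 * severity[symptoms$participant_id]
  ranks <- matrix(stats::rbinom(n_entries * 8L, 3L, rep(p_entry, 8L)),
                  nrow = n_entries)
  colnames(ranks) <- symptom_names()
  symptoms <- dplyr::bind_cols(symptoms,
                               tibble::as_tibble(`mode<-`(ranks, "integer")))

  covariates <- tibble::tibble(
    participant_id = ids,
    pss_screening = round(pmin(pmax(12 + 18 * s + stats::rnorm(np, 0, 3.5),
                                    0), 40), 1),
    vafs_mean = round(pmin(pmax(4 + 4 * s + stats::rnorm(np, 0, 0.9), 0), 10),
                      2),
    vafs_sd = round(pmax(2.2 - 1.6 * s + stats::rnorm(np, 0, 0.4), 0.05), 2),
    sleep_duration_sd = round(pmax(1.6 - 1.1 * s + stats::rnorm(np, 0, 0.3),
                                   0.05), 2),
    rcsm_morningness = round(stats::runif(np, 7, 35))
  )

  # expression: planted genes affine in the screen variable's baseline series
  xvar <- sessions |>
    dplyr::filter(.data$variable == cfg$screen_variable,
                  .data$session_index > 0L)
  sample_keys <- paste0(xvar$participant_id, ":", xvar$session_index)
  xz <- as.vector(scale(xvar$value))
  n_samp <- length(sample_keys)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  planted_genes <- genes[seq_len(cfg$n_planted_genes)]
  base_level <- stats::runif(cfg$n_genes, 2, 10)
  expr <- matrix(stats::rnorm(cfg$n_genes * n_samp, 0, 1),
                 nrow = cfg$n_genes)
  expr <- expr + base_level
  for (g in seq_len(cfg$n_planted_genes)) {
    expr[g, ] <- base_level[g] + cfg$expr_beta * xz +
      stats::rnorm(n_samp, 0, cfg$expr_noise_sd)
  }
  rownames(expr) <- genes
  colnames(expr) <- sample_keys
  expr <- round(expr, 4)

  null_pool <- setdiff(genes, planted_genes)
  pathways <- list()
  pathways[["PW01"]] <- c(sample(planted_genes, cfg$planted_overlap),
                          sample(null_pool,
                                 cfg$pathway_size - cfg$planted_overlap))
  for (k in 2:cfg$n_pathways) {
    pathways[[sprintf("PW%02d", k)]] <- sample(null_pool, cfg$pathway_size)
  }

  truth <- list(s = s, affected_variable = affected,
                planted_shedding = stats::setNames(planted_total, ids),
                severity = stats::setNames(severity, ids),
                planted_genes = planted_genes, planted_pathway = "PW01",
                screen_variable = cfg$screen_variable)

  structure(list(sessions = sessions, shedding = shedding,
                 symptoms = symptoms, covariates = covariates,
                 expression = expr, pathways = pathways, truth = truth,
                 config = cfg),
            class = "cpv_study")
}

#' @export
print.cpv_study <- function(x, ...) {
  cat("Synthetic challenge study:",
      x$config$n_participants, "participants,",
      length(unique(x$sessions$session_index)), "session slots,",
      nrow(x$expression), "genes\n")
  invisible(x)
}

#' Write a study to the on-disk fixture layout
#'
#' Writes `sessions.csv`, `shedding.csv`, `symptoms.csv`, `covariates.csv`,
#' `expression.csv` and `pathways.gmt` in exactly the dialects the readers
#' consume, so a generate-write-read cycle round-trips.
#'
#' @param study A `cpv_study` list ([simulate_study()]).
#' @param dir Output directory; created if absent. If it exists and is
#'   nonempty, refuses unless `force = TRUE`.
#' @param force Overwrite a nonempty directory? Default `FALSE`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixtures <- function(study, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop("directory ", dir, " is nonempty; use force = TRUE to overwrite")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    sessions = write_sessions(study$sessions, file.path(dir, "sessions.csv")),
    shedding = write_shedding(study$shedding, file.path(dir, "shedding.csv")),
    symptoms = write_symptoms(study$symptoms, file.path(dir, "symptoms.csv")),
    covariates = write_covariates(study$covariates,
                                  file.path(dir, "covariates.csv")),
    expression = write_expression(study$expression,
                                  file.path(dir, "expression.csv")),
    pathways = write_pathways(study$pathways, file.path(dir, "pathways.gmt"))
  )
  invisible(files)
}
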