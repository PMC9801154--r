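#' Catalog of the 18 NCPT variables
#'
#' The NeuroCognitive Performance Test battery used here comprises four
#' subtests — Digital Symbol Coding (DigSym), Go/No-Go (Reaction), Trail
#' Making B (Trail) and Attentional Cueing (Posner) — which together yield 18
#' per-session scores related to speed, accuracy and congruency. One entry,
#' `trail-layoutNum`, is a control variable: the layout number is randomly
#' generated at the start of each Trail test and carries no performance
#' signal.
#'
#' @return A tibble with columns `variable`, `test` (one of `DigSym`,
#'   `Reaction`, `Trail`, `Posner`) and `role` (one of `time`, `correct`,
#'   `congruency`, `control`), 18 rows.
#' @export
#' @examples
#' ncpt_catalog()
ncpt_catalog <- function() {
  cat <- tibble::tribble(
    ~variable,                  ~test,      ~role,
    "digSym-time",              "DigSym",   "time",
    "digSym-correct",           "DigSym",   "correct",
    "digSym-incorrect",         "DigSym",   "correct",
    "digSym-tutorialTime",      "DigSym",   "time",
    "reaction-time",            "Reaction", "time",
    "reaction-correct",         "Reaction", "correct",
    "reaction-incorrect",       "Reaction", "correct",
    "reaction-congruentTime",   "Reaction", "congruency",
    "reaction-tutorialTime",    "Reaction", "time",
    "trail-time",               "Trail",    "time",
    "trail-correct",            "Trail",    "correct",
    "trail-incorrect",          "Trail",    "correct",
    "trail-tutorialTime",       "Trail",    "time",
    "trail-layoutNum",          "Trail",    "control",
    "posner-time",              "Posner",   "time",
    "posner-correct",           "Posner",   "correct",
    "posner-congruency",        "Posner",   "congruency",
    "posner-tutorialTime",      "Posner",   "time"
  )
  stopifnot(nrow(cat) == 18L, !anyDuplicated(cat$variable),
            sum(cat$role == "control") == 1L)
  cat
}

#' Registry of recognized participant covariates
#'
#' Baseline psychometric and behavioural covariates that the study records
#' alongside cognitive testing: the Perceived Stress Scale at screening,
#' mean and standard deviation of the thrice-daily Visual Analog Fatigue
#' Scale (10 = no fatigue), the standard deviation of nightly sleep duration
#' over baseline, and the reduced Composite Scale of Morningness chronotype
#' score.
#'
#' @return Character vector of recognized covariate column names.
#' @export
covariate_registry <- function() {
  c("pss_screening", "vafs_mean", "vafs_sd", "sleep_duration_sd",
    "rcsm_morningness")
}

#' Names of the 8 diary symptoms
#'
#' Upper-respiratory symptoms ranked 0-3 at each diary entry; their sum is
#' the modified Jackson score.
#'
#' @return Character vector of length 8.
#' @export
symptom_names <- function() {
  c("chills", "cough", "headache", "nasalobstruction",
    "runnynose", "sneezing", "sorethroat", "tiredness")
}
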