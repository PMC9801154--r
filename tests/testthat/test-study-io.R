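write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

session_header <- "participant_id,session_index,time_h,digSym-time,trail-time"

test_that("session reader preserves counts, sorts, and reports missing cells", {
  f <- write_lines_tmp(c(
    session_header,
    "P02,1,8,31.2,28.0",
    "P01,2,16,29.0,27.5",
    "P01,1,8,30.1,",
    "P02,2,16,33.3,29.1"
  ))
  expect_warning(x <- read_sessions(f), "1 missing")
  expect_equal(nrow(x), 4 * 2)
  expect_equal(sum(is.na(x$value)), 1L)
  expect_equal(attr(x, "n_missing"), 1L)
  # sorted by participant then session
  keys <- unique(paste(x$participant_id, x$session_index))
  expect_equal(keys, c("P01 1", "P01 2", "P02 1", "P02 2"))
  # header-only file is an empty table, not an error
  f0 <- write_lines_tmp(session_header)
  expect_equal(nrow(read_sessions(f0)), 0L)
})

test_that("session reader rejects malformed tables", {
  f <- write_lines_tmp(c(
    "participant_id,session_index,time_h,notAVariable",
    "P01,1,8,1.0"
  ))
  expect_error(read_sessions(f), "notAVariable")
  f2 <- write_lines_tmp(c(session_header, "P01,1,8,1,2", "P01,1,9,1,2"))
  expect_error(read_sessions(f2), "duplicated")
  f3 <- write_lines_tmp(c(session_header, "P01,1,8,1,2", "P01,2,7,1,2"))
  expect_error(read_sessions(f3), "strictly increasing")
})

test_that("unparseable numeric cells become missing and are counted", {
  f <- write_lines_tmp(c(session_header, "P01,1,8,oops,2"))
  w <- capture_warnings(x <- read_sessions(f))
  expect_true(any(grepl("missing", w)))
  expect_equal(attr(x, "n_parse_failures"), 1L)
  expect_true(is.na(x$value[x$variable == "digSym-time"]))
})

test_that("outcome readers validate ranges and keys", {
  f <- write_lines_tmp(c("participant_id,study_day,titer",
                         "P01,5,2.0", "P01,6,1.5", "P02,5,0.0"))
  shed <- read_shedding(f)
  expect_equal(nrow(shed), 3L)
  f2 <- write_lines_tmp(c("participant_id,study_day,titer", "P01,5,-1"))
  expect_error(read_shedding(f2), "negative")
  sy <- paste0("participant_id,study_day,entry_index,",
               paste(symptom_names(), collapse = ","))
  f3 <- write_lines_tmp(c(sy, "P07,5,1,0,1,2,3,0,1,2,3"))
  expect_equal(nrow(read_symptoms(f3)), 1L)
  f4 <- write_lines_tmp(c(sy, "P07,5,1,0,1,2,4,0,1,2,3"))
  expect_error(read_symptoms(f4), "P07.*day 5")
  f5 <- write_lines_tmp(c("participant_id,pss_screening,shoe_size",
                          "P01,22,43"))
  expect_error(read_covariates(f5), "shoe_size")
})

test_that("a full study round-trips through the fixture files", {
  st <- default_study()
  dir <- withr::local_tempdir()
  write_fixtures(st, dir, force = TRUE)
  s2 <- suppressWarnings(read_sessions(file.path(dir, "sessions.csv")))
  key <- function(d) d[order(d$participant_id, d$session_index, d$variable), ]
  expect_equal(
    as.data.frame(key(s2)),
    as.data.frame(key(st$sessions[, names(s2)])),
    ignore_attr = TRUE
  )
  expect_equal(as.data.frame(read_shedding(file.path(dir, "shedding.csv"))),
               as.data.frame(st$shedding), ignore_attr = TRUE)
  expect_equal(as.data.frame(read_symptoms(file.path(dir, "symptoms.csv"))),
               as.data.frame(st$symptoms), ignore_attr = TRUE)
  expect_equal(
    as.data.frame(read_covariates(file.path(dir, "covariates.csv"))),
    as.data.frame(st$covariates), ignore_attr = TRUE)
  expect_equal(read_expression(file.path(dir, "expression.csv")),
               st$expression)
  expect_equal(read_pathways(file.path(dir, "pathways.gmt")), st$pathways)
})

test_that("validation report flags short and screening-less participants", {
  st <- default_study()
  rep0 <- validate_study(st$sessions, st$shedding, st$symptoms)
  expect_length(rep0$incomputable, 0L)
  expect_length(rep0$missing_screening, 0L)
  expect_true(all(rep0$session_counts$n_baseline >= 8))
  # cripple one participant: keep 2 baseline sessions, drop screening
  s <- st$sessions
  s <- s[!(s$participant_id == "P01" & s$session_index %in% c(0, 3:9)), ]
  rep1 <- validate_study(s)
  expect_identical(rep1$incomputable, "P01")
  expect_identical(rep1$missing_screening, "P01")
  expect_output(print(rep1), "P01")
})
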