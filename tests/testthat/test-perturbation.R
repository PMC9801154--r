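test_that("leave-one-session-out produces one score per session", {
  set.seed(31)
  x <- rnorm(10)
  res <- loo_session_cpv(x)
  expect_length(res$loo, 10L)
  expect_equal(res$full, cpv_univariate(x)$cpv)
  expect_true(all(loo_session_cpv(rep(2, 6))$loo == 0))
  # dropping an endpoint of a ramp keeps zero residual variance (capped);
  # dropping an interior point creates one double step but the score stays
  # far above the no-drift regime
  ramp <- loo_session_cpv(1:8)
  expect_equal(ramp$loo[c(1, 8)], rep(cpv_cap(), 2))
  expect_true(all(ramp$loo > 1))
  expect_error(loo_session_cpv(c(1, 2, 3)), "at least 4")
})

test_that("loo table covers every (participant, variable, session)", {
  st <- default_study()
  tab <- loo_session_table(st$sessions, variable_subset = "digSym-time")
  expect_equal(nrow(tab), 18 * 9)
  expect_setequal(tab$left_out_index, 1:9)
  # the full-series score is constant within a participant
  per <- tapply(tab$full_cpv, tab$participant_id, function(v)
    length(unique(v)))
  expect_true(all(per == 1))
})

test_that("pattern enumeration is exhaustive and duplicate-free", {
  expect_length(enumerate_patterns(10, 10), 1L)
  expect_length(enumerate_patterns(3, 3), choose(10, 3))
  pats <- enumerate_patterns()
  expect_length(pats, 968L)
  keys <- vapply(pats, function(p) paste(p, collapse = ","), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  sizes <- lengths(pats)
  expect_true(all(sizes >= 3 & sizes <= 10))
})

test_that("the full non-screening pattern reproduces the main analysis", {
  st <- default_study()
  oc <- default_outcomes()
  res <- evaluate_pattern(2:10, st$sessions, oc)
  sc <- cpv_score(st$sessions)
  j <- dplyr::inner_join(sc, oc, by = "participant_id")
  expect_identical(res$rho, stats::cor(j$cpv, j$total_shedding))
  expect_identical(res$auc, rank_auc(j$cpv, j$label))
  expect_identical(res$r2, res$rho^2)
  expect_true(res$evaluable)
})

test_that("a slot nobody attended does not change a pattern's result", {
  st <- default_study()
  oc <- default_outcomes()
  # remove slot 5 (session_index 4) from everyone
  sess <- st$sessions[st$sessions$session_index != 4L, ]
  with_slot <- evaluate_pattern(c(2, 3, 4, 5, 6), sess, oc)
  without <- evaluate_pattern(c(2, 3, 4, 6), sess, oc)
  expect_equal(with_slot$rho, without$rho)
  expect_equal(with_slot$auc, without$auc)
})

test_that("participants dropping below 3 sessions are excluded per pattern", {
  st <- default_study()
  oc <- default_outcomes()
  # P01 only attends slots 2..4; a pattern covering slots 8..10 drops them
  sess <- st$sessions[!(st$sessions$participant_id == "P01" &
                          !st$sessions$session_index %in% 1:3), ]
  res <- evaluate_pattern(c(8, 9, 10), sess, oc)
  expect_equal(res$n_participants, 17L)
})

test_that("LOPO screening rule and report ranking are deterministic", {
  st <- default_study()
  oc <- default_outcomes()
  pats <- c(enumerate_patterns(9, 10), list(c(2:10)))
  res <- evaluate_patterns(pats, st$sessions, oc)
  expect_true(all(res$passes_screen == (res$lopo_rho >= 0.69)))
  # LOPO minimum cannot exceed a loose bound above the full-cohort value
  expect_true(all(res$lopo_rho <= res$rho + 0.2))
  rep <- pattern_report(res, k = 5)
  expect_lte(nrow(rep$top), 5L)
  expect_true(all(diff(rep$top$rho) <= 1e-12))
  # counting identity: slot counts sum to the sizes of reported patterns
  expect_equal(sum(rep$frequencies$count), sum(rep$top$T))
  # mean rule is exposed and at least as permissive as min
  res_mean <- evaluate_patterns(pats, st$sessions, oc, lopo_rule = "mean")
  expect_true(all(res_mean$lopo_rho >= res$lopo_rho - 1e-12))
})
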