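# Shared fixtures and cached Monte-Carlo experiments. Everything is built in
# code at test time; the cache only avoids regenerating the same study within
# one test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_study <- function(seed = 42) {
  cached(paste0("study", seed),
         suppressWarnings(simulate_study(sim_config(), seed = seed)))
}

default_outcomes <- function(seed = 42) {
  st <- default_study(seed)
  cached(paste0("outcomes", seed),
         suppressWarnings(outcome_table(st$shedding, st$symptoms)))
}

small_config <- function(...) {
  sim_config(n_participants = 6, n_genes = 40, n_planted_genes = 6,
             planted_overlap = 4, pathway_size = 10, n_pathways = 4, ...)
}

# per-seed recovery statistics for the planted-signal experiments:
# CPV and CoV associations with total shedding under the default generator
recovery_stats <- function(n_seeds, drift = NULL) {
  key <- paste0("recovery", n_seeds, "_",
                if (is.null(drift)) "default" else drift)
  cached(key, {
    cfg <- if (is.null(drift)) sim_config() else sim_config(drift_effect = drift)
    vapply(seq_len(n_seeds), function(seed) {
      st <- suppressWarnings(simulate_study(cfg, seed = seed))
      oc <- suppressWarnings(outcome_table(st$shedding, st$symptoms))
      sc <- cpv_score(st$sessions)
      cv <- suppressWarnings(cov_score(st$sessions))
      j <- dplyr::inner_join(sc, oc, by = "participant_id")
      jc <- dplyr::inner_join(cv, oc, by = "participant_id")
      c(rho = stats::cor(j$cpv, j$total_shedding),
        auc = rank_auc(j$cpv, j$label),
        cov_rho = stats::cor(jc$cov, jc$total_shedding))
    }, numeric(3))
  })
}

# independent term-by-term implementation of the variability index,
# following the definition sum by sum (oracle for the closed form)
brute_force_T <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  d <- numeric(n - 1)
  for (m in 2:n) d[m - 1] <- x[m] - x[m - 1]
  dbar <- sum(d) / (n - 1)
  num <- 0
  for (m in seq_along(d)) num <- num + d[m]^2
  cen <- 0
  for (m in seq_along(d)) cen <- cen + (d[m] - dbar)^2
  ((n - 2) * num) / ((n - 2) * num + (n - 1) * cen)
}

# brute-force Benjamini-Hochberg step-up (oracle for p.adjust)
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}
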