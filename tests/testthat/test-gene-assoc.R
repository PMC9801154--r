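test_that("pairing matches expression samples to sessions by key", {
  st <- default_study()
  pr <- pair_series(st$sessions, st$expression, "digSym-correct")
  expect_length(pr$x, 18 * 9)
  expect_identical(names(pr$x), colnames(pr$expression))
  # screening sessions have no expression sample and are excluded anyway
  expect_false(any(grepl(":0$", names(pr$x))))
  # disjoint keys error
  e2 <- st$expression
  colnames(e2) <- paste0("X", seq_len(ncol(e2)))
  expect_error(pair_series(st$sessions, e2, "digSym-correct"), "shared")
})

test_that("missing expression values reduce n for that gene only", {
  st <- default_study()
  e <- st$expression
  e["G0100", 1:3] <- NA
  gs <- suppressWarnings(gene_screen(st$sessions, e, "digSym-correct"))
  expect_equal(gs$n[gs$gene == "G0100"], 162L - 3L)
  expect_true(all(gs$n[gs$gene != "G0100"] == 162L))
})

test_that("the screen recovers planted genes at the top of the list", {
  st <- default_study()
  gs <- gene_screen(st$sessions, st$expression, st$truth$screen_variable)
  planted <- st$truth$planted_genes
  expect_true(all(planted %in% gs$gene[gs$significant]))
  # planted genes dominate the top of the ranking
  expect_true(all(utils::head(gs$gene, 10) %in% planted))
  # few false positives at FDR 0.05 among 275 null genes
  expect_lt(sum(gs$significant & !gs$gene %in% planted), 15)
  expect_true(all(diff(gs$p_value) >= 0))
})

test_that("per-gene p-values match cor.test and BH matches p.adjust", {
  st <- default_study()
  gs <- gene_screen(st$sessions, st$expression, "digSym-correct")
  pr <- pair_series(st$sessions, st$expression, "digSym-correct")
  for (g in sample(gs$gene, 4)) {
    ref <- stats::cor.test(pr$x, pr$expression[g, ])
    row <- gs[gs$gene == g, ]
    expect_equal(row$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(row$p_value, ref$p.value, tolerance = 1e-9)
  }
  expect_equal(gs$fdr, stats::p.adjust(gs$p_value, method = "BH"))
  # single gene: fdr equals the raw p
  gs1 <- gene_screen(st$sessions, st$expression["G0200", , drop = FALSE],
                     "digSym-correct")
  expect_equal(gs1$fdr, gs1$p_value)
})

test_that("BH adjustment is invariant to input order", {
  st <- default_study()
  set.seed(41)
  shuffled <- st$expression[sample(nrow(st$expression)), ]
  gs1 <- gene_screen(st$sessions, st$expression, "digSym-correct")
  gs2 <- gene_screen(st$sessions, shuffled, "digSym-correct")
  j <- dplyr::inner_join(gs1, gs2, by = "gene")
  expect_equal(j$fdr.x, j$fdr.y)
})

test_that("fisher enrichment matches the hypergeometric tail on small tables", {
  pathways <- list(hit = paste0("g", 1:6), miss = paste0("h", 1:6))
  background <- c(paste0("g", 1:6), paste0("h", 1:6), paste0("n", 1:28))
  sig <- c(paste0("g", 1:5), "n1", "n2")
  res <- pathway_enrichment(sig, pathways, background)
  hit <- res[res$pathway == "hit", ]
  # one-sided Fisher p = hypergeometric upper tail, summed by brute force
  ks <- hit$shared_size:min(length(sig), hit$pathway_size)
  p_oracle <- sum(stats::dhyper(ks, hit$pathway_size,
                                length(background) - hit$pathway_size,
                                length(sig)))
  expect_equal(hit$p_value, p_oracle, tolerance = 1e-12)
  expect_gt(hit$odds_ratio, 1)
  expect_lt(res$odds_ratio[res$pathway == "miss"], 1)
})

test_that("degenerate enrichment tables use the Haldane correction", {
  background <- paste0("g", 1:40)
  sig <- paste0("g", 1:8)
  res <- pathway_enrichment(sig, list(all_sig = sig), background)
  # zero cell: raw odds ratio infinite, corrected one finite and large
  expect_true(is.finite(res$odds_ratio))
  expect_gt(res$odds_ratio, 100)
  expect_lt(res$p_value, 1e-6)
  # background must cover the significant set
  expect_error(pathway_enrichment(c(sig, "zz"), list(a = sig), background),
               "background")
})
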