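#' Pair an NCPT variable's sessions with expression samples
#'
#' Matches expression samples (columns named `participant:session_index`) to
#' the same participant-session's value of one NCPT variable, pooling pairs
#' across all participants' baseline sessions. Samples without a matching
#' session, or sessions without a sample, are dropped.
#'
#' @param sessions Long session tibble ([read_sessions()]).
#' @param expression Genes x samples matrix ([read_expression()]).
#' @param variable NCPT variable name to pair.
#' @param include_screening Include screening-session samples? Default
#'   `FALSE`.
#' @return List with `x` (named numeric vector of NCPT values per matched
#'   sample) and `expression` (the matrix restricted to matched columns, same
#'   order). Errors if no keys are shared.
#' @export
pair_series <- function(sessions, expression, variable,
                        include_screening = FALSE) {
  v <- dplyr::filter(sessions, .data$variable == !!variable)
  if (nrow(v) == 0) stop("variable not present in sessions: ", variable)
  if (!include_screening) v <- dplyr::filter(v, .data$session_index > 0L)
  key <- paste0(v$participant_id, ":", v$session_index)
  x <- stats::setNames(v$value, key)
  shared <- intersect(colnames(expression), key)
  if (length(shared) == 0) {
    stop("no shared (participant, session) keys between sessions and ",
         "expression samples")
  }
  list(x = x[shared], expression = expression[, shared, drop = FALSE])
}

#' Gene-expression correlation screen for one NCPT variable
#'
#' For each gene, the Pearson correlation between the pooled baseline NCPT
#' values and the gene's expression across matched participant-sessions, with
#' the two-sided correlation-test p-value (t reference on `n - 2` degrees of
#' freedom, pairwise-complete pairs per gene) and Benjamini-Hochberg FDR
#' across all genes tested for the variable. Genes with zero expression
#' variance (or fewer than 4 complete pairs) are skipped and counted.
#'
#' @inheritParams pair_series
#' @param alpha FDR significance level for the `significant` flag, default
#'   0.05.
#' @param log_transform Apply `log2(x + 1)` to expression first? Default
#'   `FALSE` (TPM values used as provided).
#' @return Tibble sorted by p-value with columns `gene`, `rho`, `p_value`,
#'   `fdr`, `n`, `significant`; the number of skipped genes is attached as
#'   attribute `n_skipped`.
#' @export
gene_screen <- function(sessions, expression, variable, alpha = 0.05,
                        log_transform = FALSE, include_screening = FALSE) {
  pr <- pair_series(sessions, expression, variable,
                    include_screening = include_screening)
  e <- pr$expression
  if (log_transform) e <- log2(e + 1)
  x <- pr$x
  e <- e[, !is.na(x), drop = FALSE]
  x <- x[!is.na(x)]
  n <- rowSums(!is.na(e))
  rho <- suppressWarnings(
    as.vector(stats::cor(t(e), x, use = "pairwise.complete.obs"))
  )
  sd_gene <- apply(e, 1, stats::sd, na.rm = TRUE)
  bad <- n < 4L | is.na(sd_gene) | sd_gene == 0 | stats::sd(x) == 0 |
    is.na(rho)
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = pmax(n - 2, 1))
  p[bad] <- NA_real_
  rho[bad] <- NA_real_
  res <- tibble::tibble(gene = rownames(e), rho = unname(rho),
                        p_value = unname(p), n = as.integer(unname(n)))
  skipped <- sum(is.na(res$p_value))
  if (skipped > 0) {
    warning(skipped, " gene(s) skipped (zero variance or too few pairs)")
  }
  res <- dplyr::filter(res, !is.na(.data$p_value))
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$fdr < alpha
  res <- dplyr::arrange(res, .data$p_value)
  attr(res, "n_skipped") <- skipped
  res
}

#' Pathway enrichment of a significant gene set
#'
#' One-sided Fisher exact test of over-representation of each pathway among
#' the significant genes, against a background gene universe (default: all
#' genes tested). For each pathway the 2x2 table counts
#' significant/non-significant genes inside and outside the pathway over the
#' background; the odds ratio is computed from the raw table, with a Haldane
#' 0.5 correction applied to all cells when any cell is zero. P-values are
#' BH-adjusted across pathways. Pathways empty after intersection with the
#' background are skipped.
#'
#' @param significant_genes Character vector of significant gene symbols.
#' @param pathways Named list of gene sets ([read_pathways()]).
#' @param background Character vector of all genes tested (must contain
#'   `significant_genes`).
#' @return Tibble sorted by p-value: `pathway`, `odds_ratio`, `p_value`,
#'   `fdr`, `pathway_size`, `shared_size`.
#' @export
pathway_enrichment <- function(significant_genes, pathways, background) {
  if (!all(significant_genes %in% background)) {
    stop("background must contain all significant genes")
  }
  background <- unique(background)
  sig <- unique(significant_genes)
  rows <- purrr::map_dfr(names(pathways), function(nm) {
    pw <- intersect(pathways[[nm]], background)
    if (length(pw) == 0) return(NULL)
    a <- length(intersect(pw, sig))               # in pathway, significant
    b <- length(sig) - a                          # out of pathway, significant
    c_ <- length(pw) - a                          # in pathway, not significant
    d <- length(background) - a - b - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2),
                            alternative = "greater")$p.value
    cells <- c(a, b, c_, d)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    tibble::tibble(pathway = nm, odds_ratio = or, p_value = p,
                   pathway_size = length(pw), shared_size = a)
  })
  if (nrow(rows) == 0) return(rows)
  rows$fdr <- stats::p.adjust(rows$p_value, method = "BH")
  rows <- dplyr::arrange(rows, .data$p_value)
  rows[, c("pathway", "odds_ratio", "p_value", "fdr", "pathway_size",
           "shared_size")]
}
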