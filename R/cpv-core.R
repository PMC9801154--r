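#' Successive-difference variability index
#'
#' Computes the normalized variability index `T` of an ordered series of
#' repeated cognitive-test scores. With successive differences
#' `d(m) = x(m) - x(m-1)`, the index contrasts the raw second moment of the
#' differences (`sigma0_sq`, the null-hypothesis variance estimate assuming no
#' mean change between sessions) with their centered second moment
#' (`sigma1_sq`, the alternative estimate):
#' \deqn{T = \sigma_0^2 / (\sigma_0^2 + \sigma_1^2)}
#' where \eqn{\sigma_0^2 = (N-1)^{-1}\sum d(m)^2} and
#' \eqn{\sigma_1^2 = (N-2)^{-1}\sum (d(m) - \bar d)^2}. `T` lies in `[0, 1]`
#' and grows with the magnitude of the mean successive difference relative to
#' its dispersion, so it rewards consistent drift across sessions rather than
#' mere scatter. It is invariant to affine transforms of the series.
#'
#' Missing values are removed before differencing, so differences are formed
#' between consecutive retained sessions and `N` is the retained count.
#'
#' @param x Numeric vector of session values in time order. `NA`s are dropped.
#' @return A list with elements `T`, `sigma0_sq`, `sigma1_sq`, `mean_diff`,
#'   `n_used`, and `status` (one of `"ok"`, `"constant"` — all differences
#'   zero, `T` undefined (0/0) — or `"insufficient"` — fewer than 3 retained
#'   sessions).
#' @seealso [cpv_univariate()] for the -log p transform.
#' @export
#' @examples
#' variability_index(c(0, 1, 0, 1, 0))$T  # 3/7
variability_index <- function(x) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  n <- length(x)
  out <- list(T = NA_real_, sigma0_sq = NA_real_, sigma1_sq = NA_real_,
              mean_diff = NA_real_, n_used = n, status = "insufficient")
  if (n < 3L) {
    return(out)
  }
  d <- diff(x)
  mean_diff <- mean(d)
  ss0 <- sum(d^2)
  ss1 <- sum((d - mean_diff)^2)
  out$sigma0_sq <- ss0 / (n - 1)
  out$sigma1_sq <- ss1 / (n - 2)
  out$mean_diff <- mean_diff
  num <- (n - 2) * ss0
  den <- num + (n - 1) * ss1
  if (den <= 0) {
    out$status <- "constant"
    return(out)
  }
  out$T <- num / den
  out$status <- "ok"
  out
}

#' Cap applied to univariate CPV scores at the T = 1 boundary
#'
#' A perfect ramp (zero residual variance around the mean difference) drives
#' `T` to 1 and the upper-tail beta probability to zero, so the -log p score
#' diverges. Scores are capped at minus the log of the smallest positive
#' normalized double so that downstream correlations stay finite; capped
#' scores carry a flag.
#'
#' @return A positive scalar, about 708.4.
#' @export
cpv_cap <- function() -log(.Machine$double.xmin)

#' Univariate cognitive performance variability (CPV) score
#'
#' Transforms the variability index `T` of one series into a -log p score
#' against a Beta reference distribution:
#' \deqn{CPV = -\log\{1 - I_T(a, b)\}}
#' where \eqn{I} is the regularized incomplete beta function with shape
#' parameters `a = (N-1)/2`, `b = (N-2)/2` (the operational definition;
#' `shape = "unhalved"` uses `a = N-1`, `b = N-2` instead). Natural logarithm
#' throughout. A constant series scores 0 (zero variability is the floor);
#' `T = 1` is capped at [cpv_cap()].
#'
#' The Beta reference treats the two variance estimates as independent
#' chi-square variates; they are not (the raw sum of squares contains the
#' centered one), so the reference is approximate. See [cpv_exact_pvalue()]
#' for the exact null tail probability of `T` under i.i.d. Gaussian
#' differences, and the package vignette for the comparison.
#'
#' @inheritParams variability_index
#' @param shape `"halved"` (default) for Beta((N-1)/2, (N-2)/2) or
#'   `"unhalved"` for Beta(N-1, N-2).
#' @param cap Upper bound applied to the score, default [cpv_cap()].
#' @return A list with the [variability_index()] fields plus `cpv` (the
#'   score, `NA` when `status == "insufficient"`) and `capped` (logical).
#' @export
#' @examples
#' cpv_univariate(c(0, 1, 0, 1, 0))$cpv  # about 0.343
cpv_univariate <- function(x, shape = c("halved", "unhalved"), cap = cpv_cap()) {
  shape <- match.arg(shape)
  res <- variability_index(x)
  res$cpv <- NA_real_
  res$capped <- FALSE
  if (res$status == "insufficient") {
    return(res)
  }
  if (res$status == "constant") {
    res$cpv <- 0
    return(res)
  }
  n <- res$n_used
  ab <- if (shape == "halved") c((n - 1) / 2, (n - 2) / 2) else c(n - 1, n - 2)
  # -log of the upper tail, computed on the log scale for accuracy near T = 1
  cpv <- -stats::pbeta(res$T, ab[1], ab[2], lower.tail = FALSE, log.p = TRUE)
  if (!is.finite(cpv) || cpv > cap) {
    res$cpv <- cap
    res$capped <- TRUE
  } else {
    res$cpv <- cpv
  }
  res
}

#' Exact null tail probability of the variability index
#'
#' Under the null of i.i.d. Gaussian successive differences, the index can be
#' written `T = (n-1) / (2n-1 - nB)` with `n = N-1` differences and
#' `B = n dbar^2 / sum(d^2) ~ Beta(1/2, (n-1)/2)`, because the mean of the
#' differences is independent of their centered sum of squares. This gives the
#' exact upper-tail probability `P(T >= t)`, which differs from the nominal
#' Beta((N-1)/2, (N-2)/2) reference used by [cpv_univariate()]; `T` is
#' supported on `[(n-1)/(2n-1), 1]` and is far more concentrated than the
#' nominal reference.
#'
#' @param t Observed index value(s) in `[0, 1]`.
#' @param n_used Number of retained sessions `N` (so `n = N - 1` differences).
#' @return `P(T >= t)` under the exact null, vectorized over `t`.
#' @export
cpv_exact_pvalue <- function(t, n_used) {
  stopifnot(n_used >= 3)
  n <- n_used - 1
  # invert t = (n-1)/(2n-1 - n b)  =>  b = (2n-1 - (n-1)/t)/n
  b <- (2 * n - 1 - (n - 1) / t) / n
  p <- stats::pbeta(pmin(pmax(b, 0), 1), 0.5, (n - 1) / 2, lower.tail = FALSE)
  p[t <= (n - 1) / (2 * n - 1)] <- 1
  p
}

#' One-way ANOVA p-value on the consecutive-pair matrix
#'
#' Verification oracle for the CPV transform: arranges the series into the
#' 2-row matrix whose m-th column is the pair (x(m), x(m+1)) and returns the
#' one-way ANOVA p-value treating columns as groups. Used to probe the claimed
#' equivalence between `exp(-cpv)` and standard ANOVA software output; the
#' package's tests record the observed discrepancy rather than assuming
#' agreement.
#'
#' @inheritParams variability_index
#' @return The ANOVA p-value, or `NA` if fewer than 3 sessions remain or the
#'   series is constant (zero total variance).
#' @export
anova_oracle <- function(x) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) {
    return(NA_real_)
  }
  if (stats::var(x) == 0) {
    return(NA_real_)
  }
  v <- c(rbind(x[-n], x[-1]))
  g <- factor(rep(seq_len(n - 1), each = 2))
  fit <- stats::oneway.test(v ~ g, var.equal = TRUE)
  unname(fit$p.value)
}
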