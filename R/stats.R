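#' Jarque-Bera normality test
#'
#' Moment-based omnibus normality test:
#' `JB = n/6 * (S^2 + (K - 3)^2 / 4)` with `S` the sample skewness and
#' `K` the sample kurtosis, both from biased (moment) estimators, and
#' the p-value from the upper tail of a chi-squared distribution with
#' two degrees of freedom.
#'
#' @param x numeric sample of at least 8 observations.
#' @return list with `statistic`, `p`, `skewness`, `kurtosis`, `n`.
#' @examples
#' jarque_bera(rep(c(-1, 1), 15))  # JB = 5, p ~ 0.082
#' @export
jarque_bera <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("Jarque-Bera needs at least 8 observations", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 < .Machine$double.eps) {
    stop("degenerate sample: zero variance", call. = FALSE)
  }
  S <- mean((x - m)^3) / m2^1.5
  K <- mean((x - m)^4) / m2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(statistic = jb, p = pchisq(jb, df = 2, lower.tail = FALSE),
       skewness = S, kurtosis = K, n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA`s pass
#'   through).
#' @return adjusted p-values, each at least the raw value, capped at 1.
#' @export
fdr_correct <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]",
                                       call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Normality-gated two-group comparison
#'
#' Compares two samples with a two-tailed Student t-test when both pass
#' the Jarque-Bera normality gate at `alpha_normality`, and a two-tailed
#' Mann-Whitney U-test otherwise.  Samples too small for the normality
#' test (n < 8) are treated as non-normal.  For `paired = TRUE` the
#' gate is applied to the paired differences and the branches are the
#' paired t-test and the Wilcoxon signed-rank test.
#'
#' The Mann-Whitney branch uses the exact null distribution when
#' `n_a * n_b <= 400` and the samples are tie-free, and the
#' tie-corrected normal approximation otherwise.
#'
#' @param a,b numeric samples (at least 3 observations each).
#' @param alpha_normality gate level for the Jarque-Bera p-value
#'   (default 0.05).
#' @param paired treat `a` and `b` as paired observations.
#' @param welch use the Welch t-test instead of the pooled-variance
#'   Student t-test.
#' @param force_test override the gate with `"t"` or `"mann_whitney"`.
#' @return list: `test_used`, `statistic`, `p`, `direction`
#'   (sign of `mean(a) - mean(b)`), `jb_p_a`, `jb_p_b`, `n_a`, `n_b`,
#'   `paired`.
#' @export
compare_groups <- function(a, b, alpha_normality = 0.05, paired = FALSE,
                           welch = FALSE, force_test = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3) {
    stop("each sample needs at least 3 observations", call. = FALSE)
  }
  if (paired && length(a) != length(b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  direction <- sign(mean(a) - mean(b))

  jb_safe <- function(x) {
    if (length(x) < 8) return(NA_real_)
    if (var(x) < .Machine$double.eps) return(0)  # fails the gate
    jarque_bera(x)$p
  }
  if (paired) {
    d <- a - b
    jb_a <- jb_safe(d); jb_b <- jb_a
  } else {
    jb_a <- jb_safe(a); jb_b <- jb_safe(b)
  }
  normal <- !is.na(jb_a) && !is.na(jb_b) &&
    jb_a > alpha_normality && jb_b > alpha_normality
  test_used <- if (!is.null(force_test)) {
    match.arg(force_test, c("t", "mann_whitney"))
  } else if (normal) "t" else "mann_whitney"

  pooled <- if (paired) a - b else c(a, b)
  if (var(pooled) < .Machine$double.eps) {
    gc_log("all observations identical; p = 1 by convention")
    return(list(test_used = test_used, statistic = 0, p = 1,
                direction = 0, jb_p_a = jb_a, jb_p_b = jb_b,
                n_a = length(a), n_b = length(b), paired = paired))
  }

  if (test_used == "t") {
    fit <- t.test(a, b, paired = paired, var.equal = !welch && !paired)
    stat <- unname(fit$statistic); p <- fit$p.value
  } else if (paired) {
    d <- a - b
    ties <- anyDuplicated(abs(d[d != 0])) > 0 || any(d == 0)
    fit <- suppressWarnings(
      wilcox.test(a, b, paired = TRUE, exact = !ties && length(d) <= 50,
                  correct = TRUE))
    stat <- unname(fit$statistic); p <- fit$p.value
  } else {
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- !ties && length(a) * length(b) <= 400
    fit <- suppressWarnings(
      wilcox.test(a, b, exact = exact, correct = TRUE))
    stat <- unname(fit$statistic); p <- fit$p.value
  }
  list(test_used = test_used, statistic = stat, p = p,
       direction = direction, jb_p_a = jb_a, jb_p_b = jb_b,
       n_a = length(a), n_b = length(b), paired = paired)
}
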