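#' Exact and asymptotic statistical primitives
#'
#' Thin, contract-hardened wrappers around the standard tests used throughout
#' the pipeline (Fisher's exact test, exact binomial test, Wilcoxon rank-sum,
#' Kruskal-Wallis, Welch t, Benjamini-Hochberg), plus a hand-rolled
#' Cochran-Mantel-Haenszel statistic whose continuity correction is floored at
#' zero so that strata with identical proportions give p = 1 exactly.
#'
#' All two-sided exact tests use the point-probability convention (sum of
#' outcome probabilities no larger than the observed one), matching base R.
#'
#' @name stats_core
NULL

#' Fisher's exact test on a 2x2 table
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value (point-probability method). Degenerate margins
#'   (a zero row or column) give p = 1.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Exact two-sided binomial test
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param p0 Null success probability.
#' @return Two-sided p-value by the point-probability method.
#' @export
binomial_exact_two_sided <- function(k, n, p0 = 0.5) {
  stopifnot(n > 0, k >= 0, k <= n)
  stats::binom.test(k, n, p = p0)$p.value
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact permutation p when the combined sample size is at most `exact_max`
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. Samples with zero rank variance (all values tied
#' across both groups) give p = 1.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_max Largest combined n for the exact branch.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 20) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && length(x) + length(y) <= exact_max) {
    return(stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # normal approximation; guard the all-tied degenerate case
  r <- rank(c(x, y))
  if (stats::var(r) == 0) return(1)
  suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
}

#' Wilcoxon rank-sum test on binned (grouped) data
#'
#' Equivalent to [wilcoxon_rank_sum()] on samples where every observation in
#' bin b carries the value of bin b, but computed directly from per-bin counts
#' (normal approximation with tie and continuity corrections). Used for
#' read-level comparisons where each sequencing read contributes its FACS
#' bin's fluorescence value, so counts are large and ties are total.
#'
#' @param x_counts,y_counts Integer count vectors over the same ordered bins.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum_counts <- function(x_counts, y_counts) {
  stopifnot(length(x_counts) == length(y_counts), all(x_counts >= 0), all(y_counts >= 0))
  m <- sum(x_counts)
  n <- sum(y_counts)
  if (m == 0 || n == 0) stop("both samples must be non-empty")
  tot <- x_counts + y_counts
  N <- m + n
  # midranks of each bin
  cum <- cumsum(tot)
  midrank <- cum - (tot - 1) / 2
  W <- sum(x_counts * midrank)          # rank sum of x
  mu <- m * (N + 1) / 2
  tie_term <- sum(tot^3 - tot)
  sigma2 <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- W - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' Kruskal-Wallis test
#'
#' @param groups List of numeric vectors (>= 2 groups). All-identical values
#'   give p = 1.
#' @return p-value from the tie-corrected H statistic (chi-square, k-1 df).
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1) return(1)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  stats::kruskal.test(vals, g)$p.value
}

#' Cochran-Mantel-Haenszel test over K 2x2 strata
#'
#' Continuity-corrected CMH statistic: ((|sum(a - E)| - 0.5)_+)^2 / sum(V),
#' with E and V the conditional hypergeometric mean and variance of the
#' top-left cell in each stratum. The correction is floored at zero, so strata
#' with identical group proportions give a zero statistic and p = 1. Strata
#' with a zero margin carry no information and are dropped with a warning.
#'
#' @param strata List of 2x2 count matrices, or a 2x2xK array.
#' @param correct Apply the continuity correction (default TRUE).
#' @return Two-sided p-value (chi-square, 1 df).
#' @export
cmh_2x2xk <- function(strata, correct = TRUE) {
  if (is.array(strata) && length(dim(strata)) == 3) {
    strata <- lapply(seq_len(dim(strata)[3]), function(k) strata[, , k])
  }
  stopifnot(length(strata) >= 1)
  dev <- 0; vsum <- 0; used <- 0L
  for (tab in strata) {
    tab <- as.matrix(tab)
    stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
    n <- sum(tab)
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
    c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
    if (n < 2 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
      warning("dropping degenerate stratum with a zero margin")
      next
    }
    dev <- dev + tab[1, 1] - r1 * c1 / n
    vsum <- vsum + r1 * r2 * c1 * c2 / (n^2 * (n - 1))
    used <- used + 1L
  }
  if (used == 0L || vsum == 0) return(1)
  adj <- if (correct) max(0, abs(dev) - 0.5) else abs(dev)
  stat <- adj^2 / vsum
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p Vector of p-values in [0, 1]; NA entries are passed through.
#' @return Step-up adjusted values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Welch two-sample t-test
#'
#' @param x,y Numeric samples with n >= 2 each. If both samples are constant
#'   with equal means the test is undefined and p = 1 is returned; constant
#'   samples with different means give p = 0.
#' @return Two-sided p-value.
#' @export
welch_t_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}
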