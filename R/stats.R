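# Shared statistical primitives: Mann-Whitney U, Benjamini-Hochberg FDR,
# hypergeometric upper tail.

#' Mann-Whitney U test
#'
#' Rank-based two-sample location test. The exact null distribution is
#' enumerated when the pooled sample is small (n1 + n2 <= 12) and tie-free;
#' otherwise the normal approximation with midrank tie correction and
#' continuity correction is used. Computation is delegated to
#' \code{stats::wilcox.test}; the reported statistic is the U of \code{x}.
#'
#' @param x,y numeric samples (each non-empty).
#' @param alternative \code{"two.sided"}, \code{"greater"} or \code{"less"}.
#' @return list with \code{statistic} (U), \code{p}, \code{method}
#'   (\code{"exact"} or \code{"normal-approx"}), \code{n1}, \code{n2}.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  .assert(length(x) >= 1 && length(y) >= 1, "both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 + n2 <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = min(1, wt$p.value),
       method = if (exact) "exact" else "normal-approx", n1 = n1, n2 = n2)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvals numeric p-values, each in (0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  .assert(all(is.finite(pvals)) && all(pvals > 0) && all(pvals <= 1),
          "all p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X hypergeometric with population size \code{N}, \code{K}
#' successes, and \code{n} draws.
#'
#' @param k observed successes in the draw (0 <= k <= min(K, n)).
#' @param N population size.
#' @param K successes in the population.
#' @param n draws.
#' @return the exact upper-tail probability.
#' @export
hypergeom_tail <- function(k, N, K, n) {
  .assert(K <= N && n <= N, "margins must satisfy K <= N and n <= N")
  .assert(k >= 0 && k <= min(K, n), "need 0 <= k <= min(K, n)")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}
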