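#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment. A thin validating wrapper
#' around [stats::p.adjust()] used by every thresholding and enrichment
#' stage of the pipeline, so that all of them share one set of input
#' checks and one definition.
#'
#' @param p Numeric vector of raw p-values, all in \[0, 1\].
#' @return Numeric vector of BH-adjusted p-values, same length and names
#'   as `p`. Adjusted values are capped at 1 and never smaller than the
#'   raw value; the rank order of `p` is preserved (ties allowed).
#' @examples
#' bh_adjust(c(0.005, 0.5))   # 0.01 0.50
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) stop("'p' must be non-empty")
  if (!is.numeric(p)) stop("'p' must be numeric")
  bad <- which(is.na(p) | p < 0 | p > 1)
  if (length(bad) > 0L) {
    stop(sprintf("p-value out of [0, 1] at index %d (value: %s)",
                 bad[1L], format(p[bad[1L]])))
  }
  stats::p.adjust(p, method = "BH")
}

# Coerce a 2x2 contingency table given as c(a, b, c, d) or a 2x2 matrix.
# Layout: row 1 = in query set, row 2 = not; col 1 = has property, col 2 = not.
as_table2x2 <- function(x) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L))) stop("contingency table must be 2x2")
    x <- c(x[1, 1], x[1, 2], x[2, 1], x[2, 2])
  }
  if (length(x) != 4L || !is.numeric(x)) {
    stop("contingency table must be 4 counts (a, b, c, d) or a 2x2 matrix")
  }
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("contingency table cells must be non-negative integers")
  }
  if (sum(x) < 1) stop("contingency table is empty (all cells zero)")
  as.numeric(x)
}

#' Odds ratio of a 2x2 table with zero-cell handling
#'
#' Computes (a*d)/(b*c) for the table `(a, b, c, d)` laid out as row 1 =
#' "in set", row 2 = "not in set", column 1 = "labelled positive",
#' column 2 = "labelled negative". Because the set optimizer must compare
#' finite objective values, the default policy applies the Haldane
#' correction: when any cell is zero, 0.5 is added to every cell before
#' computing the ratio.
#'
#' @param x Counts `c(a, b, c, d)` or a 2x2 matrix.
#' @param zero_cell `"haldane"` (default) adds 0.5 to all four cells
#'   whenever any cell is 0; `"none"` returns `Inf`, `0` or `NaN` as the
#'   arithmetic dictates.
#' @return A single non-negative number (possibly `Inf` under `"none"`).
#' @examples
#' odds_ratio_2x2(c(20, 5, 10, 40))              # 16
#' odds_ratio_2x2(c(5, 0, 10, 10))               # haldane: 11
#' @export
odds_ratio_2x2 <- function(x, zero_cell = c("haldane", "none")) {
  zero_cell <- match.arg(zero_cell)
  t <- as_table2x2(x)
  if (zero_cell == "haldane" && any(t == 0)) t <- t + 0.5
  (t[1L] * t[4L]) / (t[2L] * t[3L])
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with fixed margins. The two-sided p-value
#' uses the point-probability ("minlike") rule: it sums the probabilities
#' of all tables with the observed margins whose point probability does
#' not exceed that of the observed table (the same convention as
#' [stats::fisher.test()]); `"greater"` sums the upper tail over
#' `a >= observed`. Implemented directly on [stats::dhyper()] /
#' [stats::phyper()] so that the many thousands of tables tested by the
#' enrichment and pairwise stages are cheap.
#'
#' @param x Counts `c(a, b, c, d)` or a 2x2 matrix (see
#'   [odds_ratio_2x2()] for the layout).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return The exact p-value.
#' @examples
#' fisher_exact_2x2(c(2, 0, 0, 2))                    # 1/3
#' fisher_exact_2x2(c(8, 2, 1, 9), "greater")
#' @export
fisher_exact_2x2 <- function(x, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  t <- as_table2x2(x)
  a <- t[1L]; b <- t[2L]; cc <- t[3L]; d <- t[4L]
  m <- a + b          # size of row 1
  n <- cc + d         # size of row 2
  k <- a + cc         # column-1 margin
  if (alternative == "greater") {
    return(stats::phyper(a - 1, m, n, k, lower.tail = FALSE))
  }
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(a, m, n, k)
  # relative tolerance guards against ties broken only by rounding
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Empirical p-value from a resampled null distribution
#'
#' Rank of an observed statistic within null samples, upper tail. Null
#' values equal to the observed statistic count as at least as extreme.
#'
#' @param observed Observed statistic (single number).
#' @param null_samples Numeric vector of statistics under the null.
#' @param correction `"plus_one"` (default) returns `(r + 1) / (N + 1)`
#'   where `r` is the number of null samples `>= observed`, a valid
#'   p-value that can never be zero; `"raw"` returns `r / N`, the literal
#'   exceedance fraction.
#' @return A probability; in `(0, 1]` under `"plus_one"`.
#' @examples
#' empirical_pvalue(5, c(1, 2, 3))          # (0 + 1) / (3 + 1) = 0.25
#' empirical_pvalue(1, c(1, 2, 3), "raw")   # ties count: 3/3 = 1
#' @export
empirical_pvalue <- function(observed, null_samples,
                             correction = c("plus_one", "raw")) {
  correction <- match.arg(correction)
  if (length(observed) != 1L || !is.finite(observed)) {
    stop("'observed' must be a single finite number")
  }
  if (length(null_samples) == 0L) stop("'null_samples' must be non-empty")
  r <- sum(null_samples >= observed)
  n <- length(null_samples)
  if (correction == "plus_one") (r + 1) / (n + 1) else r / n
}
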