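#' Chi-square test comparing two response frequencies
#'
#' Pearson chi-square on the 2x2 success/failure table, without continuity
#' correction (arms of ~2,000 make the correction immaterial).
#'
#' @param a_success,a_n Successes and total in arm A.
#' @param b_success,b_n Successes and total in arm B.
#' @return List with `statistic`, `p.value`, `df`.
#' @examples
#' chi_square_frequency_test(930, 2000, 640, 2000)
#' @export
chi_square_frequency_test <- function(a_success, a_n, b_success, b_n) {
  stopifnot(a_success <= a_n, b_success <= b_n,
            a_success >= 0, b_success >= 0)
  tab <- rbind(c(a_success, a_n - a_success),
               c(b_success, b_n - b_success))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    stop("degenerate 2x2 table (zero margin)")
  # small-count approximation warnings are irrelevant at the population
  # sizes used here; the statistic itself is exact Pearson
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p.value = ct$p.value,
       df = unname(ct$parameter))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` and `p.value`.
#' @export
rank_sum_test <- function(x, y) {
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment preserving the input order.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}
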