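#' Fisher's exact test p-value for two read-count measurements
#'
#' Tests the null hypothesis that two samples carry the same underlying
#' variant allele frequency, using the 2x2 table of mutant and wildtype read
#' counts `[[mutant1, total1 - mutant1], [mutant2, total2 - mutant2]]`.
#' This is the statistic behind the mutation-specific negative (MSN) rule:
#' rejecting it against a positive sample shows the candidate-negative sample
#' is genuinely depleted of mutant reads rather than merely under-covered.
#'
#' The two-sided p-value is the sum of the probabilities of every
#' hypergeometric table (with the observed margins) whose probability does not
#' exceed that of the observed table; probabilities within a relative 1e-7 of
#' the observed one count as ties, the usual convention for this statistic.
#' The one-sided p-value is the lower tail for the sample with the smaller
#' VAF — for the zero-mutant candidate-negative sample this is the chance of
#' drawing no mutant reads at its coverage. When both samples have the same
#' VAF the larger of the two lower tails is returned, keeping the function
#' symmetric in its arguments. If either sample has zero coverage the test
#' carries no information and the p-value is 1.
#'
#' All four count arguments recycle to a common length.
#'
#' @param mutant1,total1 mutant and total read counts of the first sample.
#' @param mutant2,total2 mutant and total read counts of the second sample.
#' @param sidedness `"two-sided"` (default) or `"one-sided"`.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
#' @examples
#' fisher_exact_p(0, 20, 10, 20)           # deeply covered zero vs 50% VAF
#' fisher_exact_p(0, 8, 4, 9)              # shallow zero vs 44% VAF: no signal
#' fisher_exact_p(0, 15, 40, 72, "one-sided")
fisher_exact_p <- function(mutant1, total1, mutant2, total2,
                           sidedness = c("two-sided", "one-sided")) {
  sidedness <- match.arg(sidedness)
  n <- max(length(mutant1), length(total1), length(mutant2), length(total2))
  m1 <- rep_len(as.numeric(mutant1), n)
  t1 <- rep_len(as.numeric(total1), n)
  m2 <- rep_len(as.numeric(mutant2), n)
  t2 <- rep_len(as.numeric(total2), n)
  bad <- is.na(m1) | is.na(t1) | is.na(m2) | is.na(t2) |
    m1 < 0 | m2 < 0 | m1 > t1 | m2 > t2
  if (any(bad)) {
    stop("read counts must satisfy 0 <= mutant <= total", call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    fisher_p_scalar(m1[i], t1[i], m2[i], t2[i], sidedness)
  }, numeric(1))
}

fisher_p_scalar <- function(m1, t1, m2, t2, sidedness) {
  if (t1 == 0 || t2 == 0) return(1)
  k <- m1 + m2          # mutant-column margin
  nn <- t1 + t2         # grand total
  if (sidedness == "two-sided") {
    # enumerate the full support of mutant reads falling in sample 1
    support <- max(0, k - t2):min(k, t1)
    probs <- stats::dhyper(support, k, nn - k, t1)
    p0 <- stats::dhyper(m1, k, nn - k, t1)
    p <- sum(probs[probs <= p0 * (1 + 1e-7)])
  } else {
    v1 <- m1 / t1
    v2 <- m2 / t2
    lower1 <- stats::phyper(m1, k, nn - k, t1)
    lower2 <- stats::phyper(m2, k, nn - k, t2)
    p <- if (v1 < v2) lower1 else if (v2 < v1) lower2 else max(lower1, lower2)
  }
  min(p, 1)
}
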