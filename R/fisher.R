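# Two-sided Fisher exact test for 2 x 2 tables by direct hypergeometric
# enumeration.  Implemented in-package because the haplotype scan evaluates
# tens of thousands of candidate tables; the per-call overhead of a generic
# test function dominates at that scale.  Equality with brute-force tail
# summation (and with stats::fisher.test) is exercised in the test suite.

#' Two-sided Fisher exact p for 2 x 2 tables
#'
#' Conditional on both margins, sums the hypergeometric probabilities of all
#' tables no more probable than the observed one (the standard two-sided
#' definition, with the customary (1 + 1e-7) relative tolerance for
#' floating-point ties).
#'
#' @param a,b,c,d Cell counts (vectorised): the table is
#'   \code{rbind(c(a, b), c(c, d))}.
#' @return Numeric vector of p-values.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]   # row 1 total
    m2 <- c[i] + d[i]   # row 2 total
    k <- a[i] + c[i]    # column 1 total
    if (m1 + m2 == 0) { p[i] <- 1; next }
    lo <- max(0, k - m2)
    hi <- min(k, m1)
    dens <- stats::dhyper(lo:hi, m1, m2, k)
    obs <- dens[a[i] - lo + 1L]
    p[i] <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }
  p
}
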