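#' Vectorized Fisher's exact test for 2x2 tables
#'
#' Exact hypergeometric p-values for a vector of 2x2 contingency tables
#' `[a, b; c, d]`, where rows are the two groups and columns the two
#' outcomes (e.g. methylated / unmethylated read counts pooled per group).
#'
#' One-sided p-values are hypergeometric tail sums on the `a` cell
#' (`"greater"`: enrichment of the first outcome in the first row).
#' The two-sided p-value is the minimum-likelihood definition: the sum of
#' probabilities of all tables (with the same margins) no more likely than
#' the observed one, using a `1 + 1e-7` relative guard against floating-point
#' ties — the same convention as [stats::fisher.test()], which therefore
#' agrees to near machine precision and serves as an independent cross-check.
#'
#' @param a,b,c,d Non-negative integer vectors (recycled to a common length)
#'   giving the table cells.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_test_2x2(10, 90, 45, 55)          # two-sided
#' fisher_test_2x2(8, 2, 20, 80, "greater") # one-sided enrichment
#' @export
fisher_test_2x2 <- function(a, b, c, d,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  if (any(c(a, b, c, d) < 0) || anyNA(c(a, b, c, d))) {
    abort("all table cells must be non-negative and non-missing")
  }
  m <- a + c  # first-column margin
  n <- b + d  # second-column margin
  k <- a + b  # first-row margin
  if (alternative == "greater") {
    return(pmin(1, phyper(a - 1, m, n, k, lower.tail = FALSE)))
  }
  if (alternative == "less") {
    return(pmin(1, phyper(a, m, n, k)))
  }
  two_sided_minlike(a, m, n, k)
}

# minimum-likelihood two-sided p, chunked flat expansion over the support
two_sided_minlike <- function(a, m, n, k, chunk = 50000L) {
  len <- length(a)
  out <- numeric(len)
  d_obs <- dhyper(a, m, n, k)
  lo <- pmax(0, k - n)
  hi <- pmin(k, m)
  idx_start <- 1L
  while (idx_start <= len) {
    idx <- idx_start:min(len, idx_start + chunk - 1L)
    ns <- hi[idx] - lo[idx] + 1
    tab <- rep(idx, ns)
    x <- sequence(ns) - 1 + rep(lo[idx], ns)
    dx <- dhyper(x, m[tab], n[tab], k[tab])
    keep <- dx <= d_obs[tab] * (1 + 1e-7)
    out[idx] <- rowsum(dx * keep, tab)[, 1]
    idx_start <- idx_start + chunk
  }
  pmin(1, out)
}

#' Odds ratio for a 2x2 table with Haldane-Anscombe correction
#'
#' Sample odds ratio `(a*d)/(b*c)`; when any cell is zero, 0.5 is added to
#' every cell so the ratio stays finite and non-zero.
#'
#' @inheritParams fisher_test_2x2
#' @return Numeric vector of odds ratios.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
  c[zero] <- c[zero] + 0.5; d[zero] <- d[zero] + 0.5
  (a * d) / (b * c)
}
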