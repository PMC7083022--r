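#' Hardy-Weinberg equilibrium tests
#'
#' Tests agreement of observed genotype counts with Hardy-Weinberg
#' proportions by both the 1-df Pearson chi-square (no continuity correction
#' by default; Yates available) and the exact conditional test on the number
#' of heterozygotes given the allele counts. Monomorphic input returns p = 1
#' for both tests with a warning, so marker loops need not abort.
#'
#' @param g [genotype_counts()] (or length-3 vector: ref-hom, het, alt-hom).
#' @param yates Apply the Yates continuity correction to the chi-square
#'   statistic? Default `FALSE`.
#' @return Object of class `hwe_test`: observed counts, `allele_freq`
#'   (reference-allele frequency), `expected` counts, `chi2`, `df`, `p_chi2`
#'   and `p_exact`.
#' @examples
#' hwe_test(c(53, 60, 22))
#' @export
hwe_test <- function(g, yates = FALSE) {
  g <- as_genotype_counts(g)
  n <- sum(g)
  n_ref <- 2L * g[[1]] + g[[2]]
  n_alt <- 2L * g[[3]] + g[[2]]
  p <- n_ref / (2 * n)
  if (n_ref == 0L || n_alt == 0L) {
    warning("monomorphic marker: HWE p-values set to 1")
    return(structure(list(counts = g, n = n, allele_freq = p,
                          expected = as.numeric(g), chi2 = 0, df = 1,
                          p_chi2 = 1, p_exact = 1, yates = yates),
                     class = "hwe_test"))
  }
  q <- 1 - p
  e <- n * c(p^2, 2 * p * q, q^2)
  dev <- abs(as.numeric(g) - e)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / e)
  structure(list(counts = g, n = n, allele_freq = p, expected = e,
                 chi2 = chi2, df = 1,
                 p_chi2 = stats::pchisq(chi2, 1, lower.tail = FALSE),
                 p_exact = hwe_exact_p(n, n_ref, g[[2]]),
                 yates = yates),
            class = "hwe_test")
}

# Exact conditional test: distribution of the heterozygote count given the
# allele counts; p sums the probabilities of all configurations no more
# probable than the observed one.
hwe_exact_p <- function(n, n_ref, het_obs) {
  n_min <- min(n_ref, 2L * n - n_ref)
  hets <- seq.int(n_min %% 2L, n_min, by = 2L)
  lp <- hets * log(2) - lfactorial((n_min - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (n_min + hets) / 2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(het_obs, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf(
    "Hardy-Weinberg test (n = %d, ref-allele freq %.3f)\n  chi-square%s = %.4g (1 df), p = %.3g; exact p = %.3g\n",
    x$n, x$allele_freq, if (x$yates) " (Yates)" else "",
    x$chi2, x$p_chi2, x$p_exact))
  invisible(x)
}
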