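#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood estimation of the four two-locus haplotype frequencies
#' from unphased genotype counts. For two biallelic loci only the double
#' heterozygote is phase-ambiguous: every other joint-genotype cell resolves
#' deterministically into gametes, and the E-step splits the double
#' heterozygotes between the cis (ref-ref / alt-alt) and trans
#' (ref-alt / alt-ref) configurations in proportion to their current
#' expected frequencies. Initialisation is at linkage equilibrium (products
#' of the observed allele frequencies); the log-likelihood is
#' non-decreasing across iterations.
#'
#' @param joint 3x3 matrix of subject counts, rows = alt-allele dosage at
#'   locus A (0, 1, 2), columns = dosage at locus B.
#' @param tol Convergence tolerance on the maximum absolute frequency change
#'   (default 1e-10).
#' @param max_iter Maximum EM iterations (default 1000); non-convergence
#'   returns the current estimate with `converged = FALSE` and a warning.
#' @return Object of class `hap_em`: `freqs` (named frequencies of the
#'   haplotypes ref-ref, ref-alt, alt-ref, alt-alt), `loglik`, `iterations`,
#'   `converged`, `n` (subjects).
#' @examples
#' sim <- simulate_two_locus(c(0.4, 0.3, 0.2, 0.1), n = 500, seed = 1)
#' em_two_snp(sim$joint)
#' @export
em_two_snp <- function(joint, tol = 1e-10, max_iter = 1000) {
  if (!is.matrix(joint) || !all(dim(joint) == c(3, 3)) ||
      any(joint < 0) || anyNA(joint)) {
    stop("joint must be a 3x3 matrix of non-negative counts")
  }
  n <- sum(joint)
  if (n < 1) stop("no subjects")

  # gamete contributions of the eight unambiguous cells, per haplotype
  # order: h11 = ref-ref, h12 = ref-alt, h21 = alt-ref, h22 = alt-alt
  base <- c(
    h11 = 2 * joint[1, 1] + joint[1, 2] + joint[2, 1],
    h12 = 2 * joint[1, 3] + joint[1, 2] + joint[2, 3],
    h21 = 2 * joint[3, 1] + joint[2, 1] + joint[3, 2],
    h22 = 2 * joint[3, 3] + joint[2, 3] + joint[3, 2])
  dh <- joint[2, 2]

  pA <- sum(joint * matrix(2:0, 3, 3)) / (2 * n)          # ref freq, locus A
  pB <- sum(joint * matrix(2:0, 3, 3, byrow = TRUE)) / (2 * n)
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  names(h) <- c("h11", "h12", "h21", "h22")

  ll <- function(h) {
    pcell <- cell_probs(h)
    sum(joint[joint > 0] * log(pcell[joint > 0]))
  }
  ll_old <- ll(h)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    cis <- h[1] * h[4]
    trans <- h[2] * h[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    counts <- base + dh * c(w, 1 - w, 1 - w, w)
    h_new <- counts / (2 * n)
    delta <- max(abs(h_new - h))
    h <- h_new
    ll_new <- ll(h)
    if (ll_new < ll_old - 1e-8) {
      stop("internal error: EM log-likelihood decreased")  # should not happen
    }
    ll_old <- ll_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")
  structure(list(freqs = h, loglik = ll_old, iterations = it,
                 converged = converged, n = n),
            class = "hap_em")
}

# multinomial cell probabilities of the 3x3 joint genotype table given
# haplotype frequencies (h11, h12, h21, h22)
cell_probs <- function(h) {
  m <- matrix(0, 3, 3)
  m[1, 1] <- h[1]^2;          m[1, 2] <- 2 * h[1] * h[2];  m[1, 3] <- h[2]^2
  m[2, 1] <- 2 * h[1] * h[3]; m[2, 2] <- 2 * h[1] * h[4] + 2 * h[2] * h[3]
  m[2, 3] <- 2 * h[2] * h[4]
  m[3, 1] <- h[3]^2;          m[3, 2] <- 2 * h[3] * h[4];  m[3, 3] <- h[4]^2
  m
}

#' @export
print.hap_em <- function(x, ...) {
  cat(sprintf("Two-locus haplotype EM (n = %d subjects, %d iterations%s)\n",
              x$n, x$iterations, if (x$converged) "" else ", NOT converged"))
  print(round(x$freqs, 6))
  invisible(x)
}

#' Linkage-disequilibrium statistics from haplotype frequencies
#'
#' Computes D (haplotype-frequency covariance), D' (D scaled by its
#' attainable bound; reported as magnitude, with the sign of D carried
#' separately) and r-squared for two biallelic loci.
#'
#' @param freqs Frequencies of the four haplotypes in the order
#'   (ref-ref, ref-alt, alt-ref, alt-alt); non-negative, summing to 1.
#' @return Object of class `ld_stats`: `D`, `D_prime` (magnitude),
#'   `D_sign`, `r2`, and the two marginal reference-allele frequencies.
#'   With a monomorphic locus `D_prime` and `r2` are `NA`.
#' @examples
#' ld_from_haps(c(0.5, 0, 0, 0.5))  # perfect LD
#' @export
ld_from_haps <- function(freqs) {
  if (!is.numeric(freqs) || length(freqs) != 4 || any(freqs < 0) ||
      abs(sum(freqs) - 1) > 1e-6) {
    stop("freqs must be 4 non-negative frequencies summing to 1")
  }
  freqs <- unname(freqs)
  pA <- freqs[1] + freqs[2]
  pB <- freqs[1] + freqs[3]
  D <- freqs[1] - pA * pB
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    return(structure(list(D = D, D_prime = NA_real_, D_sign = sign(D),
                          r2 = NA_real_, pA = pA, pB = pB),
                     class = "ld_stats"))
  }
  d_max <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
           else       min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (D == 0) 0 else abs(D) / d_max
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(D = D, D_prime = d_prime, D_sign = sign(D),
                 r2 = r2, pA = pA, pB = pB),
            class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("LD: D = %.4g, |D'| = %s, r2 = %s (sign of D: %+d)\n",
              x$D, format(round(x$D_prime, 4)), format(round(x$r2, 4)),
              x$D_sign))
  invisible(x)
}

#' Haplotype case-control association against the most common haplotype
#'
#' The reference is the haplotype with the largest pooled (cases + controls)
#' count, ties broken lexicographically by label. Every other haplotype is
#' contrasted against the reference in a 2x2 table (cases/controls x
#' haplotype/reference) with a Woolf odds-ratio interval (Gart-adjusted when
#' a cell is zero) and a Pearson chi-square p-value. Haplotypes absent from
#' both groups are reported as absent, with no odds ratio.
#'
#' @param counts Data frame with columns `haplotype` (label), `cases`
#'   and `controls` (counts of chromosomes).
#' @return Object of class `hap_assoc`: a data frame with one row per
#'   haplotype (`or`, `ci_lower`, `ci_upper`, `or_method`, `p`, frequencies
#'   per group), reference row first; the reference label is in
#'   attribute `"reference"`.
#' @examples
#' h <- data.frame(haplotype = c("TA", "CC", "CA", "TC"),
#'                 cases = c(95, 77, 75, 0), controls = c(110, 70, 67, 0))
#' haplotype_case_control(h)
#' @export
haplotype_case_control <- function(counts) {
  req <- c("haplotype", "cases", "controls")
  if (!is.data.frame(counts) || !all(req %in% names(counts))) {
    stop("counts must be a data frame with columns haplotype, cases, controls")
  }
  if (any(counts$cases < 0) || any(counts$controls < 0)) {
    stop("counts must be non-negative")
  }
  pooled <- counts$cases + counts$controls
  if (sum(pooled > 0) < 2) stop("need at least two haplotypes with non-zero count")
  ord <- order(-pooled, counts$haplotype)
  counts <- counts[ord, , drop = FALSE]
  ref <- counts$haplotype[1]

  n_ca <- sum(counts$cases); n_co <- sum(counts$controls)
  res <- data.frame(haplotype = counts$haplotype,
                    cases = counts$cases, controls = counts$controls,
                    freq_cases = counts$cases / n_ca,
                    freq_controls = counts$controls / n_co,
                    or = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                    or_method = NA_character_, p = NA_real_,
                    absent = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))[-1]) {
    if (res$cases[i] + res$controls[i] == 0) {
      res$absent[i] <- TRUE
      next
    }
    t <- table2x2(res$cases[i], res$cases[1], res$controls[i], res$controls[1])
    orr <- or_ci(t)
    res$or[i] <- orr$or
    res$ci_lower[i] <- orr$ci_lower
    res$ci_upper[i] <- orr$ci_upper
    res$or_method[i] <- orr$method
    p <- tryCatch(pearson_chi2(t)$p.value, error = function(e) NA_real_)
    res$p[i] <- p
  }
  structure(res, reference = ref, class = c("hap_assoc", "data.frame"))
}

#' @export
print.hap_assoc <- function(x, digits = 2, ...) {
  cat("Haplotype case-control association (reference:",
      attr(x, "reference"), ")\n")
  d <- as.data.frame(x)
  d$freq_cases <- sprintf("%.2f%%", 100 * d$freq_cases)
  d$freq_controls <- sprintf("%.2f%%", 100 * d$freq_controls)
  d$or <- ifelse(is.na(d$or), ifelse(d$absent, "absent", "1.00 (ref)"),
                 sprintf("%.2f (%.2f-%.2f)", d$or, d$ci_lower, d$ci_upper))
  print(d[, c("haplotype", "cases", "controls", "freq_cases",
              "freq_controls", "or", "p")], row.names = FALSE)
  invisible(x)
}

#' Read a haplotype-count table
#'
#' Small TSV/CSV with columns `haplotype`, `cases`, `controls` (chromosome
#' counts per group), as consumed by [haplotype_case_control()].
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma.
#' @return Data frame with the three columns, validated.
#' @export
read_haplotype_counts <- function(path, sep = NULL) {
  sep <- detect_sep(path, sep)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  req <- c("haplotype", "cases", "controls")
  if (!all(req %in% names(d))) {
    stop("haplotype count file needs columns: ", paste(req, collapse = ", "))
  }
  if (!is.numeric(d$cases) || !is.numeric(d$controls) ||
      any(d$cases < 0) || any(d$controls < 0)) {
    stop("cases/controls must be non-negative counts")
  }
  d[req]
}
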