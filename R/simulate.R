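#' Simulate biallelic genotypes in Hardy-Weinberg equilibrium
#'
#' Dosages are drawn as two independent allele draws at the given minor
#' (alternate) allele frequency, so the population is in HWE by
#' construction.
#'
#' @param n Number of subjects (>= 1).
#' @param maf Alternate-allele frequency in (0, 1).
#' @param seed Optional integer seed for reproducibility.
#' @return List: `dosage` (integer vector of alt-allele counts), `counts`
#'   ([genotype_counts()]), `maf`.
#' @examples
#' simulate_genotypes(100, 0.3, seed = 1)$counts
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  check_freq(maf, "maf")
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- stats::rbinom(n, 2L, maf)
  list(dosage = d, counts = genotype_counts(sum(d == 0), sum(d == 1),
                                            sum(d == 2)), maf = maf)
}

check_freq <- function(x, what) {
  if (!is.numeric(x) || any(x <= 0) || any(x >= 1)) {
    stop(what, " must lie strictly in (0, 1)")
  }
}

#' Simulate a case-control cohort under a logistic disease model
#'
#' Genotypes are drawn in HWE at the configured allele frequencies; disease
#' status is assigned by a logistic model with the configured genotype
#' effect under the chosen inheritance model (plus optional exposure and
#' multiplicative interaction terms); cases and controls are then sampled by
#' rejection from the population stream until the requested group sizes are
#' reached.
#'
#' @param n_cases,n_controls Requested group sizes (defaults 135 and 112,
#'   the sizes of the bundled example study).
#' @param maf Alternate-allele frequency (scalar, or named vector for
#'   several independent markers).
#' @param or Genotype odds ratio(s) applied under `model`; recycled over
#'   markers.
#' @param model Inheritance model for the genotype effect.
#' @param baseline_odds Disease odds of the reference genotype with no
#'   exposure (default 0.1).
#' @param exposure_prev Optional binary exposure prevalence in (0, 1).
#' @param or_exposure,or_interaction Exposure main-effect and multiplicative
#'   gene-exposure interaction odds ratios (used when `exposure_prev` is
#'   given; the interaction multiplies the coded genotype of the first
#'   marker).
#' @param seed Optional integer seed.
#' @param max_draws Abort if the rejection sampler needs more than this many
#'   population draws (default 1e7).
#' @return A `cohort` data frame: `subject_id`, `status`, one dosage column
#'   per marker (named `snp1`, ... or by `names(maf)`), and `exposure` when
#'   simulated.
#' @export
simulate_case_control <- function(n_cases = 135, n_controls = 112,
                                  maf = 0.3, or = 1,
                                  model = c("dominant", "recessive",
                                            "additive", "overdominant"),
                                  baseline_odds = 0.1,
                                  exposure_prev = NULL, or_exposure = 1,
                                  or_interaction = 1,
                                  seed = NULL, max_draws = 1e7) {
  model <- match.arg(model)
  check_freq(maf, "maf")
  stopifnot(n_cases >= 1, n_controls >= 1, baseline_odds > 0)
  if (!is.null(exposure_prev)) check_freq(exposure_prev, "exposure_prev")
  if (!is.null(seed)) set.seed(seed)
  nm <- length(maf)
  ids <- if (!is.null(names(maf))) names(maf) else paste0("snp", seq_len(nm))
  or <- rep_len(or, nm)

  code <- function(d) switch(model,
    dominant = as.numeric(d > 0),
    recessive = as.numeric(d == 2),
    additive = as.numeric(d),
    overdominant = as.numeric(d == 1))

  cases <- list(); controls <- list()
  got_ca <- 0L; got_co <- 0L; drawn <- 0
  batch <- max(20000L, ceiling(2 * (n_cases + n_controls)))
  while (got_ca < n_cases || got_co < n_controls) {
    if (drawn >= max_draws) {
      stop("requested group sizes unattainable within ", max_draws,
           " population draws")
    }
    b <- min(batch, max_draws - drawn)
    drawn <- drawn + b
    G <- vapply(seq_len(nm),
                function(k) stats::rbinom(b, 2L, maf[k]), numeric(b))
    lp <- log(baseline_odds) +
      as.vector(vapply(seq_len(nm), function(k) code(G[, k]) * log(or[k]),
                       numeric(b)) %*% rep(1, nm))
    e <- NULL
    if (!is.null(exposure_prev)) {
      e <- stats::rbinom(b, 1L, exposure_prev)
      lp <- lp + e * log(or_exposure) + e * code(G[, 1]) * log(or_interaction)
    }
    y <- stats::rbinom(b, 1L, stats::plogis(lp))
    take_ca <- which(y == 1)[seq_len(min(sum(y == 1), n_cases - got_ca))]
    take_co <- which(y == 0)[seq_len(min(sum(y == 0), n_controls - got_co))]
    if (length(take_ca) > 0) {
      cases[[length(cases) + 1]] <- cbind(G[take_ca, , drop = FALSE],
                                          if (is.null(e)) NULL else e[take_ca])
      got_ca <- got_ca + length(take_ca)
    }
    if (length(take_co) > 0) {
      controls[[length(controls) + 1]] <- cbind(G[take_co, , drop = FALSE],
                                                if (is.null(e)) NULL else e[take_co])
      got_co <- got_co + length(take_co)
    }
  }
  M <- rbind(do.call(rbind, cases), do.call(rbind, controls))
  d <- data.frame(subject_id = sprintf("S%05d", seq_len(n_cases + n_controls)),
                  status = rep(c("case", "control"), c(n_cases, n_controls)),
                  stringsAsFactors = FALSE)
  for (k in seq_len(nm)) d[[ids[k]]] <- as.integer(M[, k])
  if (!is.null(exposure_prev)) d$exposure <- as.integer(M[, nm + 1])
  attr(d, "sim") <- list(maf = maf, or = or, model = model,
                         baseline_odds = baseline_odds, seed = seed,
                         exposure_prev = exposure_prev,
                         or_exposure = or_exposure,
                         or_interaction = or_interaction, draws = drawn)
  class(d) <- c("cohort", "data.frame")
  d
}

#' Simulate two-locus genotypes from haplotype frequencies
#'
#' Each subject receives two haplotypes drawn independently from the given
#' four-haplotype distribution; returns the 3x3 joint dosage table (the
#' unphased data the EM consumes) together with the true phased haplotype
#' counts for oracle use.
#'
#' @param hap_freqs Frequencies of (ref-ref, ref-alt, alt-ref, alt-alt),
#'   non-negative, summing to 1.
#' @param n Number of subjects.
#' @param seed Optional integer seed.
#' @return List: `joint` (3x3 matrix, rows = dosage at locus A), `hap_counts`
#'   (true counts of the 2n gametes), `hap_freqs`.
#' @export
simulate_two_locus <- function(hap_freqs, n, seed = NULL) {
  if (!is.numeric(hap_freqs) || length(hap_freqs) != 4 ||
      any(hap_freqs < 0) || abs(sum(hap_freqs) - 1) > 1e-6) {
    stop("hap_freqs must be 4 non-negative frequencies summing to 1")
  }
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  hap <- sample.int(4L, 2L * n, replace = TRUE, prob = hap_freqs)
  a_alt <- hap >= 3L               # haplotypes 3,4 carry alt at locus A
  b_alt <- hap %in% c(2L, 4L)      # haplotypes 2,4 carry alt at locus B
  dA <- a_alt[seq_len(n)] + a_alt[n + seq_len(n)]
  dB <- b_alt[seq_len(n)] + b_alt[n + seq_len(n)]
  joint <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) joint[i + 1, j + 1] <- sum(dA == i & dB == j)
  list(joint = joint,
       hap_counts = tabulate(hap, nbins = 4L),
       hap_freqs = hap_freqs)
}
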