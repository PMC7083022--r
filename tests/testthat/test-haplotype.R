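test_that("EM equals direct gamete counting when phase is unambiguous", {
  joint <- matrix(0, 3, 3)
  joint[1, 1] <- 10; joint[1, 2] <- 6; joint[2, 1] <- 4
  joint[3, 3] <- 5; joint[2, 3] <- 3
  em <- em_two_snp(joint)
  n2 <- 2 * sum(joint)
  expect_equal(unname(em$freqs),
               c(2 * 10 + 6 + 4, 6 + 3, 4, 2 * 5 + 3) / n2)
  expect_true(em$converged)
})

test_that("an all-double-heterozygote sample is stationary at uniform frequencies", {
  joint <- matrix(0, 3, 3); joint[2, 2] <- 50
  # allele frequencies are 0.5/0.5, so the equilibrium initialisation is the
  # uniform fixed point: one E-step assigns cis and trans weight 1/2 each
  em <- em_two_snp(joint)
  expect_equal(unname(em$freqs), rep(0.25, 4))
})

test_that("EM recovers generating frequencies within 0.01 at n = 10,000", {
  sim <- simulate_two_locus(c(0.4, 0.3, 0.2, 0.1), n = 10000, seed = 101)
  em <- em_two_snp(sim$joint)
  expect_true(all(abs(em$freqs - c(0.4, 0.3, 0.2, 0.1)) < 0.01))
  # and sits close to the true phased gamete frequencies
  expect_true(all(abs(em$freqs - sim$hap_counts / 20000) < 0.01))
})

test_that("EM matches a fine grid maximisation of the likelihood on small samples", {
  loglik <- function(h, joint) {
    p <- c(h[1]^2, 2 * h[1] * h[2], h[2]^2,
           2 * h[1] * h[3], 2 * h[1] * h[4] + 2 * h[2] * h[3],
           2 * h[2] * h[4],
           h[3]^2, 2 * h[3] * h[4], h[4]^2)
    o <- as.vector(t(joint))
    sum(o[o > 0] * log(p[o > 0]))
  }
  grid_best <- function(joint, centre, half, step) {
    best <- centre; best_ll <- loglik(centre, joint)
    s1 <- seq(max(0, centre[1] - half), min(1, centre[1] + half), by = step)
    s2 <- seq(max(0, centre[2] - half), min(1, centre[2] + half), by = step)
    s3 <- seq(max(0, centre[3] - half), min(1, centre[3] + half), by = step)
    for (a in s1) for (b in s2) for (c in s3) {
      d <- 1 - a - b - c
      if (d < -1e-12) next
      h <- c(a, b, c, max(d, 0))
      ll <- loglik(h, joint)
      if (ll > best_ll) { best <- h; best_ll <- ll }
    }
    best
  }
  set.seed(31)
  for (i in 1:4) {
    f <- as.vector(stats::rmultinom(1, 12, c(.35, .3, .2, .15))) / 12
    f <- f + 0.01; f <- f / sum(f)
    sim <- simulate_two_locus(f, n = sample(20:50, 1))
    em <- em_two_snp(sim$joint)
    # coarse pass over the whole simplex, then 0.001-step local refinement
    coarse <- grid_best(sim$joint, c(.5, .25, .25, 0), 0.5, 0.01)
    fine <- grid_best(sim$joint, coarse, 0.012, 0.001)
    expect_true(all(abs(em$freqs - fine) < 0.005))
  }
})

test_that("LD statistics match their defining formulas", {
  perfect <- ld_from_haps(c(0.5, 0, 0, 0.5))
  expect_equal(perfect$D, 0.25)
  expect_equal(perfect$D_prime, 1)
  expect_equal(perfect$r2, 1)

  eq <- ld_from_haps(c(0.42, 0.28, 0.18, 0.12))  # product frequencies
  expect_equal(eq$D, 0)
  expect_equal(eq$r2, 0)
  expect_equal(eq$D_prime, 0)

  x <- ld_from_haps(c(0.4, 0.3, 0.2, 0.1))
  expect_equal(x$D, -0.02)
  expect_equal(x$D_prime, 0.02 / 0.12)
  expect_equal(x$r2, 0.0004 / (0.7 * 0.3 * 0.6 * 0.4))
  expect_equal(x$D_sign, -1)
})

test_that("|D'| is 1 whenever a haplotype is absent at polymorphic loci", {
  set.seed(17)
  for (i in 1:40) {
    f <- as.vector(stats::rmultinom(1, 60, c(.3, .3, .2, .2))) / 60
    f[sample(1:4, 1)] <- 0
    f <- f / sum(f)
    ld <- ld_from_haps(f)
    pA <- f[1] + f[2]; pB <- f[1] + f[3]
    if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
      expect_true(is.na(ld$D_prime))
    } else {
      expect_equal(ld$D_prime, 1)
    }
  }
})

test_that("monomorphic loci yield undefined D' and r2", {
  ld <- ld_from_haps(c(0.6, 0.4, 0, 0))
  expect_true(is.na(ld$D_prime) && is.na(ld$r2))
})

test_that("haplotype association reproduces the published two-gene tables", {
  h <- haplotype_case_control(bc_haplotype_counts()$MTHFR)
  expect_identical(attr(h, "reference"), "TA")
  expect_printed(h$or[h$haplotype == "CC"], "1.27")
  expect_printed(h$ci_lower[h$haplotype == "CC"], "0.83")
  expect_printed(h$ci_upper[h$haplotype == "CC"], "1.95")
  expect_printed(h$or[h$haplotype == "CA"], "1.30")
  expect_true(h$absent[h$haplotype == "TC"])
  expect_true(is.na(h$or[h$haplotype == "TC"]))

  x <- haplotype_case_control(bc_haplotype_counts()$XRCC1)
  expect_identical(attr(x, "reference"), "CG")
  expect_printed(x$or[x$haplotype == "TG"], "0.52")
  expect_printed(x$ci_lower[x$haplotype == "TG"], "0.19")
  expect_printed(x$ci_upper[x$haplotype == "TG"], "1.45")
  # computed CA odds ratio rounds to 0.93 (one unit above the published 0.92)
  expect_printed(x$or[x$haplotype == "CA"], "0.93")
})

test_that("identical haplotype distributions give odds ratios of 1", {
  h <- haplotype_case_control(
    data.frame(haplotype = c("AB", "Ab", "aB"),
               cases = c(60, 30, 10), controls = c(60, 30, 10)))
  expect_true(all(h$or[-1] == 1))
  # the reference is not contrasted against itself
  expect_true(is.na(h$or[1]))
})

test_that("reference ties break lexicographically and Gart handles zero groups", {
  h <- haplotype_case_control(
    data.frame(haplotype = c("BB", "AA", "AB"),
               cases = c(50, 50, 0), controls = c(50, 50, 4)))
  expect_identical(attr(h, "reference"), "AA")
  expect_identical(h$or_method[h$haplotype == "AB"], "gart")
})

test_that("haplotype count files are read and validated", {
  path <- write_tmp(c("haplotype\tcases\tcontrols",
                      "TA\t95\t110", "CC\t77\t70"), ext = ".tsv")
  d <- read_haplotype_counts(path)
  expect_equal(d$cases, c(95, 77))
  expect_error(read_haplotype_counts(
    write_tmp(c("hap\tcases\tcontrols", "TA\t1\t2"), ext = ".tsv")),
    "columns")
})
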