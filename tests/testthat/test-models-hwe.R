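mthfr <- list(cases = c(53, 60, 22), controls = c(31, 62, 19))

test_that("model encodings reproduce the published contingency tables", {
  dom <- encode_model(mthfr$cases, mthfr$controls, "dominant")
  expect_equal(unclass(dom[[1]]$table), c(a = 82, b = 53, c = 81, d = 31))
  expect_printed(woolf_or_ci(dom[[1]]$table)$or, "0.59")

  rec <- encode_model(c(87, 46, 2), c(70, 35, 7), "recessive")
  expect_equal(unclass(rec[[1]]$table), c(a = 2, b = 133, c = 7, d = 105))
  expect_printed(woolf_or_ci(rec[[1]]$table)$or, "0.23")

  over <- encode_model(mthfr$cases, mthfr$controls, "overdominant")
  expect_equal(unclass(over[[1]]$table), c(a = 60, b = 75, c = 62, d = 50))
  expect_printed(woolf_or_ci(over[[1]]$table)$or, "0.65")

  alle <- encode_model(mthfr$cases, mthfr$controls, "allelic")
  expect_equal(unclass(alle[[1]]$table), c(a = 104, b = 166, c = 100, d = 124))
  expect_printed(woolf_or_ci(alle[[1]]$table)$or, "0.78")

  cod <- encode_model(mthfr$cases, mthfr$controls, "codominant",
                      marker = study_markers()$rs1801133)
  expect_equal(vapply(cod, `[[`, "", "contrast"),
               c("C/T vs C/C", "T/T vs C/C"))
})

test_that("encoded cells always sum to the analysed subjects (alleles: twice)", {
  set.seed(5)
  for (i in 1:50) {
    ca <- genotype_counts(rpois(1, 20) + 1, rpois(1, 20), rpois(1, 10))
    co <- genotype_counts(rpois(1, 20) + 1, rpois(1, 20), rpois(1, 10))
    n <- sum(ca) + sum(co)
    for (mod in c("dominant", "recessive", "overdominant")) {
      t <- encode_model(ca, co, mod)[[1]]$table
      expect_equal(sum(t), n)
    }
    expect_equal(sum(encode_model(ca, co, "allelic")[[1]]$table), 2 * n)
  }
})

test_that("dominant and recessive swap roles under allele relabelling", {
  set.seed(9)
  for (i in 1:30) {
    ca <- rpois(3, 15) + 1; co <- rpois(3, 15) + 1
    dom <- encode_model(ca, co, "dominant")[[1]]$table
    rec_flipped <- encode_model(rev(ca), rev(co), "recessive")[[1]]$table
    # after ref<->alt relabelling, "two alt alleles" is the old "no alt
    # allele": the recessive table is the dominant one with its exposed and
    # reference columns exchanged
    expect_equal(unname(unclass(rec_flipped)),
                 unname(unclass(dom))[c(2, 1, 4, 3)])
  }
})

test_that("codominant drops classes empty in both groups, with a flag", {
  cod <- encode_model(c(10, 5, 0), c(8, 3, 0), "codominant",
                      marker = study_markers()$rs1052133)
  expect_length(cod, 1)
  expect_equal(attr(cod, "dropped"), "G/G")
})

test_that("HWE chi-square reproduces the published case-group p-value", {
  h <- hwe_test(mthfr$cases)
  expect_printed(h$p_chi2, "0.47")
  expect_equal(sum(h$expected), 135)
  expect_equal(h$allele_freq, 166 / 270)
})

test_that("HWE chi-square matches the hand-computed statistic for controls", {
  # expected counts from p = (2*31 + 62)/224: Sum (O-E)^2/E = 1.6128
  h <- hwe_test(mthfr$controls)
  expect_equal(h$chi2, 1.6128, tolerance = 1e-4)
  expect_equal(h$p_chi2, 0.2041, tolerance = 1e-4)
})

test_that("exact HWE proportions give chi2 = 0 and exact p covering 1", {
  h <- hwe_test(c(25, 50, 25))
  expect_equal(h$chi2, 0)
  expect_equal(h$p_chi2, 1)
  expect_equal(h$p_exact, 1)
})

test_that("exact HWE test matches the published near-monomorphic marker", {
  expect_printed(hwe_test(c(128, 7, 0))$p_exact, "1.00")
})

test_that("exact HWE test matches brute-force enumeration at small n", {
  # oracle: enumerate all genotype configurations with the observed allele
  # counts and sum multinomial-conditional probabilities <= observed
  exact_oracle <- function(g) {
    n <- sum(g); n_ref <- 2 * g[1] + g[2]
    n_min <- min(n_ref, 2 * n - n_ref)
    hets <- seq(n_min %% 2, n_min, by = 2)
    pr <- vapply(hets, function(h) {
      hom_min <- (n_min - h) / 2
      hom_maj <- n - h - hom_min
      exp(h * log(2) + lfactorial(n) - lfactorial(hom_min) -
            lfactorial(h) - lfactorial(hom_maj))
    }, numeric(1))
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(g[2], hets)] * (1 + 1e-9)])
  }
  set.seed(13)
  for (i in 1:40) {
    g <- c(sample(0:8, 1), sample(0:8, 1), sample(0:8, 1))
    if (sum(g) == 0 || 2 * g[1] + g[2] == 0 || 2 * g[3] + g[2] == 0) next
    expect_equal(hwe_test(g)$p_exact, exact_oracle(g), tolerance = 1e-12)
  }
})

test_that("monomorphic input returns p = 1 with a warning", {
  expect_warning(h <- hwe_test(c(20, 0, 0)), "monomorphic")
  expect_equal(h$p_chi2, 1)
  expect_equal(h$p_exact, 1)
})

test_that("HWE chi-square rejects at close to nominal rate under the null", {
  set.seed(20240101)
  rej <- 0; B <- 400
  for (i in 1:B) {
    g <- simulate_genotypes(500, 0.3)$counts
    rej <- rej + (hwe_test(g)$p_chi2 < 0.05)
  }
  expect_gte(rej / B, 0.02)
  expect_lte(rej / B, 0.09)
})

test_that("chi-square and exact HWE p-values converge on large samples", {
  # the exact test is conservative and converges slowly: at n = 1000 the two
  # p-values still commonly differ by > 0.02, so close agreement is asserted
  # at n = 10,000 and only rough agreement below
  set.seed(77)
  close_big <- 0; B <- 100
  diffs_small <- numeric(B)
  for (i in 1:B) {
    h <- hwe_test(simulate_genotypes(10000, 0.3)$counts)
    close_big <- close_big + (abs(h$p_chi2 - h$p_exact) < 0.02)
    hs <- hwe_test(simulate_genotypes(1000, 0.3)$counts)
    diffs_small[i] <- abs(hs$p_chi2 - hs$p_exact)
  }
  expect_gte(close_big / B, 0.95)
  expect_lt(median(diffs_small), 0.05)
})

test_that("the trend test matches the allele-based chi-square direction", {
  t1 <- trend_test(c(50, 40, 10), c(30, 45, 25))
  expect_s3_class(t1, "assoc_test")
  expect_lt(t1$p.value, 0.05)
  t0 <- trend_test(c(50, 40, 10), c(50, 40, 10))
  expect_equal(t0$statistic, 0)
})
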