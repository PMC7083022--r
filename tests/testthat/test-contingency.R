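test_that("table2x2 validates its cells", {
  expect_s3_class(table2x2(1, 2, 3, 4), "table2x2")
  expect_error(table2x2(-1, 2, 3, 4), "non-negative")
  expect_error(table2x2(1.5, 2, 3, 4), "integer")
  expect_error(table2x2(0, 0, 0, 0), "empty")
})

test_that("Woolf interval reproduces the published heterozygote contrast", {
  res <- woolf_or_ci(table2x2(60, 53, 62, 31))
  expect_printed(res$or, "0.57")
  expect_printed(res$ci_lower, "0.32")
  expect_printed(res$ci_upper, "1")
  expect_identical(res$method, "woolf")
})

test_that("Woolf interval on the unit table is symmetric about 1", {
  res <- woolf_or_ci(table2x2(1, 1, 1, 1))
  expect_equal(res$or, 1)
  expect_equal(log(res$ci_upper), -log(res$ci_lower))
})

test_that("Woolf refuses zero cells and Gart refuses zero-free tables", {
  expect_error(woolf_or_ci(table2x2(0, 5, 5, 5)), "gart")
  expect_error(gart_or_ci(table2x2(1, 5, 5, 5)), "woolf")
  expect_error(gart_or_ci(table2x2(0, 0, 5, 5)), "row or column")
})

test_that("Gart adjustment adds 0.5 to all four cells", {
  res <- gart_or_ci(table2x2(2, 40, 0, 88))
  expect_equal(res$or, (2.5 * 88.5) / (40.5 * 0.5))
  expect_printed(res$or, "10.92", units = 1.5)        # printed value truncates
  expect_printed(res$ci_lower, "0.51")
  expect_printed(res$ci_upper, "232.81", units = 1.5)
  res2 <- gart_or_ci(table2x2(0, 90, 2, 43))
  expect_equal(res2$or, (0.5 * 43.5) / (90.5 * 2.5))
  expect_printed(res2$or, "0.09", units = 1.5)
  expect_equal(gart_or_ci(table2x2(0, 1, 1, 1))$or, 1 / 3)
})

test_that("odds-ratio reciprocity and log-scale CI symmetry hold on random tables", {
  set.seed(42)
  for (i in 1:400) {
    cells <- rpois(4, 12) + 1
    t1 <- table2x2(cells[1], cells[2], cells[3], cells[4])
    t_swap <- table2x2(cells[2], cells[1], cells[4], cells[3])
    r1 <- woolf_or_ci(t1); r2 <- woolf_or_ci(t_swap)
    expect_equal(r2$or, 1 / r1$or)
    expect_equal(r2$ci_lower, 1 / r1$ci_upper)
    expect_equal(r2$ci_upper, 1 / r1$ci_lower)
    expect_equal(log(r1$ci_upper) - log(r1$or), log(r1$or) - log(r1$ci_lower))
    # row swap inverts the OR too
    r3 <- woolf_or_ci(table2x2(cells[3], cells[4], cells[1], cells[2]))
    expect_equal(r3$or, 1 / r1$or)
  }
})

test_that("scaling all cells fixes the OR and strictly narrows the CI", {
  set.seed(7)
  for (i in 1:50) {
    cells <- rpois(4, 8) + 1
    r1 <- woolf_or_ci(table2x2(cells[1], cells[2], cells[3], cells[4]))
    r2 <- woolf_or_ci(table2x2(3 * cells[1], 3 * cells[2],
                               3 * cells[3], 3 * cells[4]))
    expect_equal(r2$or, r1$or)
    expect_lt(r2$ci_upper - r2$ci_lower, r1$ci_upper - r1$ci_lower)
  }
})

test_that("Pearson chi-square matches published model p-values without correction", {
  r1 <- pearson_chi2(matrix(c(53, 60, 31, 62), 2, byrow = TRUE))
  expect_printed(r1$p.value, "0.049")
  expect_printed(r1$statistic, "3.89", units = 1)
  r2 <- pearson_chi2(matrix(c(2, 133, 7, 105), 2, byrow = TRUE))
  expect_printed(r2$p.value, "0.0465")
})

test_that("Pearson chi-square equals its 2x2 closed form and is 0 under independence", {
  set.seed(11)
  for (i in 1:100) {
    m <- matrix(rpois(4, 15) + 1, 2)
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]; n <- sum(m)
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(pearson_chi2(m)$statistic, closed)
  }
  prop <- matrix(c(10, 20, 5, 10), 2, byrow = TRUE)  # proportional rows
  expect_equal(pearson_chi2(prop)$statistic, 0)
  expect_equal(pearson_chi2(prop)$p.value, 1)
  expect_error(pearson_chi2(matrix(c(0, 0, 1, 2), 2)), "degenerate")
})

test_that("Fisher exact test matches enumeration and conventions", {
  expect_equal(fisher_exact(table2x2(5, 5, 5, 5))$p.value, 1)
  expect_equal(fisher_exact(table2x2(3, 0, 0, 3))$p.value,
               fisher_enum_p(3, 0, 0, 3))
  expect_equal(fisher_exact(table2x2(10, 10, 10, 10))$p.value, 1)
  expect_equal(fisher_exact(table2x2(0, 0, 3, 4))$p.value, 1)  # empty margin
})

test_that("Fisher exact agrees with exhaustive enumeration for all tables n <= 15", {
  for (n in 1:15) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
      if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
      expect_equal(fisher_exact(m)$p.value, fisher_enum_p(a, b, c, d),
                   tolerance = 1e-10)
    }
  }
})

test_that("Student t-test matches the pooled closed form and its conventions", {
  x <- c(1.2, 2.5, 3.1); y <- c(2.0, 2.2, 4.4)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  res <- student_t(x, y)
  expect_equal(res$statistic, t_hand)
  expect_equal(res$p.value, 2 * pt(-abs(t_hand), 4))
  expect_equal(student_t(x, x)$statistic, 0)
  expect_equal(student_t(x, x)$p.value, 1)
  expect_equal(student_t(5 * x, 5 * y)$statistic, res$statistic)
  expect_equal(student_t(rep(1, 3), rep(1, 4))$p.value, 1)
})

test_that("Bonferroni thresholds match the declared families", {
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 18), 0.002778)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
  expect_error(bonferroni_threshold(1.2, 3), "alpha")
})
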