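#' Construct a 2x2 contingency table
#'
#' Cell layout follows the epidemiological convention used throughout the
#' package: group 1 (cases, or the first-listed class) in the first row,
#' the tested ("exposed") category in the first column.
#'
#' @param a Group-1, exposed count.
#' @param b Group-1, unexposed (reference) count.
#' @param c Group-2, exposed count.
#' @param d Group-2, unexposed count.
#' @return An object of class `table2x2`.
#' @examples
#' table2x2(60, 53, 62, 31)
#' @export
table2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || !is.numeric(cells)) {
    stop("all four cells must be non-missing numbers")
  }
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if (any(abs(cells - round(cells)) > 1e-8)) {
    stop("cell counts must be integers")
  }
  if (sum(cells) <= 0) stop("table is empty (all cells zero)")
  structure(as.numeric(round(cells)), names = c("a", "b", "c", "d"),
            class = "table2x2")
}

#' @export
as.matrix.table2x2 <- function(x, ...) {
  matrix(unclass(x), nrow = 2, byrow = TRUE,
         dimnames = list(group = c("group1", "group2"),
                         category = c("exposed", "reference")))
}

#' @export
print.table2x2 <- function(x, ...) {
  print(as.matrix(x))
  invisible(x)
}

as_table2x2 <- function(t) {
  if (inherits(t, "table2x2")) return(t)
  if (is.matrix(t) && all(dim(t) == 2)) {
    return(table2x2(t[1, 1], t[1, 2], t[2, 1], t[2, 2]))
  }
  if (is.numeric(t) && length(t) == 4) return(table2x2(t[1], t[2], t[3], t[4]))
  stop("cannot interpret input as a 2x2 table")
}

new_or_result <- function(or, lo, hi, method, cells, z) {
  structure(list(or = or, ci_lower = lo, ci_upper = hi,
                 conf_level = 0.95, method = method,
                 cells = cells, z = z),
            class = "or_ci")
}

#' @export
print.or_ci <- function(x, digits = 4, ...) {
  cat(sprintf("Odds ratio (%s): %.*g, 95%% CI [%.*g, %.*g]\n",
              x$method, digits, x$or, digits, x$ci_lower, digits, x$ci_upper))
  invisible(x)
}

#' Woolf confidence interval for an odds ratio
#'
#' Point estimate \eqn{(ad)/(bc)} with a 95\% interval on the log scale,
#' standard error \eqn{\sqrt{1/a + 1/b + 1/c + 1/d}} and the exact 97.5\%
#' normal quantile. Requires a zero-free table; with any zero cell use
#' [gart_or_ci()].
#'
#' @param t A [table2x2()] (or 2x2 matrix / length-4 vector).
#' @return An object of class `or_ci` with elements `or`, `ci_lower`,
#'   `ci_upper`, `method` ("woolf") and `cells` (the cells actually used).
#' @examples
#' woolf_or_ci(table2x2(60, 53, 62, 31))
#' @export
woolf_or_ci <- function(t) {
  t <- as_table2x2(t)
  if (any(t == 0)) {
    stop("zero cell present; use gart_or_ci() (Gart-adjusted logit interval)")
  }
  woolf_core(unclass(t), method = "woolf")
}

woolf_core <- function(cells, method) {
  z <- stats::qnorm(0.975)
  or <- (cells[["a"]] * cells[["d"]]) / (cells[["b"]] * cells[["c"]])
  se <- sqrt(sum(1 / cells))
  new_or_result(or, exp(log(or) - z * se), exp(log(or) + z * se),
                method, cells, z)
}

#' Gart-adjusted logit interval for an odds ratio
#'
#' For tables containing a zero cell: adds 0.5 to all four cells, then applies
#' the Woolf point estimate and interval to the adjusted cells.
#'
#' @param t A [table2x2()] with at least one zero cell. A table with an empty
#'   row or column (both cells of one margin zero) is rejected: the odds ratio
#'   is undefined there even after adjustment.
#' @return An object of class `or_ci`, `method = "gart"`; `cells` holds the
#'   adjusted (+0.5) values.
#' @examples
#' gart_or_ci(table2x2(2, 40, 0, 88))
#' @export
gart_or_ci <- function(t) {
  t <- as_table2x2(t)
  if (!any(t == 0)) stop("no zero cell; use woolf_or_ci()")
  m <- as.matrix(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("a whole row or column is zero; odds ratio undefined")
  }
  woolf_core(unclass(t) + 0.5, method = "gart")
}

#' Odds ratio with automatic zero-cell handling
#'
#' Dispatches to [woolf_or_ci()] for zero-free tables and to [gart_or_ci()]
#' when any cell is zero.
#'
#' @param t A [table2x2()].
#' @param method `"auto"` (default), `"woolf"` or `"gart"`.
#' @return An object of class `or_ci`.
#' @export
or_ci <- function(t, method = c("auto", "woolf", "gart")) {
  method <- match.arg(method)
  t <- as_table2x2(t)
  switch(method,
         auto = if (any(t == 0)) gart_or_ci(t) else woolf_or_ci(t),
         woolf = woolf_or_ci(t),
         gart = gart_or_ci(t))
}

new_test_result <- function(statistic, df, p, name) {
  structure(list(statistic = statistic, df = df, p.value = p,
                 test_name = name),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(x$test_name, "\n")
  if (!is.na(x$statistic)) {
    cat(sprintf("  statistic = %.4g, df = %s, p = %.4g\n",
                x$statistic, format(x$df), x$p.value))
  } else {
    cat(sprintf("  p = %.4g\n", x$p.value))
  }
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Classical Pearson statistic on an R x C table of counts, with no
#' continuity correction, as used for all genotype-model and haplotype
#' contrasts in this package.
#'
#' @param x Matrix of non-negative counts (a [table2x2()] is accepted), with
#'   at least two non-empty rows and columns.
#' @return An `assoc_test` with `statistic`, `df = (R-1)(C-1)` and upper-tail
#'   `p.value`.
#' @examples
#' pearson_chi2(matrix(c(53, 60, 31, 62), 2, byrow = TRUE))
#' @export
pearson_chi2 <- function(x) {
  if (inherits(x, "table2x2")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (any(x < 0) || anyNA(x)) stop("counts must be non-negative and non-missing")
  x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("degenerate table: fewer than two non-empty rows or columns")
  }
  res <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  new_test_result(unname(res$statistic), unname(res$parameter),
                  res$p.value, "Pearson chi-square (no continuity correction)")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value obtained by summing hypergeometric probabilities no
#' larger than that of the observed table. A table with an empty margin has
#' p = 1 by convention.
#'
#' @param t A [table2x2()] or 2x2 count matrix.
#' @return An `assoc_test` (statistic is `NA`; the test is exact).
#' @export
fisher_exact <- function(t) {
  m <- if (inherits(t, "table2x2")) as.matrix(t) else as_table2x2(t) |> as.matrix()
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(new_test_result(NA_real_, NA_real_, 1, "Fisher exact test"))
  }
  p <- stats::fisher.test(m)$p.value
  new_test_result(NA_real_, NA_real_, min(p, 1), "Fisher exact test")
}

#' Two-sample Student's t-test
#'
#' Pooled-variance two-sided t-test by default (Welch available via
#' `pooled = FALSE`), as used for continuous descriptive variables such as
#' age or BMI. If both samples are constant with equal means the test returns
#' t = 0, p = 1 by convention.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param pooled Use the pooled-variance statistic (default `TRUE`).
#' @return An `assoc_test`.
#' @export
student_t <- function(x, y, pooled = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(new_test_result(0, length(x) + length(y) - 2, 1, "Student t-test"))
    }
    return(new_test_result(Inf, length(x) + length(y) - 2, 0, "Student t-test"))
  }
  res <- stats::t.test(x, y, var.equal = pooled)
  new_test_result(unname(res$statistic), unname(res$parameter), res$p.value,
                  if (pooled) "Student t-test (pooled variance)" else "Welch t-test")
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of tests in the family (>= 1).
#' @return `alpha / m`, reported to 4 significant digits (round-half-even).
#' @examples
#' bonferroni_threshold(0.05, 5)   # 0.01
#' bonferroni_threshold(0.05, 18)  # 0.002778
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)")
  }
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != round(m)) {
    stop("m must be a positive integer")
  }
  signif(alpha / m, 4)
}
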