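#' Per-SNP case-control association scan
#'
#' Runs, for every marker and inheritance model, the complete-case
#' contingency analysis: genotype counts per group, model encoding
#' ([encode_model()]), Pearson chi-square per contrast and an odds ratio
#' with Woolf interval (Gart-adjusted when a cell is zero, or the contrast
#' skipped, per `zero_cell`). Hardy-Weinberg tests for both groups are
#' attached per marker; only the control-group result is conventionally used
#' for marker inclusion. Nominal significance is flagged at `alpha` and
#' family-corrected significance at `alpha / m` (Bonferroni).
#'
#' @param cohort A `cohort` data frame (see [cohort_table()] or
#'   [cohort_from_counts()]): `status` column (`"case"`/`"control"`) plus
#'   one dosage column per marker.
#' @param markers Named list of [marker_def()]; defaults to the `"markers"`
#'   attribute of `cohort`.
#' @param models Inheritance models to fit (default all five).
#' @param alpha Nominal significance level (default 0.05).
#' @param bonferroni_m Number of tests in the Bonferroni family; default the
#'   number of markers analysed.
#' @param zero_cell `"gart"` (default) to use the Gart-adjusted interval on
#'   zero-cell tables, `"skip"` to omit such contrasts.
#' @return Object of class `snp_assoc`: a data frame with one row per
#'   marker x model x contrast (counts, `or`, `ci_lower`, `ci_upper`,
#'   `or_method`, `chi2`, `p`, significance flags), with per-marker
#'   [hwe_test()] results in attribute `"hwe"`.
#' @export
run_snp_association <- function(cohort, markers = attr(cohort, "markers"),
                                models = c("codominant", "dominant",
                                           "recessive", "overdominant",
                                           "allelic"),
                                alpha = 0.05, bonferroni_m = NULL,
                                zero_cell = c("gart", "skip")) {
  zero_cell <- match.arg(zero_cell)
  models <- match.arg(models, inheritance_models, several.ok = TRUE)
  if (is.null(markers)) stop("no marker definitions supplied")
  if (!"status" %in% names(cohort)) stop("cohort needs a status column")
  status <- as.character(cohort$status)
  if (!all(status %in% c("case", "control") | is.na(status))) {
    stop("status must be 'case' or 'control'")
  }
  ids <- intersect(names(markers), names(cohort))
  if (length(ids) == 0) stop("no marker columns found in cohort")

  rows <- list(); hwe <- list()
  for (id in ids) {
    d <- cohort[[id]]
    ok <- !is.na(d) & !is.na(status)
    g_ca <- tabulate3(d[ok & status == "case"])
    g_co <- tabulate3(d[ok & status == "control"])
    if (sum(g_ca) == 0 || sum(g_co) == 0) {
      warning("marker ", id, ": a group is entirely missing; skipped")
      next
    }
    hwe[[id]] <- list(cases = suppressWarnings(hwe_test(g_ca)),
                      controls = suppressWarnings(hwe_test(g_co)))
    rows[[length(rows) + 1]] <-
      assoc_rows(id, markers[[id]]$gene, g_ca, g_co, models,
                 marker = markers[[id]], zero_cell = zero_cell,
                 group_labels = c("case", "control"))
  }
  if (length(rows) == 0) stop("no marker could be analysed")
  res <- do.call(rbind, rows)
  m <- if (is.null(bonferroni_m)) length(hwe) else bonferroni_m
  finish_assoc(res, alpha, m, hwe)
}

tabulate3 <- function(d) {
  if (any(!d %in% 0:2, na.rm = TRUE)) stop("dosages must be 0, 1 or 2")
  c(sum(d == 0L), sum(d == 1L), sum(d == 2L))
}

# shared engine: one marker, two groups given as genotype counts
assoc_rows <- function(id, gene, g1, g2, models, marker, zero_cell,
                       group_labels) {
  out <- list()
  for (mod in models) {
    enc <- tryCatch(encode_model(g1, g2, mod, marker = marker),
                    error = function(e) NULL)
    if (is.null(enc)) next
    for (ct in enc) {
      t <- ct$table
      # a category empty in both groups leaves the odds ratio undefined
      if (t[["a"]] + t[["c"]] == 0 || t[["b"]] + t[["d"]] == 0) next
      if (any(t == 0) && zero_cell == "skip") next
      orr <- tryCatch(or_ci(t), error = function(e) NULL)
      p <- tryCatch(pearson_chi2(t), error = function(e) NULL)
      out[[length(out) + 1]] <- data.frame(
        marker = id, gene = gene, model = mod, contrast = ct$contrast,
        n1_exposed = t[["a"]], n1_reference = t[["b"]],
        n2_exposed = t[["c"]], n2_reference = t[["d"]],
        group1 = group_labels[1], group2 = group_labels[2],
        or = if (is.null(orr)) NA_real_ else orr$or,
        ci_lower = if (is.null(orr)) NA_real_ else orr$ci_lower,
        ci_upper = if (is.null(orr)) NA_real_ else orr$ci_upper,
        or_method = if (is.null(orr)) NA_character_ else orr$method,
        chi2 = if (is.null(p)) NA_real_ else p$statistic,
        p = if (is.null(p)) NA_real_ else p$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

finish_assoc <- function(res, alpha, m, hwe) {
  res$sig_nominal <- !is.na(res$p) & res$p <= alpha
  res$sig_corrected <- !is.na(res$p) & res$p < alpha / m
  rownames(res) <- NULL
  structure(res, hwe = hwe, alpha = alpha, bonferroni_m = m,
            class = c("snp_assoc", "data.frame"))
}

#' Build a cohort from printed genotype counts
#'
#' Expands per-group genotype counts into a subject-level cohort table, so
#' published contingency tables can be fed to the same pipeline as raw data.
#' With several markers, per-subject genotypes are assigned marker-by-marker
#' in order (the joint distribution is arbitrary, which is irrelevant for
#' per-marker analyses); all markers must imply the same group sizes.
#'
#' @param markers A [marker_def()] or named list of them.
#' @param group1,group2 For one marker: length-3 genotype count vectors.
#'   For several: named lists of such vectors, keyed by marker id.
#' @param group_labels Labels of the two groups (default
#'   `c("case", "control")`).
#' @param group_var Column name holding the group label (default
#'   `"status"`). When it is not `"status"`, a constant `status = "case"`
#'   column is added (case-only subgroup data).
#' @return A `cohort` data frame.
#' @examples
#' mk <- study_markers()$rs1801133
#' cc <- cohort_from_counts(mk, c(53, 60, 22), c(31, 62, 19))
#' @export
cohort_from_counts <- function(markers, group1, group2,
                               group_labels = c("case", "control"),
                               group_var = "status") {
  if (inherits(markers, "marker_def")) {
    id <- markers$marker_id
    markers <- stats::setNames(list(markers), id)
    group1 <- stats::setNames(list(group1), id)
    group2 <- stats::setNames(list(group2), id)
  }
  n1 <- unique(vapply(group1, sum, 0))
  n2 <- unique(vapply(group2, sum, 0))
  if (length(n1) != 1 || length(n2) != 1) {
    stop("all markers must imply the same group sizes")
  }
  d <- data.frame(subject_id = sprintf("S%04d", seq_len(n1 + n2)),
                  stringsAsFactors = FALSE)
  d[[group_var]] <- factor(rep(group_labels, c(n1, n2)),
                           levels = group_labels)
  for (id in names(markers)) {
    d[[id]] <- c(rep(0:2, group1[[id]]), rep(0:2, group2[[id]]))
  }
  if (group_var != "status") d$status <- "case"
  attr(d, "markers") <- markers
  class(d) <- c("cohort", "data.frame")
  d
}

#' Case-only clinicopathological subgroup association
#'
#' Tests the genotype distribution of a marker against a binary clinical
#' characteristic within cases, with the same model encodings, chi-square
#' tests and odds-ratio machinery as the case-control scan; zero cells use
#' the Gart adjustment.
#'
#' @param cohort A `cohort` data frame (cases are selected via the `status`
#'   column when present).
#' @param marker Marker id (column name) or a [marker_def()].
#' @param variable Name of the clinical variable column.
#' @param scheme Grouping scheme for [binarize_clinical()] (default
#'   `"binary"` for variables that are already two-level).
#' @param models Inheritance models (default all five).
#' @param alpha,bonferroni_m As in [run_snp_association()] (default m = 1).
#' @return A `snp_assoc` object; `group1`/`group2` columns hold the two
#'   clinical classes.
#' @export
run_subgroup_association <- function(cohort, marker, variable,
                                     scheme = "binary",
                                     models = c("codominant", "dominant",
                                                "recessive", "overdominant",
                                                "allelic"),
                                     alpha = 0.05, bonferroni_m = 1) {
  models <- match.arg(models, inheritance_models, several.ok = TRUE)
  mk <- if (inherits(marker, "marker_def")) marker
        else attr(cohort, "markers")[[marker]]
  if (is.null(mk)) stop("unknown marker: ", marker)
  id <- mk$marker_id
  if (!id %in% names(cohort)) stop("cohort lacks column ", id)
  if (!variable %in% names(cohort)) stop("cohort lacks column ", variable)
  d <- cohort
  if ("status" %in% names(d)) d <- d[as.character(d$status) == "case", ]
  cls <- binarize_clinical(d[[variable]], scheme)
  if (nlevels(cls) != 2) stop("scheme must produce exactly two classes")
  ok <- !is.na(cls) & !is.na(d[[id]])
  lv <- levels(cls)
  g1 <- tabulate3(d[[id]][ok & cls == lv[1]])
  g2 <- tabulate3(d[[id]][ok & cls == lv[2]])
  if (sum(g1) == 0 || sum(g2) == 0) {
    stop("a clinical class has no genotyped subjects; analysis skipped")
  }
  res <- assoc_rows(id, mk$gene, g1, g2, models, marker = mk,
                    zero_cell = "gart", group_labels = lv)
  if (is.null(res)) stop("no contrast could be formed")
  hwe <- list()
  hwe[[id]] <- list(group1 = suppressWarnings(hwe_test(g1)),
                    group2 = suppressWarnings(hwe_test(g2)))
  finish_assoc(res, alpha, bonferroni_m, hwe)
}

#' Multiplicative gene-environment interaction test
#'
#' Fits case/control status on genotype, a binary exposure and their
#' product by maximum-likelihood logistic regression (IRLS; convergence on a
#' log-likelihood change below 1e-8, at most 50 iterations) and reports the
#' Wald test of the interaction coefficient. Complete or quasi-complete
#' separation (a fitted probability within 1e-6 of 0/1 with a diverging
#' coefficient) is flagged and no p-value is reported.
#'
#' @param cohort A `cohort` data frame with `status` and the exposure column.
#' @param marker Marker id or [marker_def()].
#' @param exposure Name of the binary exposure column (both levels must be
#'   present; a constant exposure is an error).
#' @param coding Genotype coding: `"dominant"` (default, 0/1 carrier),
#'   `"recessive"` or `"additive"` (dosage).
#' @return Object of class `gxe_test`: interaction log-odds `estimate`,
#'   `se`, `z`, `p`, interaction odds ratio `or`, `separation` flag and the
#'   underlying `glm` fit.
#' @export
gxe_interaction <- function(cohort, marker, exposure,
                            coding = c("dominant", "recessive", "additive")) {
  coding <- match.arg(coding)
  id <- if (inherits(marker, "marker_def")) marker$marker_id else marker
  if (!id %in% names(cohort)) stop("cohort lacks column ", id)
  if (!exposure %in% names(cohort)) stop("cohort lacks column ", exposure)
  d <- cohort[!is.na(cohort[[id]]) & !is.na(cohort[[exposure]]) &
                !is.na(cohort$status), ]
  e <- d[[exposure]]
  if (is.factor(e) || is.character(e)) e <- as.integer(factor(e)) - 1L
  e <- as.numeric(e)
  if (!all(e %in% c(0, 1))) stop("exposure must be binary (two levels)")
  if (length(unique(e)) < 2) stop("exposure is constant; both levels required")
  g <- switch(coding,
              dominant = as.numeric(d[[id]] > 0),
              recessive = as.numeric(d[[id]] == 2),
              additive = as.numeric(d[[id]]))
  y <- as.numeric(as.character(d$status) == "case")
  fit <- stats::glm(y ~ g + e + g:e, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  cf <- summary(fit)$coefficients
  sep <- any(fit$fitted.values < 1e-6 | fit$fitted.values > 1 - 1e-6) &&
    any(abs(stats::coef(fit)) > 10, na.rm = TRUE)
  est <- cf["g:e", "Estimate"]
  se <- cf["g:e", "Std. Error"]
  structure(list(marker = id, exposure = exposure, coding = coding,
                 estimate = est, se = se,
                 z = if (sep) NA_real_ else est / se,
                 p = if (sep) NA_real_ else
                   2 * stats::pnorm(-abs(est / se)),
                 or = exp(est), separation = sep, n = nrow(d), fit = fit),
            class = "gxe_test")
}

#' @export
print.gxe_test <- function(x, ...) {
  cat(sprintf("Gene-environment interaction: %s x %s (%s coding, n = %d)\n",
              x$marker, x$exposure, x$coding, x$n))
  if (x$separation) {
    cat("  separation detected; interaction estimate unreliable, no p-value\n")
  } else {
    cat(sprintf("  interaction OR = %.3f (log-odds %.4f, SE %.4f), Wald p = %.4g\n",
                x$or, x$estimate, x$se, x$p))
  }
  invisible(x)
}

#' @export
`[.snp_assoc` <- function(x, ...) {
  y <- NextMethod()
  if (is.data.frame(y)) class(y) <- "data.frame"
  y
}

#' @export
print.snp_assoc <- function(x, ...) {
  cat(sprintf("SNP association scan: %d contrasts, alpha = %g (Bonferroni m = %d)\n",
              nrow(x), attr(x, "alpha"), attr(x, "bonferroni_m")))
  d <- as.data.frame(x)
  d$OR <- ifelse(is.na(d$or), "-",
                 sprintf("%.2f (%.2f-%.2f)%s", d$or, d$ci_lower, d$ci_upper,
                         ifelse(d$or_method == "gart", "*", "")))
  d$p_disp <- display_p(d$p)
  print(d[, c("marker", "model", "contrast", "n1_exposed", "n1_reference",
              "n2_exposed", "n2_reference", "OR", "p_disp")],
        row.names = FALSE)
  if (any(d$or_method == "gart", na.rm = TRUE)) {
    cat("* Gart-adjusted logit interval (zero cell)\n")
  }
  invisible(x)
}

#' @export
summary.snp_assoc <- function(object, ...) {
  cat("Significant contrasts (nominal alpha =", attr(object, "alpha"), "):\n")
  sig <- object[object$sig_nominal, , drop = FALSE]
  if (nrow(sig) == 0) cat("  none\n") else
    print(as.data.frame(sig)[, c("marker", "model", "contrast", "or", "p",
                                 "sig_corrected")], row.names = FALSE)
  hwe <- attr(object, "hwe")
  if (length(hwe) > 0) {
    cat("Hardy-Weinberg (chi-square p / exact p):\n")
    for (id in names(hwe)) {
      g <- hwe[[id]]
      cat(sprintf("  %s: %s %.2g/%.2g, %s %.2g/%.2g\n", id,
                  names(g)[1], g[[1]]$p_chi2, g[[1]]$p_exact,
                  names(g)[2], g[[2]]$p_chi2, g[[2]]$p_exact))
    }
  }
  invisible(object)
}

# paper-style display rounding: 2 significant digits below 0.1, 2 decimals
# otherwise
display_p <- function(p) {
  ifelse(is.na(p), "-",
         ifelse(p < 0.1, formatC(signif(p, 2), format = "fg"),
                formatC(round(p, 2), format = "f", digits = 2)))
}

#' Write an association report
#'
#' Serialises a `snp_assoc` result as TSV (one row per contrast, stable
#' column order, full precision plus display-rounded `or_disp` and `p_disp`
#' columns) or JSON (nested by marker). Identical results produce
#' byte-identical TSV files.
#'
#' @param results A `snp_assoc` object (non-empty).
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("results must be a non-empty association result")
  }
  d <- as.data.frame(results)
  cols <- c("marker", "gene", "model", "contrast", "group1", "group2",
            "n1_exposed", "n1_reference", "n2_exposed", "n2_reference",
            "or", "ci_lower", "ci_upper", "or_method", "chi2", "p",
            "sig_nominal", "sig_corrected")
  d <- d[intersect(cols, names(d))]
  d$or_disp <- ifelse(is.na(d$or), "",
                      sprintf("%.2f (%.2f-%.2f)", d$or, d$ci_lower,
                              d$ci_upper))
  d$p_disp <- display_p(d$p)
  if (format == "tsv") {
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(x) formatC(x, digits = 15,
                                                 format = "g"))
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    by_marker <- split(d, d$marker)
    jsonlite::write_json(by_marker, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(jsonlite::fromJSON(path), as.data.frame))
  }
}
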