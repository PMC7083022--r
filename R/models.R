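#' Genotype counts for one group
#'
#' @param ref_hom,het,alt_hom Non-negative integer subject counts of the
#'   reference-homozygote, heterozygote and alternate-homozygote classes.
#' @return Object of class `genotype_counts` (named integer vector).
#' @export
genotype_counts <- function(ref_hom, het, alt_hom) {
  g <- c(ref_hom = ref_hom, het = het, alt_hom = alt_hom)
  if (anyNA(g) || any(g < 0) || any(g != round(g))) {
    stop("genotype counts must be non-negative integers")
  }
  if (sum(g) == 0) stop("group is empty")
  structure(as.integer(g), names = names(g), class = "genotype_counts")
}

as_genotype_counts <- function(g) {
  if (inherits(g, "genotype_counts")) return(g)
  if (is.numeric(g) && length(g) == 3) return(genotype_counts(g[1], g[2], g[3]))
  stop("cannot interpret input as genotype counts (ref-hom, het, alt-hom)")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("genotype counts: ref-hom %d, het %d, alt-hom %d (n = %d)\n",
              x[1], x[2], x[3], sum(x)))
  invisible(x)
}

inheritance_models <- c("codominant", "dominant", "recessive",
                        "overdominant", "allelic")

#' Encode case/control genotype counts under an inheritance model
#'
#' Collapses the three genotype classes of both groups into the 2x2
#' contingency table(s) of the requested inheritance model:
#' \describe{
#'   \item{codominant}{up to two tables — heterozygote vs reference
#'     homozygote, and alternate homozygote vs reference homozygote. A
#'     non-reference class empty in both groups is dropped (flagged in the
#'     `"dropped"` attribute).}
#'   \item{dominant}{(het + alt-hom) vs ref-hom.}
#'   \item{recessive}{alt-hom vs (ref-hom + het).}
#'   \item{overdominant}{het vs (ref-hom + alt-hom).}
#'   \item{allelic}{alternate vs reference allele counts; each subject
#'     contributes two alleles (the additive/allele-count contrast).}
#' }
#' Orientation: cases are group 1, the tested category is "exposed", the
#' reference category "unexposed", so odds ratios read as the odds of the
#' tested genotype in cases relative to controls.
#'
#' @param cases,controls [genotype_counts()] (or length-3 vectors).
#' @param model One of `"codominant"`, `"dominant"`, `"recessive"`,
#'   `"overdominant"`, `"allelic"`.
#' @param marker Optional [marker_def()] used to label contrasts; otherwise
#'   generic A/B labels are used.
#' @return List of contrasts, each a list with `contrast` (label string) and
#'   `table` (a [table2x2()]). Attribute `"dropped"` lists codominant classes
#'   absent from both groups.
#' @examples
#' encode_model(c(53, 60, 22), c(31, 62, 19), "dominant")
#' @export
encode_model <- function(cases, controls,
                         model = c("codominant", "dominant", "recessive",
                                   "overdominant", "allelic"),
                         marker = NULL) {
  model <- match.arg(model)
  ca <- as_genotype_counts(cases)
  co <- as_genotype_counts(controls)
  if (is.null(marker)) {
    gl <- c("A/A", "A/B", "B/B"); al <- c("A", "B")
  } else {
    stopifnot(inherits(marker, "marker_def"))
    gl <- unname(marker$genotype_labels)
    al <- c(marker$ref_allele, marker$alt_allele)
  }
  ctr <- function(contrast, a, b, c, d)
    list(contrast = contrast, table = table2x2(a, b, c, d))
  out <- switch(model,
    codominant = {
      res <- list(); dropped <- character(0)
      for (i in 2:3) {
        if (ca[i] == 0 && co[i] == 0) {
          dropped <- c(dropped, gl[i])
        } else {
          res[[length(res) + 1]] <- ctr(paste(gl[i], "vs", gl[1]),
                                        ca[i], ca[1], co[i], co[1])
        }
      }
      attr(res, "dropped") <- dropped
      res
    },
    dominant = list(ctr(paste0(gl[2], "-", gl[3], " vs ", gl[1]),
                        ca[2] + ca[3], ca[1], co[2] + co[3], co[1])),
    recessive = list(ctr(paste0(gl[3], " vs ", gl[1], "-", gl[2]),
                         ca[3], ca[1] + ca[2], co[3], co[1] + co[2])),
    overdominant = list(ctr(paste0(gl[2], " vs ", gl[1], "-", gl[3]),
                            ca[2], ca[1] + ca[3], co[2], co[1] + co[3])),
    allelic = list(ctr(paste(al[2], "vs", al[1]),
                       ca[2] + 2L * ca[3], ca[2] + 2L * ca[1],
                       co[2] + 2L * co[3], co[2] + 2L * co[1]))
  )
  out
}

#' Cochran-Armitage trend test
#'
#' A 1-df test for linear trend of case proportion across the three genotype
#' classes (scores 0, 1, 2). Provided as an additional additive-model test
#' alongside the allele-count contrast of [encode_model()].
#'
#' @param cases,controls [genotype_counts()].
#' @return An `assoc_test`.
#' @export
trend_test <- function(cases, controls) {
  ca <- as_genotype_counts(cases); co <- as_genotype_counts(controls)
  n <- as.numeric(ca + co); s <- 0:2
  N <- sum(n); R <- sum(ca)
  num <- sum(s * (as.numeric(ca) - n * R / N))
  pbar <- R / N
  den <- pbar * (1 - pbar) * (sum(s^2 * n) - sum(s * n)^2 / N)
  stat <- num^2 / den
  new_test_result(stat, 1, stats::pchisq(stat, 1, lower.tail = FALSE),
                  "Cochran-Armitage trend test")
}
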