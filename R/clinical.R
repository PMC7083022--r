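#' Smoking pack-years
#'
#' Years smoked multiplied by the current number of cigarettes smoked per
#' day, divided by 20 (one pack).
#'
#' @param years_smoked Years of smoking (>= 0).
#' @param cigarettes_per_day Current cigarettes per day (>= 0).
#' @return Pack-years; vectorised, `NA` propagates.
#' @examples
#' pack_years(10, 20)  # 10
#' @export
pack_years <- function(years_smoked, cigarettes_per_day) {
  if (any(years_smoked < 0, na.rm = TRUE) ||
      any(cigarettes_per_day < 0, na.rm = TRUE)) {
    stop("pack_years() arguments must be non-negative")
  }
  years_smoked * cigarettes_per_day / 20
}

#' Clinical variable class assignment
#'
#' Deterministic grouping of clinicopathological variables at the cutpoints
#' used in the case-only subgroup analyses; missing values propagate.
#' Schemes:
#' \describe{
#'   \item{`ki67_30`}{Ki67 percentage, `<=30%` vs `>30%` (boundary in the
#'     lower class).}
#'   \item{`age_dx_40`}{Age at diagnosis, `<=40` vs `>40`.}
#'   \item{`bmi_who`}{BMI classes `<25`, `25-30` (25 inclusive, 30
#'     exclusive), `>=30` kg/m2.}
#'   \item{`family_history`}{`"sporadic"` vs `"familial"` labels passed
#'     through (validated).}
#'   \item{`binary`}{any two-level variable passed through as a factor.}
#' }
#'
#' @param x Values of the clinical variable.
#' @param scheme Scheme name (see Details).
#' @return Factor of class labels, `NA` where `x` is missing.
#' @examples
#' binarize_clinical(c(30, 31, NA), "ki67_30")
#' @export
binarize_clinical <- function(x, scheme = c("ki67_30", "age_dx_40",
                                            "bmi_who", "family_history",
                                            "binary")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    ki67_30 = cut(as.numeric(x), c(-Inf, 30, Inf),
                  labels = c("<=30%", ">30%")),
    age_dx_40 = cut(as.numeric(x), c(-Inf, 40, Inf),
                    labels = c("<=40", ">40")),
    bmi_who = cut(as.numeric(x), c(-Inf, 25, 30, Inf), right = FALSE,
                  labels = c("<25", "25-30", ">=30")),
    family_history = {
      bad <- setdiff(unique(x[!is.na(x)]), c("sporadic", "familial"))
      if (length(bad) > 0) {
        stop("family_history values must be sporadic/familial; got: ",
             paste(bad, collapse = ", "))
      }
      factor(x, levels = c("sporadic", "familial"))
    },
    binary = {
      f <- if (is.factor(x)) x else factor(x)  # keep given level order
      if (nlevels(f) > 2) stop("variable has more than two levels")
      f
    })
}
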