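#' Example study data: genotype counts of the five-SNP breast-cancer panel
#'
#' Published per-group genotype counts from a candidate-gene case-control
#' study of breast cancer in 135 patients and 112 healthy women from
#' Northern Sardinia, for the five markers of [study_markers()]. These
#' counts are the inputs from which every per-SNP association table of the
#' study can be recomputed (see [cohort_from_counts()] and
#' [run_snp_association()]).
#'
#' @return Named list, one entry per marker, each with `cases` and
#'   `controls` length-3 genotype count vectors (ref-hom, het, alt-hom).
#' @export
bc_genotype_counts <- function() {
  list(
    rs1801133 = list(cases = c(53, 60, 22), controls = c(31, 62, 19)),
    rs1801131 = list(cases = c(66, 55, 14), controls = c(56, 49, 7)),
    rs1799782 = list(cases = c(128, 7, 0),  controls = c(102, 10, 0)),
    rs25487   = list(cases = c(64, 55, 16), controls = c(53, 43, 16)),
    rs1052133 = list(cases = c(87, 46, 2),  controls = c(70, 35, 7))
  )
}

#' Example study data: two-locus haplotype counts
#'
#' Published chromosome counts of the MTHFR (rs1801133/rs1801131) and XRCC1
#' (rs1799782/rs25487) two-locus haplotypes in the same case-control study,
#' as consumed by [haplotype_case_control()]. Haplotype labels concatenate
#' the allele at the first and second locus.
#'
#' @return Named list of two data frames (`MTHFR`, `XRCC1`) with columns
#'   `haplotype`, `cases`, `controls`.
#' @export
bc_haplotype_counts <- function() {
  list(
    MTHFR = data.frame(haplotype = c("TA", "CC", "CA", "TC"),
                       cases = c(95, 77, 75, 0),
                       controls = c(110, 70, 67, 0),
                       stringsAsFactors = FALSE),
    XRCC1 = data.frame(haplotype = c("CG", "CA", "TG", "TA"),
                       cases = c(160, 81, 6, 0),
                       controls = c(153, 83, 11, 0),
                       stringsAsFactors = FALSE)
  )
}

#' Example study data: case-only subgroup genotype counts
#'
#' Published case-only contingency counts for the clinicopathological
#' subgroup analyses: OGG1 rs1052133 against progesterone-receptor and Her2
#' status, and XRCC1 rs25487 against breast-cancer family history
#' (sporadic vs familial).
#'
#' For the PgR and Her2 tables only the recessive collapse (G/G carriers vs
#' all others) was published, so the non-G/G subjects are pooled into the
#' reference-homozygote slot and only the recessive contrast is meaningful
#' for those two entries; the family-history entry carries the full
#' three-class codominant counts.
#'
#' @return Named list with entries `pgr`, `her2`, `family_history`; each a
#'   list with `marker`, `groups` (two class labels, group 1 first) and
#'   `group1`/`group2` genotype count vectors.
#' @export
bc_subgroup_counts <- function() {
  list(
    pgr = list(marker = "rs1052133", groups = c("PgR+", "PgR-"),
               group1 = c(90, 0, 0), group2 = c(43, 0, 2)),
    her2 = list(marker = "rs1052133", groups = c("Her2+", "Her2-"),
                group1 = c(40, 0, 2), group2 = c(88, 0, 0)),
    family_history = list(marker = "rs25487",
                          groups = c("sporadic", "familial"),
                          group1 = c(31, 37, 8), group2 = c(33, 18, 8))
  )
}
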