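#' Define a biallelic PCR-RFLP marker
#'
#' A marker definition carries the allele orientation used for dosage coding
#' (dosage = count of the alternate allele) together with the expected
#' restriction-fragment signature of each genotype class, so genotypes can be
#' called from observed fragment-size patterns.
#'
#' @param marker_id Marker identifier, e.g. `"rs1801133"`.
#' @param gene Gene symbol.
#' @param ref_allele,alt_allele Single-character allele labels; must differ.
#' @param genotype_labels Character vector of length 3 naming the
#'   reference-homozygote, heterozygote and alternate-homozygote classes
#'   (e.g. `c("C/C", "C/T", "T/T")`); must be unique.
#' @param rflp_signatures Optional named list of three integer vectors (names
#'   equal to `genotype_labels`): the expected fragment lengths (bp, as a
#'   multiset) of each genotype class.
#' @param min_resolvable_fragment_bp Fragments at or below this length may be
#'   absent from an observed pattern (they can run off a gel) and are treated
#'   as optional during matching. Default 25 bp. The three signatures must
#'   remain pairwise distinct after dropping optional fragments.
#' @return An object of class `marker_def`.
#' @examples
#' marker_def("rs1801133", "MTHFR", "C", "T",
#'            genotype_labels = c("C/C", "C/T", "T/T"),
#'            rflp_signatures = list("C/C" = 201, "C/T" = c(201, 178, 23),
#'                                   "T/T" = c(178, 23)))
#' @export
marker_def <- function(marker_id, gene, ref_allele, alt_allele,
                       genotype_labels = NULL, rflp_signatures = NULL,
                       min_resolvable_fragment_bp = 25) {
  stopifnot(is.character(marker_id), length(marker_id) == 1,
            is.character(gene), length(gene) == 1)
  if (!is.character(ref_allele) || nchar(ref_allele) != 1 ||
      !is.character(alt_allele) || nchar(alt_allele) != 1) {
    stop("alleles must be single characters")
  }
  if (identical(ref_allele, alt_allele)) {
    stop("ref_allele and alt_allele must differ")
  }
  if (is.null(genotype_labels)) {
    genotype_labels <- c(paste(ref_allele, ref_allele, sep = "/"),
                         paste(ref_allele, alt_allele, sep = "/"),
                         paste(alt_allele, alt_allele, sep = "/"))
  }
  if (length(genotype_labels) != 3 || anyDuplicated(genotype_labels)) {
    stop("genotype_labels must be 3 unique strings (ref-hom, het, alt-hom)")
  }
  names(genotype_labels) <- c("ref_hom", "het", "alt_hom")
  if (!is.null(rflp_signatures)) {
    if (!is.list(rflp_signatures) || length(rflp_signatures) != 3 ||
        !setequal(names(rflp_signatures), genotype_labels)) {
      stop("rflp_signatures must be a named list keyed by the three genotype labels")
    }
    rflp_signatures <- rflp_signatures[genotype_labels]
    for (s in rflp_signatures) {
      if (!is.numeric(s) || any(s <= 0) || any(s != round(s))) {
        stop("fragment lengths must be positive integers")
      }
    }
    req <- lapply(rflp_signatures, function(s)
      sort(s[s > min_resolvable_fragment_bp]))
    if (anyDuplicated(vapply(req, paste, "", collapse = ",")) > 0) {
      stop("signatures are not distinguishable after dropping fragments <= ",
           min_resolvable_fragment_bp, " bp")
    }
  }
  structure(list(marker_id = marker_id, gene = gene,
                 ref_allele = ref_allele, alt_allele = alt_allele,
                 genotype_labels = genotype_labels,
                 rflp_signatures = rflp_signatures,
                 min_resolvable_fragment_bp = min_resolvable_fragment_bp),
            class = "marker_def")
}

#' @export
print.marker_def <- function(x, ...) {
  cat(sprintf("<marker_def> %s (%s): %s>%s; genotypes %s\n",
              x$marker_id, x$gene, x$ref_allele, x$alt_allele,
              paste(x$genotype_labels, collapse = " ")))
  if (!is.null(x$rflp_signatures)) {
    for (g in names(x$rflp_signatures)) {
      cat(sprintf("  %s: %s bp\n", g,
                  paste(x$rflp_signatures[[g]], collapse = ", ")))
    }
  }
  invisible(x)
}

#' Flip the allele orientation of a marker
#'
#' Swaps reference and alternate alleles (and the corresponding genotype
#' labels and signatures); dosages called against the flipped marker are
#' `2 - d`.
#'
#' @param marker A [marker_def()].
#' @return A `marker_def` with alleles swapped.
#' @export
flip_marker <- function(marker) {
  stopifnot(inherits(marker, "marker_def"))
  labs <- unname(marker$genotype_labels[c(3, 2, 1)])
  sig <- marker$rflp_signatures
  if (!is.null(sig)) sig <- sig[labs]
  marker_def(marker$marker_id, marker$gene,
             marker$alt_allele, marker$ref_allele,
             genotype_labels = labs, rflp_signatures = sig,
             min_resolvable_fragment_bp = marker$min_resolvable_fragment_bp)
}

#' Marker definitions of the five candidate DNA-repair / folate-pathway SNPs
#'
#' The built-in panel analysed in the bundled breast-cancer example data:
#' MTHFR C677T (rs1801133) and A1298C (rs1801131), XRCC1 Arg194Trp
#' (rs1799782) and Arg399Gln (rs25487), and OGG1 Ser326Cys (rs1052133),
#' each with the restriction-fragment signature of its PCR-RFLP assay.
#' The two XRCC1 codons are amplified in one multiplex; see
#' [call_genotype_multiplex()].
#'
#' @return Named list of five [marker_def()] objects.
#' @export
study_markers <- function() {
  list(
    rs1801133 = marker_def(
      "rs1801133", "MTHFR", "C", "T",
      genotype_labels = c("C/C", "C/T", "T/T"),
      rflp_signatures = list("C/C" = 201,
                             "C/T" = c(201, 178, 23),
                             "T/T" = c(178, 23))),
    rs1801131 = marker_def(
      "rs1801131", "MTHFR", "A", "C",
      genotype_labels = c("A/A", "A/C", "C/C"),
      rflp_signatures = list("A/A" = c(56, 31, 30, 28, 18),
                             "A/C" = c(84, 56, 31, 30, 28, 18),
                             "C/C" = c(84, 31, 30, 28, 18))),
    rs1799782 = marker_def(
      "rs1799782", "XRCC1", "C", "T",
      genotype_labels = c("C/C", "C/T", "T/T"),
      rflp_signatures = list("C/C" = c(292, 174, 21),
                             "C/T" = c(313, 292, 174, 21),
                             "T/T" = c(313, 174))),
    rs25487 = marker_def(
      "rs25487", "XRCC1", "G", "A",
      genotype_labels = c("G/G", "G/A", "A/A"),
      rflp_signatures = list("G/G" = c(374, 241),
                             "G/A" = c(615, 374, 241),
                             "A/A" = 615)),
    rs1052133 = marker_def(
      "rs1052133", "OGG1", "C", "G",
      genotype_labels = c("C/C", "C/G", "G/G"),
      rflp_signatures = list("C/C" = c(213, 21),
                             "C/G" = c(213, 164, 49, 21),
                             "G/G" = c(164, 49, 21)))
  )
}
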