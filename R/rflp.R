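#' Call a genotype from a PCR-RFLP fragment pattern
#'
#' Matches an observed multiset of restriction-fragment lengths against the
#' three genotype signatures of a marker ("virtual gel" reading). A signature
#' matches when every fragment longer than `min_resolvable_fragment_bp` is
#' observed with its multiplicity, fragments at or below that size are
#' optionally absent, and no observed fragment is unexplained by the
#' signature.
#'
#' @param marker A [marker_def()] with `rflp_signatures`.
#' @param fragments Integer vector of observed fragment lengths (bp); a
#'   multiset, so repeated lengths count.
#' @return A length-1 integer alt-allele dosage (0, 1 or 2) named by the
#'   genotype label, or `NA` (with a warning) when no signature matches.
#'   Two compatible signatures are an error, never a guess.
#' @examples
#' mk <- study_markers()$rs1801133
#' call_genotype(mk, c(178, 23))   # T/T, dosage 2
#' call_genotype(mk, 201)          # C/C, dosage 0
#' @export
call_genotype <- function(marker, fragments) {
  stopifnot(inherits(marker, "marker_def"))
  if (is.null(marker$rflp_signatures)) {
    stop("marker ", marker$marker_id, " has no RFLP signatures")
  }
  if (!is.numeric(fragments) || any(fragments <= 0) ||
      any(fragments != round(fragments))) {
    stop("fragments must be positive integers")
  }
  thr <- marker$min_resolvable_fragment_bp
  matches <- vapply(marker$rflp_signatures, function(sig)
    signature_matches(sig, fragments, thr), logical(1))
  hit <- which(matches)
  if (length(hit) == 0) {
    warning(sprintf("marker %s: pattern {%s} matches no signature; call is missing",
                    marker$marker_id, paste(sort(fragments), collapse = ", ")))
    return(stats::setNames(NA_integer_, NA_character_))
  }
  if (length(hit) > 1) {
    stop(sprintf("marker %s: ambiguous pattern, compatible with %s",
                 marker$marker_id,
                 paste(names(matches)[hit], collapse = " and ")))
  }
  stats::setNames(hit - 1L, names(matches)[hit])
}

# multiset match: required fragments (> thr) all present with multiplicity,
# optional fragments (<= thr) present at most their signature multiplicity,
# and nothing observed outside the signature.
signature_matches <- function(sig, obs, thr) {
  sig_t <- table(sig)
  obs_t <- table(obs)
  extra <- setdiff(names(obs_t), names(sig_t))
  if (length(extra) > 0) return(FALSE)
  for (f in names(sig_t)) {
    have <- if (f %in% names(obs_t)) obs_t[[f]] else 0L
    need <- sig_t[[f]]
    if (have > need) return(FALSE)
    if (have < need && as.numeric(f) > thr) return(FALSE)
  }
  TRUE
}

#' Call genotypes from a multiplex PCR-RFLP fragment pattern
#'
#' Splits a joint fragment pattern from a multiplex digest into per-marker
#' sub-patterns by fragment-length membership (each fragment is assigned to
#' the marker whose signatures contain its length), then calls each marker
#' with [call_genotype()]. Designed for the XRCC1 codon-194 / codon-399
#' multiplex of [study_markers()], whose signature fragment sets are
#' disjoint.
#'
#' @param markers List of [marker_def()] objects sharing the multiplex.
#' @param fragments Observed joint fragment-length multiset.
#' @return Named integer vector of dosages, one per marker (`NA` where a
#'   sub-pattern matches nothing).
#' @examples
#' xr <- study_markers()[c("rs1799782", "rs25487")]
#' call_genotype_multiplex(xr, c(374, 292, 241, 174))  # Arg/Arg at both codons
#' @export
call_genotype_multiplex <- function(markers, fragments) {
  stopifnot(is.list(markers), length(markers) >= 2)
  universe <- lapply(markers, function(m) unique(unlist(m$rflp_signatures)))
  ids <- vapply(markers, function(m) m$marker_id, "")
  out <- stats::setNames(rep(NA_integer_, length(markers)), ids)
  assigned <- lapply(markers, function(m) numeric(0))
  for (f in fragments) {
    owner <- which(vapply(universe, function(u) f %in% u, logical(1)))
    if (length(owner) > 1) {
      stop("fragment ", f, " bp is diagnostic for more than one marker")
    }
    if (length(owner) == 0) {
      thr <- max(vapply(markers, function(m) m$min_resolvable_fragment_bp, 0))
      if (f > thr) stop("fragment ", f, " bp matches no marker in the multiplex")
      next  # sub-resolution stray fragment: ignore
    }
    assigned[[owner]] <- c(assigned[[owner]], f)
  }
  for (i in seq_along(markers)) {
    out[i] <- call_genotype(markers[[i]], assigned[[i]])
  }
  out
}

#' Expected RFLP fragment pattern for a genotype
#'
#' Inverse of [call_genotype()]: the fragment multiset a digest of the given
#' genotype produces, optionally with sub-resolution fragments dropped (as
#' they would be lost from a gel). Used by the synthetic-data generator to
#' exercise the virtual gel caller end-to-end.
#'
#' @param marker A [marker_def()] with signatures.
#' @param dosage Alt-allele dosage 0, 1 or 2.
#' @param drop_small Drop fragments at or below
#'   `marker$min_resolvable_fragment_bp`? Default `FALSE`.
#' @return Integer vector of fragment lengths.
#' @export
rflp_fragments <- function(marker, dosage, drop_small = FALSE) {
  stopifnot(inherits(marker, "marker_def"), dosage %in% 0:2)
  sig <- marker$rflp_signatures[[dosage + 1L]]
  if (drop_small) sig <- sig[sig > marker$min_resolvable_fragment_bp]
  sig
}
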