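detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a genotype table
#'
#' Delimited text with a `subject_id` column plus one column per marker,
#' genotype cells written as `"X/Y"` allele pairs (order-insensitive:
#' `"C/T"` and `"T/C"` are the same heterozygote). Cells are converted to
#' alt-allele dosages against each marker's allele definition; an allele
#' character outside the marker's two alleles is an error, never a missing
#' call.
#'
#' @param path File path (CSV or TSV; separator auto-detected or given).
#' @param marker_defs Named list of [marker_def()] objects covering every
#'   marker column.
#' @param sep Field separator; `NULL` auto-detects.
#' @param missing Token encoding a missing genotype (default `"NA"`).
#' @return Data frame: `subject_id` plus one integer dosage column per
#'   marker; marker definitions attached as attribute `"markers"`.
#' @export
read_genotype_table <- function(path, marker_defs, sep = NULL, missing = "NA") {
  sep <- detect_sep(path, sep)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  if (!"subject_id" %in% names(d)) stop("genotype table needs a subject_id column")
  if (anyDuplicated(d$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(d$subject_id[duplicated(d$subject_id)]), collapse = ", "))
  }
  marker_cols <- setdiff(names(d), "subject_id")
  unknown <- setdiff(marker_cols, names(marker_defs))
  if (length(unknown) > 0) {
    stop("unknown marker column(s): ", paste(unknown, collapse = ", "))
  }
  out <- data.frame(subject_id = d$subject_id, stringsAsFactors = FALSE)
  for (mcol in marker_cols) {
    out[[mcol]] <- genotype_to_dosage(d[[mcol]], marker_defs[[mcol]],
                                      missing, mcol)
  }
  attr(out, "markers") <- marker_defs[marker_cols]
  out
}

genotype_to_dosage <- function(cells, marker, missing, colname) {
  dos <- rep(NA_integer_, length(cells))
  is_miss <- cells == missing | cells == ""
  todo <- which(!is_miss)
  parts <- strsplit(cells[todo], "/", fixed = TRUE)
  for (k in seq_along(todo)) {
    al <- parts[[k]]
    i <- todo[k]
    if (length(al) != 2) {
      stop(sprintf("malformed genotype '%s' (row %d, column %s)",
                   cells[i], i, colname))
    }
    bad <- setdiff(al, c(marker$ref_allele, marker$alt_allele))
    if (length(bad) > 0) {
      stop(sprintf("allele '%s' not in {%s,%s} for %s (row %d, column %s)",
                   bad[1], marker$ref_allele, marker$alt_allele,
                   marker$marker_id, i, colname))
    }
    dos[i] <- sum(al == marker$alt_allele)
  }
  dos
}

clinicopathological_fields <- c("ER", "PgR", "Her2", "Ki67", "lymph_node",
                                "family_history", "age_at_diagnosis",
                                "menopause_at_diagnosis")

#' Read a phenotype table
#'
#' Delimited text with one row per subject: a `subject_id` column, a
#' `status` column using configurable case/control labels, optional
#' covariates (age, BMI, binary exposure flags) and, for cases only, the
#' clinicopathological fields (`ER`, `PgR`, `Her2`, `Ki67`, `lymph_node`,
#' `family_history`, `age_at_diagnosis`, `menopause_at_diagnosis`). A
#' control carrying a non-missing clinicopathological value is rejected.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` auto-detects.
#' @param case_label,control_label Status labels (defaults `"case"`,
#'   `"control"`).
#' @return Data frame with `status` as a factor with levels
#'   `c("control", "case")` and all other columns typed by `read.table`.
#' @export
read_phenotype_table <- function(path, sep = NULL,
                                 case_label = "case",
                                 control_label = "control") {
  sep <- detect_sep(path, sep)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("subject_id", "status") %in% names(d))) {
    stop("phenotype table needs subject_id and status columns")
  }
  if (anyDuplicated(d$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(d$subject_id[duplicated(d$subject_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(d$status), c(case_label, control_label))
  if (length(bad) > 0) {
    stop("unknown status label(s): ", paste(bad, collapse = ", "))
  }
  d$status <- factor(ifelse(d$status == case_label, "case", "control"),
                     levels = c("control", "case"))
  clin <- intersect(clinicopathological_fields, names(d))
  for (f in clin) {
    offending <- d$status == "control" & !is.na(d[[f]]) & d[[f]] != ""
    if (any(offending)) {
      stop(sprintf("control subject %s has a value for case-only field %s",
                   d$subject_id[which(offending)[1]], f))
    }
  }
  d
}

#' Assemble a cohort table
#'
#' Joins a genotype table (from [read_genotype_table()]) with a phenotype
#' table (from [read_phenotype_table()]) on `subject_id`.
#'
#' @param genotypes Genotype data frame (dosage columns).
#' @param phenotypes Phenotype data frame.
#' @return Data frame of class `cohort`; marker definitions carried in
#'   attribute `"markers"`.
#' @export
cohort_table <- function(genotypes, phenotypes) {
  d <- merge(phenotypes, genotypes, by = "subject_id", all = FALSE,
             sort = FALSE)
  attr(d, "markers") <- attr(genotypes, "markers")
  class(d) <- c("cohort", "data.frame")
  d
}

#' Write / re-read a cohort table
#'
#' `write_cohort()` writes a cohort as TSV with genotypes re-expanded to
#' `"X/Y"` strings; `read_cohort()` reads it back through the validating
#' readers, so a round trip preserves dosages and phenotypes exactly.
#'
#' @param cohort A `cohort` data frame whose `"markers"` attribute holds the
#'   marker definitions.
#' @param path Output path (TSV).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   `cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  markers <- attr(cohort, "markers")
  if (is.null(markers)) stop("cohort has no marker definitions attached")
  d <- as.data.frame(cohort)
  for (id in names(markers)) {
    m <- markers[[id]]
    d[[id]] <- ifelse(is.na(d[[id]]), NA,
                      unname(m$genotype_labels[d[[id]] + 1L]))
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param marker_defs Named list of [marker_def()] (for `read_cohort()`).
#' @export
read_cohort <- function(path, marker_defs) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  ids <- intersect(names(marker_defs), names(d))
  geno <- d[c("subject_id", ids)]
  for (id in ids) geno[[id]] <- as.character(geno[[id]])
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(geno, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- read_genotype_table(tmp, marker_defs)
  pheno <- d[setdiff(names(d), ids)]
  pheno$status <- factor(pheno$status, levels = c("control", "case"))
  cohort_table(g, pheno)
}

#' Read genotypes from a VCF file
#'
#' Optional VCF 4.x ingestion (requires the `vcfR` package): biallelic
#' records are matched to marker definitions by the ID column, GT fields are
#' mapped to alt-allele dosages against the marker's alleles, and
#' multi-allelic records are rejected. Coordinates are not used.
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @param marker_defs Named list of [marker_def()].
#' @return Data frame `subject_id` + dosage columns, as
#'   [read_genotype_table()].
#' @export
read_genotypes_vcf <- function(path, marker_defs) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_genotypes_vcf() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  keep <- which(ids %in% names(marker_defs))
  if (length(keep) == 0) stop("no VCF records match the marker definitions")
  gt <- vcfR::extract.gt(v, element = "GT")
  out <- data.frame(subject_id = colnames(gt), stringsAsFactors = FALSE)
  for (i in keep) {
    id <- ids[i]
    m <- marker_defs[[id]]
    ref <- fix[i, "REF"]; alt <- fix[i, "ALT"]
    if (grepl(",", alt)) stop("multi-allelic record for ", id)
    if (nchar(ref) != 1 || nchar(alt) != 1) stop("non-SNP record for ", id)
    if (!setequal(c(ref, alt), c(m$ref_allele, m$alt_allele))) {
      stop(sprintf("VCF alleles %s/%s do not match marker %s (%s/%s)",
                   ref, alt, id, m$ref_allele, m$alt_allele))
    }
    alt_count <- function(x) {
      if (is.na(x)) return(NA_integer_)
      a <- strsplit(x, "[/|]")[[1]]
      if (any(a == ".")) return(NA_integer_)
      sum(a == "1")
    }
    d <- vapply(gt[i, ], alt_count, integer(1))
    # orient to the marker's alt allele
    if (alt != m$alt_allele) d <- 2L - d
    out[[id]] <- unname(d)
  }
  attr(out, "markers") <- marker_defs[intersect(names(marker_defs), ids)]
  out
}
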