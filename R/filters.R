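#' Initial sample-, variant- and patient-level filters
#'
#' The standard preprocessing applied to PanCanAtlas-style inputs before any
#' driver calling: restrict every file to primary-tumour samples, drop
#' samples flagged by the quality blacklist, drop low-purity samples from
#' the aneuploidy table only, keep PASS mutation rows (repairing zero Entrez
#' ids from the Ensembl gene id where possible), and restrict the clinical
#' table to primary malignant neoplasms present in all molecular data types.
#'
#' @name driverscape-filters
NULL

# Extract the sample axis of a supported table: column names for matrices
# (genes x samples), row names for arm-call matrices (samples x arms),
# Tumor_Sample_Barcode for MAF data.frames.
sample_axis <- function(table) {
  if (is.matrix(table)) {
    if (!is.null(attr(table, "samples_as_rows")) && attr(table, "samples_as_rows")) {
      rownames(table)
    } else {
      colnames(table)
    }
  } else if (is.data.frame(table) && "Tumor_Sample_Barcode" %in% names(table)) {
    table$Tumor_Sample_Barcode
  } else {
    stop("unsupported table type for sample filtering")
  }
}

subset_samples <- function(table, keep) {
  if (is.matrix(table)) {
    if (!is.null(attr(table, "samples_as_rows")) && attr(table, "samples_as_rows")) {
      table[keep, , drop = FALSE]
    } else {
      symbols <- attr(table, "gene_symbols")
      out <- table[, keep, drop = FALSE]
      attr(out, "gene_symbols") <- symbols
      out
    }
  } else {
    table[keep, , drop = FALSE]
  }
}

# Arm-call matrices are samples x arms; tag them so the generic sample-axis
# helpers subset the right dimension.
as_sample_rows <- function(m) {
  attr(m, "samples_as_rows") <- TRUE
  m
}

#' @rdname driverscape-filters
#' @param table a gene x sample matrix, an arm-call matrix (pass through
#'   [keep_primary_arms()]), or a MAF data.frame.
#' @return the table restricted to primary-tumour samples (type codes
#'   01/03/09).
#' @export
keep_primary <- function(table) {
  barcodes <- sample_axis(table)
  keep <- parse_barcodes(barcodes)$sample_type_code %in% PRIMARY_SAMPLE_CODES
  subset_samples(table, keep)
}

#' @rdname driverscape-filters
#' @param arms sample x arm call matrix from [read_arm_calls()].
#' @export
keep_primary_arms <- function(arms) {
  keep_primary(as_sample_rows(arms))
}

#' Remove blacklisted samples
#'
#' Drops every sample whose quality annotation flags `Do_not_use` as true.
#' Samples without an annotation are kept. Annotation barcodes may be longer
#' than the table's (aliquot vs sample level); matching truncates to the
#' shared prefix.
#'
#' @param table gene x sample matrix, arm-call matrix
#'   (`apply_quality_blacklist_arms`), or MAF data.frame.
#' @param quality data.frame from [read_quality()].
#' @return the table without blacklisted samples.
#' @export
apply_quality_blacklist <- function(table, quality) {
  barcodes <- sample_axis(table)
  flagged <- quality$aliquot_barcode[quality$Do_not_use]
  idx <- match_barcodes(barcodes, flagged)
  keep <- is.na(idx)
  if (!any(keep)) warning("quality blacklist removed every sample")
  subset_samples(table, keep)
}

#' @rdname apply_quality_blacklist
#' @export
apply_quality_blacklist_arms <- function(table, quality) {
  apply_quality_blacklist(as_sample_rows(table), quality)
}

#' Purity filter for the aneuploidy table
#'
#' Removes samples whose ABSOLUTE "Cancer DNA fraction" is below 0.5 or
#' unknown, or whose "Subclonal genome fraction" is above 0.5 or unknown.
#' Both thresholds are strict, so a fraction of exactly 0.5 passes. This
#' filter applies only to the arm-call table; other data types keep their
#' low-purity samples.
#'
#' @param arms sample x arm call matrix.
#' @param purity data.frame from [read_purity()].
#' @return the filtered arm-call matrix.
#' @export
apply_purity_filter <- function(arms, purity) {
  idx <- match_barcodes(rownames(arms), purity$sample)
  cdf <- purity[["Cancer DNA fraction"]][idx]
  sgf <- purity[["Subclonal genome fraction"]][idx]
  keep <- !is.na(cdf) & !is.na(sgf) & cdf >= 0.5 & sgf <= 0.5
  arms[keep, , drop = FALSE]
}

#' Filter a mutation table to PASS calls and repair Entrez ids
#'
#' Keeps only rows whose `FILTER` column is exactly `"PASS"`, then replaces
#' zero `Entrez_Gene_Id` values with the id mapped from the row's Ensembl
#' gene id. Zero-id rows with no mapping are retained with id 0 and counted
#' in a message.
#'
#' @param maf MAF data.frame from [read_maf()].
#' @param id_map named integer vector, Ensembl gene id -> Entrez id; may be
#'   partial or NULL.
#' @return the filtered, repaired MAF.
#' @export
filter_maf <- function(maf, id_map = NULL) {
  maf <- maf[maf$FILTER == "PASS", , drop = FALSE]
  zero <- which(maf$Entrez_Gene_Id == 0L)
  if (length(zero) > 0L && !is.null(id_map)) {
    mapped <- id_map[maf$Gene[zero]]
    ok <- !is.na(mapped)
    maf$Entrez_Gene_Id[zero[ok]] <- as.integer(mapped[ok])
    zero <- zero[!ok]
  }
  if (length(zero) > 0L) {
    message(length(zero), " PASS mutation rows retain Entrez id 0 (no Ensembl mapping)")
  }
  rownames(maf) <- NULL
  maf
}

#' Filter the clinical table
#'
#' Keeps patients whose ICD-O-3 histology code ends in "/3" (primary
#' malignant neoplasm) and who are present in all three molecular datasets
#' (mutations, copy number, arm calls). Presence is matched at the patient
#' level (first three barcode tokens).
#'
#' @param clinical data.frame from [read_clinical()].
#' @param maf_samples,cna_samples,arm_samples character vectors of sample
#'   barcodes present in the respective filtered datasets.
#' @return the filtered clinical table.
#' @export
filter_clinical <- function(clinical, maf_samples, cna_samples, arm_samples) {
  malignant <- !is.na(clinical$icd_o_3_histology) &
    grepl("/3$", clinical$icd_o_3_histology)
  pts <- clinical$bcr_patient_barcode
  keep <- malignant &
    pts %in% barcode_patient(maf_samples) &
    pts %in% barcode_patient(cna_samples) &
    pts %in% barcode_patient(arm_samples) &
    !is.na(clinical$acronym) & nzchar(clinical$acronym)
  out <- clinical[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deduplicate samples per patient
#'
#' After filtering, a patient can retain several primary samples; the
#' lexicographically smallest barcode is kept for determinism.
#'
#' @param barcodes character vector of sample barcodes.
#' @return logical vector marking the barcodes to keep.
#' @export
dedupe_patient_samples <- function(barcodes) {
  pts <- barcode_patient(barcodes)
  ord <- order(pts, barcodes)
  first <- !duplicated(pts[ord])
  keep <- logical(length(barcodes))
  keep[ord[first]] <- TRUE
  keep
}
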