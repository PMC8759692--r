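#' Read and write the TCGA-PanCanAtlas-style TSV dialects
#'
#' All pipeline inputs are tab-separated UTF-8 files with a header row,
#' mirroring the PanCanAtlas releases: an mc3-style somatic mutation table,
#' a GISTIC-thresholded gene x sample copy-number matrix, gene/miRNA x
#' sample expression matrices, a sample x chromosome-arm aneuploidy call
#' table, a clinical patient table, sample-quality annotations, an ABSOLUTE
#' purity table, and cohort-level driver lists from external algorithms.
#' Missing cells are empty strings on disk and `NA` in memory (never 0,
#' which is a meaningful call).
#'
#' Matrices are returned as base numeric matrices. Gene-keyed matrices have
#' `rownames` equal to the Entrez gene id (as character) and carry the HUGO
#' symbols in `attr(, "gene_symbols")`; the miRNA matrix is keyed by miRNA
#' name; the arm-call table has samples as rows and arm names as columns.
#'
#' @param path file path.
#' @name driverscape-io
NULL

maf_columns <- function() {
  c("Tumor_Sample_Barcode", "Hugo_Symbol", "Entrez_Gene_Id", "Gene",
    "Transcript_ID", "Variant_Classification", "HGVSp_Short", "FILTER")
}

#' @rdname driverscape-io
#' @return `read_maf()`: data.frame of mutation records with the mc3-dialect
#'   columns `Tumor_Sample_Barcode`, `Hugo_Symbol`, `Entrez_Gene_Id`,
#'   `Gene` (Ensembl gene id), `Transcript_ID`, `Variant_Classification`,
#'   `HGVSp_Short`, `FILTER`.
#' @export
read_maf <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = setdiff(maf_columns(), "Entrez_Gene_Id")),
                          na.strings = NULL, data.table = FALSE)
  missing_cols <- setdiff(maf_columns(), names(dt))
  if (length(missing_cols) > 0L) {
    stop("MAF file ", path, " lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  dt$Entrez_Gene_Id <- as.integer(dt$Entrez_Gene_Id)
  dt[maf_columns()]
}

#' @rdname driverscape-io
#' @param maf data.frame in the mc3 dialect.
#' @export
write_maf <- function(maf, path) {
  data.table::fwrite(maf[maf_columns()], path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

# Shared reader for gene x sample numeric matrices. id_cols are the leading
# annotation columns; key_col supplies rownames.
read_matrix_tsv <- function(path, id_cols, key_col, symbol_col = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "",
                          data.table = FALSE, check.names = FALSE)
  missing_cols <- setdiff(id_cols, names(dt))
  if (length(missing_cols) > 0L) {
    stop("matrix file ", path, " lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  sample_cols <- setdiff(names(dt), id_cols)
  m <- as.matrix(dt[sample_cols])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(dt[[key_col]])
  if (anyDuplicated(rownames(m))) {
    keep <- !duplicated(rownames(m))
    warning("dropping ", sum(!keep), " duplicate gene rows in ", path)
    m <- m[keep, , drop = FALSE]
    dt <- dt[keep, , drop = FALSE]
  }
  if (!is.null(symbol_col)) {
    attr(m, "gene_symbols") <- stats::setNames(as.character(dt[[symbol_col]]), rownames(m))
  }
  m
}

write_matrix_tsv <- function(m, path, id_frame) {
  df <- cbind(id_frame, as.data.frame(m, check.names = FALSE),
              stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' @rdname driverscape-io
#' @return `read_cna_matrix()`: GISTIC-thresholded calls in {-2,-1,0,1,2}
#'   keyed by Entrez id (`Locus ID` column), symbols in
#'   `attr(, "gene_symbols")`.
#' @export
read_cna_matrix <- function(path) {
  read_matrix_tsv(path, id_cols = c("Gene Symbol", "Locus ID"),
                  key_col = "Locus ID", symbol_col = "Gene Symbol")
}

#' @rdname driverscape-io
#' @param m numeric matrix as returned by the corresponding reader.
#' @export
write_cna_matrix <- function(m, path) {
  symbols <- attr(m, "gene_symbols")
  if (is.null(symbols)) symbols <- rownames(m)
  id <- data.frame("Gene Symbol" = unname(symbols[rownames(m)]),
                   "Locus ID" = rownames(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_matrix_tsv(m, path, id)
}

#' @rdname driverscape-io
#' @return `read_expression_matrix()`: gene x sample expression keyed by
#'   Entrez id; the on-disk `gene_id` column is `"SYMBOL|ENTREZ"`.
#' @export
read_expression_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "",
                          data.table = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(dt)) stop("expression file ", path, " lacks 'gene_id'")
  parts <- strsplit(dt$gene_id, "|", fixed = TRUE)
  symbols <- vapply(parts, `[`, "", 1L)
  entrez <- vapply(parts, function(p) p[length(p)], "")
  m <- as.matrix(dt[setdiff(names(dt), "gene_id")])
  storage.mode(m) <- "double"
  rownames(m) <- entrez
  if (anyDuplicated(entrez)) {
    keep <- !duplicated(entrez)
    warning("dropping ", sum(!keep), " duplicate gene rows in ", path)
    m <- m[keep, , drop = FALSE]
    symbols <- symbols[keep]
  }
  attr(m, "gene_symbols") <- stats::setNames(symbols, rownames(m))
  m
}

#' @rdname driverscape-io
#' @export
write_expression_matrix <- function(m, path) {
  symbols <- attr(m, "gene_symbols")
  if (is.null(symbols)) symbols <- rownames(m)
  id <- data.frame(gene_id = paste0(unname(symbols[rownames(m)]), "|", rownames(m)),
                   stringsAsFactors = FALSE)
  write_matrix_tsv(m, path, id)
}

#' @rdname driverscape-io
#' @return `read_mirna_matrix()`: miRNA x sample expression keyed by miRNA
#'   name (`Genes` column).
#' @export
read_mirna_matrix <- function(path) {
  read_matrix_tsv(path, id_cols = "Genes", key_col = "Genes")
}

#' @rdname driverscape-io
#' @export
write_mirna_matrix <- function(m, path) {
  write_matrix_tsv(m, path, data.frame(Genes = rownames(m), stringsAsFactors = FALSE))
}

#' @rdname driverscape-io
#' @return `read_arm_calls()`: sample x arm integer matrix over {-1,0,1,NA},
#'   rownames are sample barcodes (`Sample` column), colnames arm names
#'   such as `"1p"`, `"13q"`.
#' @export
read_arm_calls <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "",
                          data.table = FALSE, check.names = FALSE)
  if (!"Sample" %in% names(dt)) stop("arm-call file ", path, " lacks 'Sample'")
  m <- as.matrix(dt[setdiff(names(dt), "Sample")])
  storage.mode(m) <- "integer"
  ok <- m %in% c(-1L, 0L, 1L) | is.na(m)
  if (!all(ok)) stop("arm-call file ", path, " contains values outside {-1,0,1}")
  rownames(m) <- dt$Sample
  m
}

#' @rdname driverscape-io
#' @export
write_arm_calls <- function(m, path) {
  write_matrix_tsv(m, path, data.frame(Sample = rownames(m), stringsAsFactors = FALSE))
}

clinical_columns <- function() {
  c("bcr_patient_barcode", "acronym", "gender",
    "age_at_initial_pathologic_diagnosis", "pathologic_stage",
    "clinical_stage", "pathologic_T", "clinical_T", "icd_o_3_histology")
}

#' @rdname driverscape-io
#' @return `read_clinical()`: patient-level clinical table with columns
#'   `bcr_patient_barcode`, `acronym`, `gender`,
#'   `age_at_initial_pathologic_diagnosis`, `pathologic_stage`,
#'   `clinical_stage`, `pathologic_T`, `clinical_T`, `icd_o_3_histology`.
#' @export
read_clinical <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "",
                          colClasses = list(character = setdiff(clinical_columns(),
                                            "age_at_initial_pathologic_diagnosis")),
                          data.table = FALSE)
  missing_cols <- setdiff(clinical_columns(), names(dt))
  if (length(missing_cols) > 0L) {
    stop("clinical file ", path, " lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  dt$age_at_initial_pathologic_diagnosis <-
    as.integer(dt$age_at_initial_pathologic_diagnosis)
  dt[clinical_columns()]
}

#' @rdname driverscape-io
#' @param clinical data.frame in the clinical dialect.
#' @export
write_clinical <- function(clinical, path) {
  data.table::fwrite(clinical[clinical_columns()], path, sep = "\t",
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname driverscape-io
#' @return `read_quality()`: sample-quality annotations with columns
#'   `aliquot_barcode` and `Do_not_use` (logical).
#' @export
read_quality <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "",
                          colClasses = list(character = c("aliquot_barcode", "Do_not_use")),
                          data.table = FALSE)
  if (!all(c("aliquot_barcode", "Do_not_use") %in% names(dt))) {
    stop("quality file ", path, " lacks 'aliquot_barcode'/'Do_not_use'")
  }
  dt$Do_not_use <- tolower(dt$Do_not_use) %in% "true"
  dt[c("aliquot_barcode", "Do_not_use")]
}

#' @rdname driverscape-io
#' @param quality data.frame with `aliquot_barcode` and logical `Do_not_use`.
#' @export
write_quality <- function(quality, path) {
  out <- data.frame(aliquot_barcode = quality$aliquot_barcode,
                    Do_not_use = ifelse(quality$Do_not_use, "True", "False"),
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

purity_columns <- function() {
  c("sample", "Cancer DNA fraction", "Subclonal genome fraction")
}

#' @rdname driverscape-io
#' @return `read_purity()`: ABSOLUTE purity calls with columns `sample`,
#'   `Cancer DNA fraction`, `Subclonal genome fraction` (fractions in
#'   [0,1] or NA).
#' @export
read_purity <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "",
                          data.table = FALSE, check.names = FALSE)
  missing_cols <- setdiff(purity_columns(), names(dt))
  if (length(missing_cols) > 0L) {
    stop("purity file ", path, " lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in purity_columns()[-1L]) {
    dt[[col]] <- as.numeric(dt[[col]])
    bad <- !is.na(dt[[col]]) & (dt[[col]] < 0 | dt[[col]] > 1)
    if (any(bad)) stop("purity file ", path, ": '", col, "' outside [0,1]")
  }
  dt[purity_columns()]
}

#' @rdname driverscape-io
#' @param purity data.frame in the purity dialect.
#' @export
write_purity <- function(purity, path) {
  data.table::fwrite(purity[purity_columns()], path, sep = "\t",
                     quote = FALSE, na = "")
  invisible(path)
}

driver_list_columns <- function() {
  c("source", "level", "scope", "cohort", "Hugo_Symbol", "Entrez_Gene_Id",
    "Transcript_ID", "Substitution", "q_value")
}

#' @rdname driverscape-io
#' @return `read_driver_list()`: cohort-level driver predictions from an
#'   external algorithm; columns `source`, `level` (gene/mutation), `scope`
#'   (pancancer/cohort), `cohort`, `Hugo_Symbol`, `Entrez_Gene_Id`,
#'   `Transcript_ID`, `Substitution`, `q_value`.
#' @export
read_driver_list <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "",
                          colClasses = list(character = setdiff(driver_list_columns(),
                                            c("Entrez_Gene_Id", "q_value"))),
                          data.table = FALSE)
  missing_cols <- setdiff(driver_list_columns(), names(dt))
  if (length(missing_cols) > 0L) {
    stop("driver list ", path, " lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  dt$Entrez_Gene_Id <- as.integer(dt$Entrez_Gene_Id)
  dt$q_value <- as.numeric(dt$q_value)
  lv <- unique(dt$level)
  if (!all(lv %in% c("gene", "mutation"))) {
    stop("driver list ", path, ": level must be 'gene' or 'mutation'")
  }
  dt[driver_list_columns()]
}

#' @rdname driverscape-io
#' @param driver_list data.frame in the driver-list dialect.
#' @export
write_driver_list <- function(driver_list, path) {
  data.table::fwrite(driver_list[driver_list_columns()], path, sep = "\t",
                     quote = FALSE, na = "")
  invisible(path)
}
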