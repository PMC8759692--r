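#' Parse TCGA sample barcodes
#'
#' A TCGA barcode is a dash-separated string such as
#' `"TCGA-OR-A5J1-01A-11D-A29I-10"`. The first three tokens identify the
#' patient; the first two characters of the fourth token are the sample type
#' code (`"01"` primary solid tumour, `"06"` metastasis, `"10"` blood
#' normal, ...).
#'
#' @param barcodes character vector of full barcodes.
#' @return `parse_barcodes()` returns a data.frame with columns
#'   `full_barcode`, `patient_id` and `sample_type_code`.
#' @examples
#' parse_barcodes("TCGA-AB-0001-01A")
#' @export
parse_barcodes <- function(barcodes) {
  tokens <- strsplit(as.character(barcodes), "-", fixed = TRUE)
  n_tok <- lengths(tokens)
  bad <- which(n_tok < 4L)
  if (length(bad) > 0L) {
    stop("malformed barcode (fewer than 4 tokens) at row ",
         paste(utils::head(bad, 5L), collapse = ", "),
         ": ", paste(utils::head(barcodes[bad], 5L), collapse = ", "))
  }
  patient_id <- vapply(tokens, function(t) paste(t[1:3], collapse = "-"), "")
  sample_type_code <- vapply(tokens, function(t) substr(t[4L], 1L, 2L), "")
  data.frame(full_barcode = as.character(barcodes),
             patient_id = patient_id,
             sample_type_code = sample_type_code,
             stringsAsFactors = FALSE)
}

#' @rdname parse_barcodes
#' @return `barcode_patient()` returns the patient id (first three tokens);
#'   tolerant of barcodes that are already patient-level.
#' @export
barcode_patient <- function(barcodes) {
  tokens <- strsplit(as.character(barcodes), "-", fixed = TRUE)
  vapply(tokens, function(t) paste(t[seq_len(min(3L, length(t)))], collapse = "-"), "")
}

#' Keep primary-tumour samples
#'
#' Retains barcodes whose sample type code is 01 (primary solid tumour),
#' 03 (primary blood-derived cancer) or 09 (primary bone marrow), the three
#' primary-tumour codes; input order is preserved.
#'
#' @param barcodes character vector of full TCGA barcodes.
#' @return the subset of `barcodes` that are primary-tumour samples.
#' @examples
#' filter_primary_samples(c("TCGA-AB-0001-01A", "TCGA-AB-0001-06A"))
#' @export
filter_primary_samples <- function(barcodes) {
  if (length(barcodes) == 0L) return(barcodes[0L])
  parsed <- parse_barcodes(barcodes)
  barcodes[parsed$sample_type_code %in% PRIMARY_SAMPLE_CODES]
}

PRIMARY_SAMPLE_CODES <- c("01", "03", "09")

# Map sample barcodes of one table onto those of another by truncating both
# to their shared prefix length (TCGA files carry barcodes of different
# depths). Returns an integer index into `b` for each element of `a`
# (NA where unmatched); duplicate matches resolve to the lexicographically
# smallest full barcode in `b`.
match_barcodes <- function(a, b) {
  len <- min(min(nchar(a), .Machine$integer.max), min(nchar(b), .Machine$integer.max))
  if (!is.finite(len) || length(a) == 0L || length(b) == 0L) {
    return(rep(NA_integer_, length(a)))
  }
  a_key <- substr(a, 1L, len)
  b_key <- substr(b, 1L, len)
  ord <- order(b_key, b)              # smallest full barcode wins per key
  first <- !duplicated(b_key[ord])
  lookup <- ord[first]
  names(lookup) <- b_key[ord][first]
  idx <- lookup[a_key]
  unname(idx)
}
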