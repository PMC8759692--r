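# Independent reference implementations used as oracles; deliberately
# written from first principles, not by calling the package's code paths.

# BH step-up: largest k with p_(k) <= k*q/m rejects the k smallest p-values.
bh_stepup_ref <- function(p, q) {
  m <- length(p)
  if (m == 0L) return(logical(0L))
  o <- order(p)
  ok <- which(p[o] <= q * seq_len(m) / m)
  pass <- rep(FALSE, m)
  if (length(ok) > 0L) pass[o[seq_len(max(ok))]] <- TRUE
  pass
}

# Brute-force NSEI/HISR per gene from raw MAF rows, re-stating the variant
# category sets independently of classify_variant().
brute_gene_scores <- function(maf) {
  inact <- c("Frame_Shift_Del", "Frame_Shift_Ins", "Nonsense_Mutation",
             "Nonstop_Mutation", "Translation_Start_Site")
  hyper <- c("De_novo_Start_InFrame", "In_Frame_Del", "In_Frame_Ins",
             "Missense_Mutation")
  silent <- c("De_novo_Start_OutOfFrame", "Silent")
  genes <- sort(unique(maf$Entrez_Gene_Id))
  out <- data.frame(Entrez_Gene_Id = genes, H = 0L, I = 0L, P = 0L,
                    NSEI = NA_real_, HISR = NA_real_)
  for (k in seq_along(genes)) {
    vc <- maf$Variant_Classification[maf$Entrez_Gene_Id == genes[k]]
    H <- sum(vc %in% hyper); I <- sum(vc %in% inact); P <- sum(vc %in% silent)
    out$H[k] <- H; out$I[k] <- I; out$P[k] <- P
    out$NSEI[k] <- (H + I + 1) / (P + 1)
    out$HISR[k] <- (H + 1) / (I + 1)
  }
  out
}

# Minimal MAF builder.
make_maf <- function(barcode, hugo, entrez, vc, filter = "PASS",
                     ensembl = NULL, transcript = NULL, sub = NULL) {
  n <- max(length(barcode), length(hugo), length(entrez), length(vc))
  data.frame(
    Tumor_Sample_Barcode = rep_len(barcode, n),
    Hugo_Symbol = rep_len(hugo, n),
    Entrez_Gene_Id = as.integer(rep_len(entrez, n)),
    Gene = rep_len(if (is.null(ensembl)) sprintf("ENSG%05d", rep_len(entrez, n)) else ensembl, n),
    Transcript_ID = rep_len(if (is.null(transcript)) sprintf("ENST%05d", rep_len(entrez, n)) else transcript, n),
    Variant_Classification = rep_len(vc, n),
    HGVSp_Short = rep_len(if (is.null(sub)) "p.A1B" else sub, n),
    FILTER = rep_len(filter, n),
    stringsAsFactors = FALSE)
}

# Minimal clinical builder (one row per patient).
make_clinical <- function(patient, acronym, gender = "FEMALE", age = 60L,
                          stage = "Stage II", histology = "8140/3") {
  n <- length(patient)
  data.frame(
    bcr_patient_barcode = patient,
    acronym = rep_len(acronym, n),
    gender = rep_len(gender, n),
    age_at_initial_pathologic_diagnosis = as.integer(rep_len(age, n)),
    pathologic_stage = rep_len(stage, n),
    clinical_stage = NA_character_, pathologic_T = NA_character_,
    clinical_T = NA_character_,
    icd_o_3_histology = rep_len(histology, n),
    stringsAsFactors = FALSE)
}

# Gene x sample matrix with Entrez rownames and symbol attribute.
make_gene_matrix <- function(values, entrez, samples, symbols = NULL) {
  m <- matrix(values, nrow = length(entrez), ncol = length(samples),
              dimnames = list(as.character(entrez), samples))
  if (is.null(symbols)) symbols <- paste0("G", entrez)
  attr(m, "gene_symbols") <- stats::setNames(symbols, rownames(m))
  m
}

# Driver-list row builder.
make_driver_list <- function(source, level, scope, cohort, hugo, entrez,
                             transcript = NA_character_, sub = NA_character_,
                             q = 0.01) {
  n <- max(length(hugo), length(entrez), length(cohort))
  data.frame(source = source, level = level, scope = rep_len(scope, n),
             cohort = rep_len(cohort, n), Hugo_Symbol = rep_len(hugo, n),
             Entrez_Gene_Id = as.integer(rep_len(entrez, n)),
             Transcript_ID = rep_len(transcript, n),
             Substitution = rep_len(sub, n), q_value = rep_len(q, n),
             stringsAsFactors = FALSE)
}
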