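#' Convert a cohort-level driver gene list to patient-level pairs
#'
#' Keeps MAF rows whose Entrez id appears in the driver list, whose
#' patient's cohort (acronym via the clinical table) matches the entry's
#' cohort (or the list is pancancer-scope), and whose variant class is
#' protein-altering (any of the nonsynonymous MAF classes). Emits unique
#' (barcode, Entrez) pairs. Rows for patients absent from the clinical
#' table are skipped with a message.
#'
#' @param driver_list data.frame in the driver-list dialect
#'   ([read_driver_list()]) with `level == "gene"`.
#' @param maf filtered MAF data.frame.
#' @param clinical filtered clinical data.frame.
#' @return data.frame `Tumor_Sample_Barcode`, `Entrez_Gene_Id`,
#'   `Hugo_Symbol`.
#' @export
match_gene_list <- function(driver_list, maf, clinical) {
  stopifnot(all(driver_list$level == "gene"))
  match_sna_rows(driver_list, maf, clinical, by_mutation = FALSE)
}

#' Convert a cohort-level driver mutation list to patient-level pairs
#'
#' As [match_gene_list()] but the join key is the (Ensembl transcript id,
#' substitution) pair, so the mutation-level granularity of algorithms like
#' CHASMplus is preserved; emitted pairs still collapse to
#' (barcode, Entrez).
#'
#' @inheritParams match_gene_list
#' @export
match_mutation_list <- function(driver_list, maf, clinical) {
  stopifnot(all(driver_list$level == "mutation"))
  match_sna_rows(driver_list, maf, clinical, by_mutation = TRUE)
}

match_sna_rows <- function(driver_list, maf, clinical, by_mutation) {
  empty <- data.frame(Tumor_Sample_Barcode = character(),
                      Entrez_Gene_Id = integer(), Hugo_Symbol = character(),
                      stringsAsFactors = FALSE)
  if (nrow(driver_list) == 0L || nrow(maf) == 0L) return(empty)
  cohort_of <- stats::setNames(clinical$acronym, clinical$bcr_patient_barcode)
  pt <- barcode_patient(maf$Tumor_Sample_Barcode)
  maf_cohort <- cohort_of[pt]
  skipped <- is.na(maf_cohort)
  if (any(skipped)) {
    message(sum(skipped), " mutation rows skipped: patient absent from clinical table")
  }
  keep_class <- maf$Variant_Classification %in% NONSYNONYMOUS_CLASSES

  if (by_mutation) {
    key_list <- paste(driver_list$Transcript_ID, driver_list$Substitution, sep = "\r")
    key_maf <- paste(maf$Transcript_ID, maf$HGVSp_Short, sep = "\r")
  } else {
    key_list <- as.character(driver_list$Entrez_Gene_Id)
    key_maf <- as.character(maf$Entrez_Gene_Id)
  }
  hit <- match(key_maf, key_list)
  pancancer <- driver_list$scope[hit] == "pancancer"
  cohort_ok <- !is.na(hit) &
    (pancancer | (!is.na(maf_cohort) & driver_list$cohort[hit] == maf_cohort))
  sel <- which(!skipped & keep_class & cohort_ok)
  if (length(sel) == 0L) return(empty)
  out <- unique(data.frame(Tumor_Sample_Barcode = maf$Tumor_Sample_Barcode[sel],
                           Entrez_Gene_Id = maf$Entrez_Gene_Id[sel],
                           Hugo_Symbol = maf$Hugo_Symbol[sel],
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Convert a driver list to patient-level pairs via copy number
#'
#' Emits (barcode, Entrez) pairs for listed genes carrying a nonzero
#' thresholded CNA call ({-2,-1,1,2}) in cohort-matched patients.
#'
#' @param driver_list data.frame with gene-level entries.
#' @param cna gene x sample thresholded CNA matrix.
#' @param clinical filtered clinical data.frame.
#' @return data.frame `Tumor_Sample_Barcode`, `Entrez_Gene_Id`,
#'   `Hugo_Symbol`.
#' @export
match_cna <- function(driver_list, cna, clinical) {
  empty <- data.frame(Tumor_Sample_Barcode = character(),
                      Entrez_Gene_Id = integer(), Hugo_Symbol = character(),
                      stringsAsFactors = FALSE)
  genes <- intersect(as.character(driver_list$Entrez_Gene_Id), rownames(cna))
  if (length(genes) == 0L) return(empty)
  cohort_of <- stats::setNames(clinical$acronym, clinical$bcr_patient_barcode)
  col_cohort <- cohort_of[barcode_patient(colnames(cna))]
  symbols <- attr(cna, "gene_symbols")
  rows <- list()
  for (g in genes) {
    entries <- driver_list[as.character(driver_list$Entrez_Gene_Id) == g, ,
                           drop = FALSE]
    vals <- cna[g, ]
    nonzero <- !is.na(vals) & vals != 0
    cohort_ok <- rep(FALSE, ncol(cna))
    for (j in seq_len(nrow(entries))) {
      if (entries$scope[j] == "pancancer") {
        cohort_ok <- cohort_ok | !is.na(col_cohort)
      } else {
        cohort_ok <- cohort_ok | (!is.na(col_cohort) & col_cohort == entries$cohort[j])
      }
    }
    sel <- colnames(cna)[nonzero & cohort_ok]
    if (length(sel) > 0L) {
      rows[[g]] <- data.frame(Tumor_Sample_Barcode = sel,
                              Entrez_Gene_Id = as.integer(g),
                              Hugo_Symbol = if (!is.null(symbols)) unname(symbols[g]) else g,
                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Combine the SNA- and CNA-derived pairs of one source
#'
#' Set union keyed on (barcode, Entrez); duplicate pairs collapse to one.
#'
#' @param sna_pairs,cna_pairs data.frames of pairs.
#' @return unique combined data.frame of pairs.
#' @export
combine_source <- function(sna_pairs, cna_pairs) {
  out <- rbind(sna_pairs, cna_pairs)
  out <- out[!duplicated(out[c("Tumor_Sample_Barcode", "Entrez_Gene_Id")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus of per-source patient-level pairs
#'
#' Keeps (barcode, Entrez) pairs present in at least `min_sources` of the
#' supplied per-source pair sets and records in how many they appear.
#'
#' @param pair_sets list of data.frames of pairs (one per source).
#' @param min_sources minimum number of supporting sources (default 2).
#' @return data.frame `Tumor_Sample_Barcode`, `Entrez_Gene_Id`,
#'   `Hugo_Symbol`, `source_count`.
#' @export
consensus_pairs <- function(pair_sets, min_sources = 2L) {
  if (length(pair_sets) < min_sources) {
    stop("need at least ", min_sources, " sources, got ", length(pair_sets))
  }
  keyed <- lapply(pair_sets, function(p) {
    p <- p[!duplicated(p[c("Tumor_Sample_Barcode", "Entrez_Gene_Id")]), ,
           drop = FALSE]
    p
  })
  all_pairs <- do.call(rbind, keyed)
  key <- paste(all_pairs$Tumor_Sample_Barcode, all_pairs$Entrez_Gene_Id)
  counts <- table(key)
  first <- !duplicated(key)
  out <- all_pairs[first, , drop = FALSE]
  out$source_count <- as.integer(counts[paste(out$Tumor_Sample_Barcode,
                                              out$Entrez_Gene_Id)])
  out <- out[out$source_count >= min_sources, , drop = FALSE]
  out <- out[order(out$Tumor_Sample_Barcode, out$Entrez_Gene_Id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate consensus pairs for classification
#'
#' Attaches the per-patient hyperactivating/inactivating counts (0 when the
#' pair has no SNA record), the gene's HISR (missing when the gene was not
#' scored), and the expression-validated CNA status (0 when absent).
#'
#' @param pairs data.frame from [consensus_pairs()].
#' @param tally per-patient counts from [tally_sna()].
#' @param gene_scores data.frame with `Entrez_Gene_Id` and `HISR` (the
#'   low-count-filtered gene table).
#' @param validated_cna matrix from [validate_cna()].
#' @return `pairs` with columns `H`, `I`, `HISR`, `cna` added.
#' @export
annotate_pairs <- function(pairs, tally, gene_scores, validated_cna) {
  key <- paste(pairs$Tumor_Sample_Barcode, pairs$Entrez_Gene_Id)
  tkey <- paste(tally$Tumor_Sample_Barcode, tally$Entrez_Gene_Id)
  ti <- match(key, tkey)
  pairs$H <- ifelse(is.na(ti), 0L, tally$H[ti])
  pairs$I <- ifelse(is.na(ti), 0L, tally$I[ti])
  pairs$HISR <- gene_scores$HISR[match(pairs$Entrez_Gene_Id,
                                       gene_scores$Entrez_Gene_Id)]
  ri <- match(as.character(pairs$Entrez_Gene_Id), rownames(validated_cna))
  ci <- match_barcodes(pairs$Tumor_Sample_Barcode, colnames(validated_cna))
  cna <- rep(0L, nrow(pairs))
  ok <- !is.na(ri) & !is.na(ci)
  vals <- validated_cna[cbind(ri[ok], ci[ok])]
  cna[ok] <- ifelse(is.na(vals), 0L, as.integer(vals))
  pairs$cna <- cna
  pairs
}

DRIVER_EVENT_CLASSES <- c("SNA_oncogene", "CNA_oncogene", "mixed_oncogene",
                          "SNA_suppressor", "CNA_suppressor", "mixed_suppressor")
GENE_EVENT_CLASSES <- c(DRIVER_EVENT_CLASSES, "passenger", "low_probability")
ANEUPLOIDY_EVENT_CLASSES <- c("DCL", "DCG", "DAL", "DAG")

#' Classify a patient-gene pair into a driver event class
#'
#' The classification rules, with N = H + I the number of nonsynonymous
#' SNAs in the pair:
#' \itemize{
#'   \item N>=1, I=0, HISR>5, cna=0: SNA-based oncogene (1 event)
#'   \item N=0, HISR>5, cna in {1,2}: CNA-based oncogene (1 event)
#'   \item N>=1, I=0, HISR>5, cna in {1,2}: mixed oncogene (1 event)
#'   \item N>=1, HISR<=5, cna=0: SNA-based tumour suppressor (1 event)
#'   \item N=0, HISR<=5, cna in {-1,-2}: CNA-based tumour suppressor (1 event)
#'   \item N>=1, HISR<=5, cna in {-1,-2}: mixed tumour suppressor (1 event)
#'   \item N=0, cna=0: passenger (0 events)
#'   \item all the rest: low-probability driver (0 events)
#' }
#' A missing HISR fails both the ">5" and "<=5" tests, so an altered pair
#' in an unscored gene is a low-probability driver and an unaltered one a
#' passenger.
#'
#' @param H,I integer counts (vectorized).
#' @param HISR numeric, may be NA.
#' @param cna integer in {-2,-1,0,1,2}.
#' @return data.frame `event_class` (one of the eight classes) and
#'   `event_count` (1 for the six driver classes, else 0).
#' @examples
#' classify_pair(H = 1, I = 0, HISR = 8, cna = 0)   # SNA_oncogene, 1
#' @export
classify_pair <- function(H, I, HISR, cna) {
  n <- max(length(H), length(I), length(HISR), length(cna))
  H <- rep_len(H, n); I <- rep_len(I, n)
  HISR <- rep_len(HISR, n); cna <- rep_len(cna, n)
  N <- H + I
  onc <- !is.na(HISR) & HISR > 5
  sup <- !is.na(HISR) & HISR <= 5
  amp <- cna %in% c(1L, 2L)
  del <- cna %in% c(-1L, -2L)
  cls <- rep("low_probability", n)
  cls[N >= 1 & I == 0 & onc & cna == 0] <- "SNA_oncogene"
  cls[N == 0 & onc & amp] <- "CNA_oncogene"
  cls[N >= 1 & I == 0 & onc & amp] <- "mixed_oncogene"
  cls[N >= 1 & sup & cna == 0] <- "SNA_suppressor"
  cls[N == 0 & sup & del] <- "CNA_suppressor"
  cls[N >= 1 & sup & del] <- "mixed_suppressor"
  cls[N == 0 & cna == 0] <- "passenger"
  data.frame(event_class = cls,
             event_count = as.integer(cls %in% DRIVER_EVENT_CLASSES))
}

#' Normalize a tumour stage string to I-IV
#'
#' Strips sub-stage letters ("Stage IA" -> "I"); T-category strings map
#' T1-T4 (with sub-letters) to I-IV. Anything else is missing.
#'
#' @param stage character vector of stage or T-category strings.
#' @return character vector over c("I","II","III","IV", NA).
#' @export
normalize_stage <- function(stage) {
  s <- toupper(trimws(ifelse(is.na(stage), "", stage)))
  s <- sub("^STAGE\\s*", "", s)
  out <- rep(NA_character_, length(s))
  roman <- regmatches(s, regexpr("^(IV|III|II|I)", s))
  has_roman <- grepl("^(IV|III|II|I)", s)
  out[has_roman] <- roman
  tnum <- grepl("^T[1-4]", s)
  out[tnum] <- c("I", "II", "III", "IV")[as.integer(substr(s[tnum], 2L, 2L))]
  out
}

#' Ten-year age bins
#'
#' Decade bins with open ends: "<20", "20-29", ..., "70-79", ">=80".
#'
#' @param age integer ages in years.
#' @return character vector of bin labels (NA for missing ages).
#' @export
age_bin <- function(age) {
  out <- rep(NA_character_, length(age))
  ok <- !is.na(age)
  a <- age[ok]
  lab <- ifelse(a < 20, "<20",
         ifelse(a >= 80, ">=80",
                paste0((a %/% 10) * 10, "-", (a %/% 10) * 10 + 9)))
  out[ok] <- lab
  out
}

#' Per-patient driver event counts
#'
#' Tallies the classified gene-level pairs and the patient-level aneuploidy
#' events into one row per clinical patient over the 12 event classes (six
#' gene-level driver classes, passenger and low-probability tallies kept
#' for reference but excluded from the total, and DCL/DCG/DAL/DAG).
#' Clinical patients without any event appear with all-zero counts. The
#' stage is `pathologic_stage`, falling back to `clinical_stage`,
#' `pathologic_T`, then `clinical_T`, then normalized to I-IV.
#'
#' @param classified data.frame of annotated pairs with `event_class`
#'   (from [classify_pair()]).
#' @param aneuploidy_events data.frame from [aneuploidy_patient_events()].
#' @param clinical filtered clinical data.frame.
#' @return data.frame with one row per patient: `patient_id`, `cohort`,
#'   `gender`, `age`, `stage`, the 12 class counts, and `total` (driver
#'   classes + aneuploidy only).
#' @export
count_events <- function(classified, aneuploidy_events, clinical) {
  patients <- clinical$bcr_patient_barcode
  base <- data.frame(patient_id = patients,
                     cohort = clinical$acronym,
                     gender = tolower(ifelse(is.na(clinical$gender), "",
                                             clinical$gender)),
                     age = clinical$age_at_initial_pathologic_diagnosis,
                     stringsAsFactors = FALSE)
  base$gender[!base$gender %in% c("male", "female")] <- NA_character_
  stage_raw <- clinical$pathologic_stage
  for (alt in c("clinical_stage", "pathologic_T", "clinical_T")) {
    use <- is.na(stage_raw) | !nzchar(stage_raw)
    stage_raw[use] <- clinical[[alt]][use]
  }
  base$stage <- normalize_stage(stage_raw)

  for (cls in c(GENE_EVENT_CLASSES, ANEUPLOIDY_EVENT_CLASSES)) base[[cls]] <- 0L

  if (nrow(classified) > 0L) {
    cpt <- barcode_patient(classified$Tumor_Sample_Barcode)
    tab <- table(cpt, classified$event_class)
    hit <- intersect(rownames(tab), patients)
    for (cls in intersect(colnames(tab), GENE_EVENT_CLASSES)) {
      base[[cls]][match(hit, patients)] <- as.integer(tab[hit, cls])
    }
  }
  if (nrow(aneuploidy_events) > 0L) {
    apt <- barcode_patient(aneuploidy_events$Tumor_Sample_Barcode)
    tab <- table(apt, aneuploidy_events$label)
    hit <- intersect(rownames(tab), patients)
    for (cls in intersect(colnames(tab), ANEUPLOIDY_EVENT_CLASSES)) {
      base[[cls]][match(hit, patients)] <- as.integer(tab[hit, cls])
    }
  }
  base$total <- as.integer(rowSums(base[c(DRIVER_EVENT_CLASSES,
                                          ANEUPLOIDY_EVENT_CLASSES)]))
  base
}

#' Group-wise mean event counts
#'
#' Arithmetic mean of every event-class count within groups defined by
#' gender, age decade, normalized stage, cohort, or each integer total
#' event count from 1 to 100. Groups with no patients are omitted;
#' patients with a missing grouping value are excluded from that grouping.
#'
#' @param counts data.frame from [count_events()].
#' @param group_by one of "gender", "age_bin", "stage", "cohort",
#'   "total_events".
#' @return data.frame with `group`, `n_patients` and one mean column per
#'   event class (plus `total`).
#' @export
aggregate_events <- function(counts,
                             group_by = c("gender", "age_bin", "stage",
                                          "cohort", "total_events")) {
  group_by <- match.arg(group_by)
  g <- switch(group_by,
              gender = counts$gender,
              age_bin = age_bin(counts$age),
              stage = counts$stage,
              cohort = counts$cohort,
              total_events = {
                t <- counts$total
                ifelse(t >= 1L & t <= 100L, as.character(t), NA_character_)
              })
  keep <- !is.na(g)
  counts <- counts[keep, , drop = FALSE]
  g <- g[keep]
  cols <- c(GENE_EVENT_CLASSES, ANEUPLOIDY_EVENT_CLASSES, "total")
  groups <- unique(g)
  if (group_by == "total_events") groups <- as.character(sort(as.integer(groups)))
  else groups <- sort(groups)
  out <- data.frame(group = groups,
                    n_patients = as.integer(table(g)[groups]),
                    stringsAsFactors = FALSE)
  for (col in cols) {
    out[[col]] <- vapply(groups, function(gr) mean(counts[[col]][g == gr]), 0)
  }
  rownames(out) <- NULL
  out
}

#' Histogram of total driver events per patient
#'
#' Counts patients at each integer total from 0 to 100; totals above 100
#' are clamped into the 100 bin (with a message). Optionally split by
#' gender.
#'
#' @param counts data.frame from [count_events()].
#' @param by_gender split into male/female histograms?
#' @return integer vector named "0".."100", or a list of such vectors per
#'   gender.
#' @export
event_histogram <- function(counts, by_gender = FALSE) {
  hist_one <- function(tot) {
    over <- tot > 100L
    if (any(over)) {
      message(sum(over), " patients with more than 100 events clamped into the 100 bin")
      tot[over] <- 100L
    }
    tabulate(tot + 1L, nbins = 101L) |> stats::setNames(as.character(0:100))
  }
  if (!by_gender) return(hist_one(counts$total))
  lapply(split(counts$total, counts$gender), hist_one)
}

#' Welch's heteroscedastic t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' one- or two-tailed. The one-tailed p-value is for the alternative that
#' group A's mean exceeds group B's.
#'
#' @param group_a,group_b numeric vectors (each length >= 2; at least one
#'   with nonzero variance).
#' @param tails 1 or 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(group_a, group_b, tails = 2L) {
  stopifnot(tails %in% c(1L, 2L))
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations")
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    stop("both groups are constant; t-test undefined")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      alternative = if (tails == 1L) "greater" else "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Run the PALDRIC pipeline
#'
#' Converts each cohort-level driver list into patient-level pairs (via
#' mutations and copy number), forms the consensus of at least
#' `min_sources` sources, annotates and classifies every pair, merges
#' patient-level aneuploidy events, and tallies per-patient counts.
#'
#' @param driver_lists list of driver-list data.frames (one per source).
#' @param maf filtered MAF.
#' @param cna raw thresholded CNA matrix (used for CNA matching).
#' @param validated_cna expression-validated CNA matrix (used for
#'   annotation).
#' @param tally,gene_scores SNADRIF outputs ([tally_sna()], low-count
#'   filtered [sna_gene_scores()]).
#' @param aneuploidy_events ANDRIF patient events.
#' @param clinical filtered clinical table.
#' @param min_sources consensus threshold (default 2).
#' @return list with `pairs` (classified annotated pairs) and `counts`
#'   (per-patient event counts).
#' @export
run_paldric <- function(driver_lists, maf, cna, validated_cna, tally,
                        gene_scores, aneuploidy_events, clinical,
                        min_sources = 2L) {
  per_source <- lapply(driver_lists, function(dl) {
    sna <- if (all(dl$level == "mutation")) {
      match_mutation_list(dl, maf, clinical)
    } else {
      match_gene_list(dl[dl$level == "gene", , drop = FALSE], maf, clinical)
    }
    cna_pairs <- match_cna(dl[dl$level == "gene", , drop = FALSE], cna, clinical)
    combine_source(sna, cna_pairs)
  })
  pairs <- consensus_pairs(per_source, min_sources)
  # drop pairs for patients outside the filtered clinical table
  pairs <- pairs[barcode_patient(pairs$Tumor_Sample_Barcode) %in%
                 clinical$bcr_patient_barcode, , drop = FALSE]
  pairs <- annotate_pairs(pairs, tally, gene_scores, validated_cna)
  pairs <- cbind(pairs, classify_pair(pairs$H, pairs$I, pairs$HISR, pairs$cna))
  counts <- count_events(pairs, aneuploidy_events, clinical)
  list(pairs = pairs, counts = counts)
}
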