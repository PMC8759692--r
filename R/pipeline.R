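#' Run the full driver-event workflow on one dataset
#'
#' Chains every stage on in-memory tables: initial filtering (primary
#' samples, quality blacklist, PASS mutations, purity filter on the arm
#' table, clinical restriction to primary malignant neoplasms present in
#' all molecular data), GECNAV expression validation of copy number, ANDRIF
#' aneuploidy driver calling, SNADRIF mutation driver calling, and PALDRIC
#' patient-level consensus classification. SNADRIF's pancancer driver list
#' is added as one consensus source alongside the supplied cohort-level
#' lists.
#'
#' @param maf,cna,expr,mirna,arms,clinical,purity,quality input tables in
#'   the dialects of the package readers (a `synthetic_dataset`'s elements
#'   fit directly).
#' @param driver_lists list of driver-list data.frames from external
#'   algorithms.
#' @param seed integer seed driving both bootstrap nulls (ANDRIF derives
#'   distinct per-stage seeds; SNADRIF uses `seed + 2`).
#' @param n_iter bootstrap iterations for both nulls.
#' @param q FDR level for both BH selections.
#' @param min_sources consensus threshold over the driver lists.
#' @param include_snadrif add SNADRIF's own driver list as a source?
#' @return list with the filtered inputs (`filtered`), `validated_cna`,
#'   `andrif`, `snadrif`, `paldric`.
#' @export
run_pipeline <- function(maf, cna, expr, mirna = NULL, arms, clinical,
                         purity, quality, driver_lists = list(),
                         seed = 1L, n_iter = 10000L, q = 0.05,
                         min_sources = 2L, include_snadrif = TRUE) {
  # --- initial filtering ---
  maf <- filter_maf(keep_primary(maf))
  maf <- apply_quality_blacklist(maf, quality)
  cna <- apply_quality_blacklist(keep_primary(cna), quality)
  expr <- apply_quality_blacklist(keep_primary(expr), quality)
  if (!is.null(mirna)) {
    mirna <- apply_quality_blacklist(keep_primary(mirna), quality)
  }
  arms <- apply_quality_blacklist_arms(keep_primary_arms(arms), quality)
  arms <- apply_purity_filter(arms, purity)

  # one sample per patient, deterministically
  cna <- subset_samples(cna, dedupe_patient_samples(colnames(cna)))
  expr <- subset_samples(expr, dedupe_patient_samples(colnames(expr)))
  arms <- arms[dedupe_patient_samples(rownames(arms)), , drop = FALSE]
  maf_samples <- sort(unique(maf$Tumor_Sample_Barcode))
  maf <- maf[maf$Tumor_Sample_Barcode %in%
             maf_samples[dedupe_patient_samples(maf_samples)], , drop = FALSE]

  clinical <- filter_clinical(clinical, unique(maf$Tumor_Sample_Barcode),
                              colnames(cna), rownames(arms))

  # --- GECNAV ---
  validated_cna <- run_gecnav(cna, expr, mirna)

  # --- ANDRIF (arm table restricted to clinical patients) ---
  cohort_of_pat <- stats::setNames(clinical$acronym, clinical$bcr_patient_barcode)
  arm_keep <- barcode_patient(rownames(arms)) %in% clinical$bcr_patient_barcode
  arms_clin <- arms[arm_keep, , drop = FALSE]
  cohort_of <- stats::setNames(cohort_of_pat[barcode_patient(rownames(arms_clin))],
                               rownames(arms_clin))
  andrif <- run_andrif(arms_clin, cohort_of, n_iter = n_iter, seed = seed, q = q)

  # --- SNADRIF ---
  snadrif <- run_snadrif(maf, n_iter = n_iter, seed = seed + 2L, q = q)

  # --- PALDRIC ---
  sources <- driver_lists
  if (include_snadrif && nrow(snadrif$drivers) > 0L) {
    sources$SNADRIF <- data.frame(
      source = "SNADRIF", level = "gene", scope = "pancancer",
      cohort = NA_character_, Hugo_Symbol = snadrif$drivers$Hugo_Symbol,
      Entrez_Gene_Id = snadrif$drivers$Entrez_Gene_Id,
      Transcript_ID = NA_character_, Substitution = NA_character_,
      q_value = snadrif$drivers$p, stringsAsFactors = FALSE)
  }
  paldric <- run_paldric(sources, maf, cna, validated_cna, snadrif$tally,
                         filter_low_count(sna_gene_scores(snadrif$tally)),
                         andrif$events, clinical, min_sources = min_sources)

  list(filtered = list(maf = maf, cna = cna, expr = expr, mirna = mirna,
                       arms = arms, clinical = clinical),
       validated_cna = validated_cna, andrif = andrif, snadrif = snadrif,
       paldric = paldric)
}

#' Write the main pipeline outputs as TSV files
#'
#' Deterministic on-disk summary of a [run_pipeline()] result: the
#' validated CNA matrix, cohort x unit aneuploidy averages and labels,
#' patient-level aneuploidy events, SNADRIF gene scores and driver list,
#' classified patient-gene pairs and per-patient event counts.
#'
#' @param res result of [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  paths <- c(validated_cna = p("cna_validated.tsv"),
             arm_averages = p("arm_averages.tsv"),
             arm_drivers = p("arm_drivers.tsv"),
             chromosome_drivers = p("chromosome_drivers.tsv"),
             aneuploidy_events = p("aneuploidy_events.tsv"),
             gene_scores = p("sna_gene_scores.tsv"),
             sna_drivers = p("sna_drivers.tsv"),
             pairs = p("classified_pairs.tsv"),
             patient_counts = p("patient_event_counts.tsv"))
  write_cna_matrix(res$validated_cna, paths[["validated_cna"]])
  avg <- res$andrif$arm$averages
  data.table::fwrite(data.frame(cohort = rownames(avg), avg,
                                check.names = FALSE),
                     paths[["arm_averages"]], sep = "\t", quote = FALSE, na = "")
  data.table::fwrite(res$andrif$arm$labels, paths[["arm_drivers"]],
                     sep = "\t", quote = FALSE, na = "")
  data.table::fwrite(res$andrif$chromosome$labels, paths[["chromosome_drivers"]],
                     sep = "\t", quote = FALSE, na = "")
  data.table::fwrite(res$andrif$events, paths[["aneuploidy_events"]],
                     sep = "\t", quote = FALSE, na = "")
  data.table::fwrite(res$snadrif$gene_scores, paths[["gene_scores"]],
                     sep = "\t", quote = FALSE, na = "")
  data.table::fwrite(res$snadrif$drivers, paths[["sna_drivers"]],
                     sep = "\t", quote = FALSE, na = "")
  data.table::fwrite(res$paldric$pairs, paths[["pairs"]],
                     sep = "\t", quote = FALSE, na = "")
  data.table::fwrite(res$paldric$counts, paths[["patient_counts"]],
                     sep = "\t", quote = FALSE, na = "")
  paths
}
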