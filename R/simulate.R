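#' Configuration for the synthetic-data generator
#'
#' Defines a complete synthetic study: cohorts and their sizes, the gene
#' universe, planted driver genes (oncogenes with hyperactivating SNAs and
#' amplifications, suppressors with truncating SNAs and deletions), planted
#' arm-level aneuploidy events, and the background rates that calibrate the
#' null. Defaults describe a null study of four 50-patient cohorts over a
#' 500-gene panel with no planted drivers: a background somatic SNA
#' probability of 0.1 per patient-gene (about 50 SNAs per patient in the
#' panel), a silent fraction of 0.5 among informative mutations so neutral
#' genes have NSEI near 1, symmetric arm-call noise of 0.05, and 90%
#' expression-copy-number concordance.
#'
#' @param cohorts named integer vector, cohort acronym -> number of
#'   patients.
#' @param n_genes size of the gene universe (planted genes included).
#' @param planted_oncogenes,planted_suppressors data.frames with columns
#'   `cohort`, `gene` (HUGO-style symbol), `sna_prob`, `cna_prob`
#'   (per-patient probabilities in the cohort), or NULL.
#' @param planted_arm_events data.frame with columns `cohort`, `arm`,
#'   `direction` (+1/-1), `frequency`, or NULL.
#' @param background_sna_rate per patient-gene probability of a background
#'   somatic SNA.
#' @param silent_fraction fraction of background SNAs that are silent.
#' @param unclear_rate per patient-gene probability of a noncoding-class
#'   (unclear) mutation row.
#' @param cna_background_rate per patient-gene probability of a background
#'   single-copy CNA call (+1 or -1, equiprobable).
#' @param arm_noise per-sample probability of a background arm call (+1 or
#'   -1, equiprobable) on an unplanted arm.
#' @param arm_missing_rate per-sample-arm probability of a missing call.
#' @param expression_concordance fraction of nonzero CNA calls whose
#'   expression is shifted concordantly beyond the coding thresholds.
#' @param n_mirna number of miRNA genes in the miRNA expression matrix.
#' @param nonpass_rate per patient-gene probability of an extra
#'   non-PASS MAF row (exercises the FILTER step; never part of the truth).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return validated list of class `truth_config`.
#' @export
truth_config <- function(cohorts = c(BRCA = 50L, COAD = 50L, LUAD = 50L,
                                     PRAD = 50L),
                         n_genes = 500L,
                         planted_oncogenes = NULL,
                         planted_suppressors = NULL,
                         planted_arm_events = NULL,
                         background_sna_rate = 0.1,
                         silent_fraction = 0.5,
                         unclear_rate = 0.005,
                         cna_background_rate = 0.02,
                         arm_noise = 0.05,
                         arm_missing_rate = 0.02,
                         expression_concordance = 0.9,
                         n_mirna = 10L,
                         nonpass_rate = 0.002,
                         seed = 1L) {
  cfg <- list(cohorts = cohorts, n_genes = as.integer(n_genes),
              planted_oncogenes = planted_oncogenes,
              planted_suppressors = planted_suppressors,
              planted_arm_events = planted_arm_events,
              background_sna_rate = background_sna_rate,
              silent_fraction = silent_fraction,
              unclear_rate = unclear_rate,
              cna_background_rate = cna_background_rate,
              arm_noise = arm_noise, arm_missing_rate = arm_missing_rate,
              expression_concordance = expression_concordance,
              n_mirna = as.integer(n_mirna), nonpass_rate = nonpass_rate,
              seed = as.integer(seed))
  problems <- character()
  if (is.null(names(cfg$cohorts)) || any(!nzchar(names(cfg$cohorts)))) {
    problems <- c(problems, "cohorts: must be a named vector of sizes")
  }
  if (any(cfg$cohorts < 1L)) problems <- c(problems, "cohorts: sizes must be >= 1")
  for (f in c("background_sna_rate", "silent_fraction", "unclear_rate",
              "cna_background_rate", "arm_noise", "arm_missing_rate",
              "expression_concordance", "nonpass_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      problems <- c(problems, paste0(f, ": must be a probability in [0,1]"))
    }
  }
  for (f in c("planted_oncogenes", "planted_suppressors")) {
    pl <- cfg[[f]]
    if (!is.null(pl)) {
      need <- c("cohort", "gene", "sna_prob", "cna_prob")
      if (!all(need %in% names(pl))) {
        problems <- c(problems, paste0(f, ": needs columns ", paste(need, collapse = ", ")))
      } else if (any(pl$sna_prob < 0 | pl$sna_prob > 1 |
                     pl$cna_prob < 0 | pl$cna_prob > 1)) {
        problems <- c(problems, paste0(f, ": probabilities must lie in [0,1]"))
      } else if (!all(pl$cohort %in% names(cfg$cohorts))) {
        problems <- c(problems, paste0(f, ": unknown cohort"))
      }
    }
  }
  if (!is.null(cfg$planted_arm_events)) {
    pe <- cfg$planted_arm_events
    need <- c("cohort", "arm", "direction", "frequency")
    if (!all(need %in% names(pe))) {
      problems <- c(problems, "planted_arm_events: needs columns cohort, arm, direction, frequency")
    } else {
      if (any(!pe$direction %in% c(-1L, 1L))) {
        problems <- c(problems, "planted_arm_events: direction must be +1 or -1")
      }
      if (any(pe$frequency < 0 | pe$frequency > 1)) {
        problems <- c(problems, "planted_arm_events: frequency must lie in [0,1]")
      }
      if (!all(pe$arm %in% standard_arms())) {
        problems <- c(problems, "planted_arm_events: unknown arm name")
      }
      if (!all(pe$cohort %in% names(cfg$cohorts))) {
        problems <- c(problems, "planted_arm_events: unknown cohort")
      }
    }
  }
  if (length(problems) > 0L) {
    stop("invalid truth_config:\n  ", paste(problems, collapse = "\n  "))
  }
  structure(cfg, class = "truth_config")
}

#' The 39 standard autosomal chromosome arms
#'
#' Both arms of chromosomes 1-12 and 16-20, plus the q arms of the
#' acrocentric chromosomes 13, 14, 15, 21 and 22.
#'
#' @return character vector of arm names.
#' @export
standard_arms <- function() {
  two_arm <- setdiff(1:22, c(13, 14, 15, 21, 22))
  sort_key <- c(paste0(two_arm, "p"), paste0(two_arm, "q"),
                paste0(c(13, 14, 15, 21, 22), "q"))
  chrom <- as.integer(sub("[pq]$", "", sort_key))
  sort_key[order(chrom, sub("^[0-9]+", "", sort_key))]
}

#' Generate a complete synthetic TCGA-dialect dataset
#'
#' Produces internally consistent mutation, copy-number, expression,
#' aneuploidy, clinical, purity and quality tables plus synthetic
#' cohort-level driver lists ("synthA", "synthB", each listing all planted
#' driver genes) and planted-truth tables. All barcodes parse, all files
#' round-trip through the package readers, and the truth tables are
#' sufficient to compute expected per-patient event counts. The dataset is
#' a deterministic function of the configuration (same config, same seed:
#' identical data).
#'
#' @param config a [truth_config()].
#' @return list of class `synthetic_dataset` with elements `maf`, `cna`,
#'   `expr`, `mirna`, `arms`, `clinical`, `purity`, `quality`,
#'   `driver_lists` (list of data.frames), `truth` (list of truth tables)
#'   and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  set.seed(config$seed)
  cohorts <- names(config$cohorts)

  # --- gene universe: planted genes first, then background filler ---
  planted <- rbind(
    if (!is.null(config$planted_oncogenes))
      cbind(config$planted_oncogenes, role = "oncogene"),
    if (!is.null(config$planted_suppressors))
      cbind(config$planted_suppressors, role = "suppressor"))
  planted_genes <- unique(if (is.null(planted)) character() else planted$gene)
  n_bg <- config$n_genes - length(planted_genes)
  if (n_bg < 0L) stop("n_genes smaller than the number of planted genes")
  symbols <- c(planted_genes, sprintf("BG%04d", seq_len(n_bg)))
  genes <- data.frame(
    Hugo_Symbol = symbols,
    Entrez_Gene_Id = 100000L + seq_along(symbols),
    Gene = sprintf("ENSG%011d", seq_along(symbols)),
    Transcript_ID = sprintf("ENST%011d", seq_along(symbols)),
    stringsAsFactors = FALSE)

  # --- patients ---
  site <- vapply(seq_along(cohorts), function(i) {
    paste0(LETTERS[(i - 1L) %/% 26L + 1L], LETTERS[(i - 1L) %% 26L + 1L])
  }, "")
  barcodes <- unlist(lapply(seq_along(cohorts), function(i) {
    sprintf("TCGA-%s-%04d-01A", site[i], seq_len(config$cohorts[[i]]))
  }))
  cohort_of <- rep(cohorts, times = as.integer(config$cohorts))
  names(cohort_of) <- barcodes
  np <- length(barcodes)
  ng <- nrow(genes)

  # --- background somatic mutations (background genes only: planted driver
  # genes carry exactly their planted spectrum) ---
  planted_idx <- match(planted_genes, genes$Hugo_Symbol)
  mut_cell <- which(matrix(stats::runif(np * ng), np, ng) < config$background_sna_rate)
  pat_i <- (mut_cell - 1L) %% np + 1L
  gene_i <- (mut_cell - 1L) %/% np + 1L
  bg_only <- !(gene_i %in% planted_idx)
  mut_cell <- mut_cell[bg_only]
  pat_i <- pat_i[bg_only]
  gene_i <- gene_i[bg_only]
  is_silent <- stats::runif(length(mut_cell)) < config$silent_fraction
  nonsilent_classes <- c("Missense_Mutation", "Nonsense_Mutation",
                         "Frame_Shift_Del", "In_Frame_Del")
  vc <- ifelse(is_silent, "Silent",
               sample(nonsilent_classes, length(mut_cell), replace = TRUE,
                      prob = c(0.75, 0.12, 0.08, 0.05)))
  maf <- data.frame(
    Tumor_Sample_Barcode = barcodes[pat_i],
    Hugo_Symbol = genes$Hugo_Symbol[gene_i],
    Entrez_Gene_Id = genes$Entrez_Gene_Id[gene_i],
    Gene = genes$Gene[gene_i],
    Transcript_ID = genes$Transcript_ID[gene_i],
    Variant_Classification = vc,
    HGVSp_Short = sprintf("p.%s%d%s",
                          sample(LETTERS, length(mut_cell), replace = TRUE),
                          sample.int(900L, length(mut_cell), replace = TRUE),
                          sample(LETTERS, length(mut_cell), replace = TRUE)),
    FILTER = "PASS", stringsAsFactors = FALSE)

  # --- unclear (noncoding-class) rows ---
  unc_cell <- which(matrix(stats::runif(np * ng), np, ng) < config$unclear_rate)
  if (length(unc_cell) > 0L) {
    up <- (unc_cell - 1L) %% np + 1L
    ug <- (unc_cell - 1L) %/% np + 1L
    maf <- rbind(maf, data.frame(
      Tumor_Sample_Barcode = barcodes[up],
      Hugo_Symbol = genes$Hugo_Symbol[ug],
      Entrez_Gene_Id = genes$Entrez_Gene_Id[ug],
      Gene = genes$Gene[ug], Transcript_ID = genes$Transcript_ID[ug],
      Variant_Classification = sample(c("3'UTR", "5'Flank", "Intron"),
                                      length(unc_cell), replace = TRUE),
      HGVSp_Short = "", FILTER = "PASS", stringsAsFactors = FALSE))
  }

  # --- planted driver SNAs and CNAs ---
  cna <- matrix(0L, ng, np, dimnames = list(as.character(genes$Entrez_Gene_Id),
                                            barcodes))
  noise_cell <- which(matrix(stats::runif(np * ng), ng, np) < config$cna_background_rate)
  cna[noise_cell] <- sample(c(-1L, 1L), length(noise_cell), replace = TRUE)

  truth_sna <- list(); truth_cna <- list()
  if (!is.null(planted) && nrow(planted) > 0L) {
    for (j in seq_len(nrow(planted))) {
      row <- planted[j, ]
      gi <- match(row$gene, genes$Hugo_Symbol)
      members <- barcodes[cohort_of == row$cohort]
      sna_carriers <- members[stats::runif(length(members)) < row$sna_prob]
      cna_carriers <- members[stats::runif(length(members)) < row$cna_prob]
      if (length(sna_carriers) > 0L) {
        vc_p <- if (row$role == "oncogene") "Missense_Mutation" else
          sample(c("Nonsense_Mutation", "Frame_Shift_Del", "Frame_Shift_Ins"),
                 length(sna_carriers), replace = TRUE)
        maf <- rbind(maf, data.frame(
          Tumor_Sample_Barcode = sna_carriers,
          Hugo_Symbol = row$gene,
          Entrez_Gene_Id = genes$Entrez_Gene_Id[gi],
          Gene = genes$Gene[gi], Transcript_ID = genes$Transcript_ID[gi],
          Variant_Classification = vc_p,
          HGVSp_Short = sprintf("p.V%dE", 100L + gi),
          FILTER = "PASS", stringsAsFactors = FALSE))
        truth_sna[[length(truth_sna) + 1L]] <- data.frame(
          Tumor_Sample_Barcode = sna_carriers,
          Entrez_Gene_Id = genes$Entrez_Gene_Id[gi],
          Hugo_Symbol = row$gene, cohort = row$cohort, role = row$role,
          stringsAsFactors = FALSE)
      }
      if (length(cna_carriers) > 0L) {
        cna[gi, match(cna_carriers, barcodes)] <-
          if (row$role == "oncogene") 2L else -2L
        truth_cna[[length(truth_cna) + 1L]] <- data.frame(
          Tumor_Sample_Barcode = cna_carriers,
          Entrez_Gene_Id = genes$Entrez_Gene_Id[gi],
          Hugo_Symbol = row$gene, cohort = row$cohort, role = row$role,
          stringsAsFactors = FALSE)
      }
    }
  }
  attr(cna, "gene_symbols") <- stats::setNames(genes$Hugo_Symbol,
                                               rownames(cna))

  # --- extra non-PASS rows (must be removed by the FILTER step) ---
  n_np <- stats::rbinom(1L, np * ng, config$nonpass_rate)
  if (n_np > 0L) {
    fp <- sample.int(np, n_np, replace = TRUE)
    fg <- sample.int(ng, n_np, replace = TRUE)
    maf <- rbind(maf, data.frame(
      Tumor_Sample_Barcode = barcodes[fp],
      Hugo_Symbol = genes$Hugo_Symbol[fg],
      Entrez_Gene_Id = genes$Entrez_Gene_Id[fg],
      Gene = genes$Gene[fg], Transcript_ID = genes$Transcript_ID[fg],
      Variant_Classification = "Missense_Mutation",
      HGVSp_Short = "p.A1B", FILTER = "wga", stringsAsFactors = FALSE))
  }
  maf <- maf[order(maf$Tumor_Sample_Barcode, maf$Entrez_Gene_Id,
                   maf$Variant_Classification, maf$HGVSp_Short), , drop = FALSE]
  rownames(maf) <- NULL

  # --- expression, concordant with CNA for a configurable fraction ---
  baseline <- round(stats::rlnorm(ng, meanlog = log(1000), sdlog = 1), 3)
  expr <- matrix(stats::runif(ng * np, 0.9, 1.1), ng, np) * baseline
  nonzero <- which(cna != 0)
  if (length(nonzero) > 0L) {
    concordant <- nonzero[stats::runif(length(nonzero)) < config$expression_concordance]
    gains <- concordant[cna[concordant] > 0L]
    losses <- concordant[cna[concordant] < 0L]
    row_of <- function(cells) (cells - 1L) %% ng + 1L
    expr[gains] <- baseline[row_of(gains)] * stats::runif(length(gains), 2.5, 3.5)
    expr[losses] <- baseline[row_of(losses)] * stats::runif(length(losses), 0.2, 0.5)
  }
  expr <- round(expr, 3)
  dimnames(expr) <- dimnames(cna)
  attr(expr, "gene_symbols") <- attr(cna, "gene_symbols")

  mirna <- NULL
  if (config$n_mirna > 0L) {
    mb <- round(stats::rlnorm(config$n_mirna, meanlog = log(500), sdlog = 1), 3)
    mirna <- round(matrix(stats::runif(config$n_mirna * np, 0.9, 1.1),
                          config$n_mirna, np) * mb, 3)
    dimnames(mirna) <- list(sprintf("hsa-mir-%03d", seq_len(config$n_mirna)),
                            barcodes)
  }

  # --- arm calls with planted cohort-level events ---
  arms <- standard_arms()
  arm_calls <- matrix(0L, np, length(arms), dimnames = list(barcodes, arms))
  noise_draw <- matrix(stats::runif(np * length(arms)), np, length(arms))
  arm_calls[noise_draw < config$arm_noise / 2] <- -1L
  arm_calls[noise_draw >= config$arm_noise / 2 &
            noise_draw < config$arm_noise] <- 1L
  truth_arm_events <- list()
  pe <- config$planted_arm_events
  if (!is.null(pe) && nrow(pe) > 0L) {
    for (j in seq_len(nrow(pe))) {
      members <- which(cohort_of == pe$cohort[j])
      hit <- members[stats::runif(length(members)) < pe$frequency[j]]
      arm_calls[hit, pe$arm[j]] <- as.integer(pe$direction[j])
      if (length(hit) > 0L) {
        truth_arm_events[[length(truth_arm_events) + 1L]] <- data.frame(
          Tumor_Sample_Barcode = barcodes[hit], arm = pe$arm[j],
          direction = as.integer(pe$direction[j]), cohort = pe$cohort[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  miss <- which(matrix(stats::runif(np * length(arms)), np,
                       length(arms)) < config$arm_missing_rate)
  arm_calls[miss] <- NA_integer_

  # --- clinical, purity, quality ---
  stages <- paste("Stage", c("I", "IA", "IB", "II", "IIA", "III", "IIIB", "IV"))
  clinical <- data.frame(
    bcr_patient_barcode = barcode_patient(barcodes),
    acronym = unname(cohort_of),
    gender = sample(c("MALE", "FEMALE"), np, replace = TRUE),
    age_at_initial_pathologic_diagnosis = sample(25:85, np, replace = TRUE),
    pathologic_stage = sample(stages, np, replace = TRUE),
    clinical_stage = NA_character_, pathologic_T = NA_character_,
    clinical_T = NA_character_,
    icd_o_3_histology = "8140/3", stringsAsFactors = FALSE)
  # a sprinkling of patients rely on the stage fallbacks
  fallback <- sample.int(np, max(1L, np %/% 20L))
  clinical$pathologic_stage[fallback] <- NA_character_
  clinical$clinical_stage[fallback] <- sample(stages, length(fallback),
                                              replace = TRUE)

  purity <- data.frame(
    sample = barcodes,
    `Cancer DNA fraction` = round(stats::runif(np, 0.55, 0.95), 3),
    `Subclonal genome fraction` = round(stats::runif(np, 0, 0.45), 3),
    check.names = FALSE, stringsAsFactors = FALSE)
  quality <- data.frame(aliquot_barcode = barcodes, Do_not_use = FALSE,
                        stringsAsFactors = FALSE)

  # --- synthetic cohort-level driver lists covering the planted genes ---
  make_list <- function(source_name) {
    if (is.null(planted) || nrow(planted) == 0L) {
      return(data.frame(source = character(), level = character(),
                        scope = character(), cohort = character(),
                        Hugo_Symbol = character(), Entrez_Gene_Id = integer(),
                        Transcript_ID = character(), Substitution = character(),
                        q_value = numeric(), stringsAsFactors = FALSE))
    }
    gi <- match(planted$gene, genes$Hugo_Symbol)
    data.frame(source = source_name, level = "gene", scope = "cohort",
               cohort = planted$cohort, Hugo_Symbol = planted$gene,
               Entrez_Gene_Id = genes$Entrez_Gene_Id[gi],
               Transcript_ID = NA_character_, Substitution = NA_character_,
               q_value = 0.01, stringsAsFactors = FALSE)
  }
  driver_lists <- list(synthA = make_list("synthA"), synthB = make_list("synthB"))

  bind_or_empty <- function(lst, cols) {
    if (length(lst) > 0L) {
      out <- do.call(rbind, lst); rownames(out) <- NULL; out
    } else {
      as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols),
                    stringsAsFactors = FALSE)
    }
  }
  truth <- list(
    driver_genes = if (is.null(planted) || nrow(planted) == 0L) {
      data.frame(cohort = character(), Hugo_Symbol = character(),
                 Entrez_Gene_Id = integer(), role = character(),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cohort = planted$cohort, Hugo_Symbol = planted$gene,
                 Entrez_Gene_Id = genes$Entrez_Gene_Id[
                   match(planted$gene, genes$Hugo_Symbol)],
                 role = planted$role, stringsAsFactors = FALSE)
    },
    sna_events = bind_or_empty(truth_sna,
      c("Tumor_Sample_Barcode", "Entrez_Gene_Id", "Hugo_Symbol", "cohort", "role")),
    cna_events = bind_or_empty(truth_cna,
      c("Tumor_Sample_Barcode", "Entrez_Gene_Id", "Hugo_Symbol", "cohort", "role")),
    arm_drivers = if (is.null(pe)) {
      data.frame(cohort = character(), arm = character(), direction = integer(),
                 stringsAsFactors = FALSE)
    } else {
      pe[c("cohort", "arm", "direction")]
    },
    arm_events = bind_or_empty(truth_arm_events,
      c("Tumor_Sample_Barcode", "arm", "direction", "cohort")))

  structure(list(maf = maf, cna = cna, expr = expr, mirna = mirna,
                 arms = arm_calls, clinical = clinical, purity = purity,
                 quality = quality, driver_lists = driver_lists,
                 truth = truth, config = config),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to TSV files
#'
#' Writes the seven input files in their PanCanAtlas dialects plus the
#' synthetic driver lists and the planted-truth tables.
#'
#' @param ds a `synthetic_dataset` from [generate_dataset()].
#' @param outdir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_dataset <- function(ds, outdir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  paths <- c(maf = p("mutations.maf.tsv"), cna = p("cna_thresholded.tsv"),
             expr = p("expression.tsv"), mirna = p("mirna_expression.tsv"),
             arms = p("arm_calls.tsv"), clinical = p("clinical.tsv"),
             purity = p("purity.tsv"), quality = p("quality_annotations.tsv"))
  write_maf(ds$maf, paths[["maf"]])
  write_cna_matrix(ds$cna, paths[["cna"]])
  write_expression_matrix(ds$expr, paths[["expr"]])
  if (!is.null(ds$mirna)) write_mirna_matrix(ds$mirna, paths[["mirna"]]) else
    paths <- paths[names(paths) != "mirna"]
  write_arm_calls(ds$arms, paths[["arms"]])
  write_clinical(ds$clinical, paths[["clinical"]])
  write_purity(ds$purity, paths[["purity"]])
  write_quality(ds$quality, paths[["quality"]])
  for (nm in names(ds$driver_lists)) {
    paths[[paste0("source_", nm)]] <- p(paste0("driver_list_", nm, ".tsv"))
    write_driver_list(ds$driver_lists[[nm]], paths[[paste0("source_", nm)]])
  }
  for (nm in names(ds$truth)) {
    paths[[paste0("truth_", nm)]] <- p(paste0("truth_", nm, ".tsv"))
    data.table::fwrite(ds$truth[[nm]], paths[[paste0("truth_", nm)]],
                       sep = "\t", quote = FALSE, na = "")
  }
  paths
}
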