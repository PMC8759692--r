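#' Cohort-level average alteration status per chromosomal unit
#'
#' For every cohort (cancer type) and every unit (chromosome arm or whole
#' chromosome), the arithmetic mean of the non-missing {-1,0,1} calls of
#' that unit over the cohort's samples.
#'
#' @param calls sample x unit matrix over {-1,0,1,NA}.
#' @param cohort_of named character vector mapping sample barcode -> cohort
#'   acronym; every sample in `calls` must be covered.
#' @return cohort x unit numeric matrix of averages in [-1,1]; NaN where a
#'   cohort has no non-missing call for a unit.
#' @export
aneuploidy_unit_averages <- function(calls, cohort_of) {
  cohorts <- cohort_of[rownames(calls)]
  unknown <- is.na(cohorts)
  if (any(unknown)) {
    stop("no cohort assignment for sample(s): ",
         paste(utils::head(rownames(calls)[unknown], 5L), collapse = ", "))
  }
  groups <- sort(unique(cohorts))
  avg <- matrix(NA_real_, length(groups), ncol(calls),
                dimnames = list(groups, colnames(calls)))
  for (g in groups) {
    avg[g, ] <- colMeans(calls[cohorts == g, , drop = FALSE], na.rm = TRUE)
  }
  avg
}

#' Bootstrap null distribution of cohort averages
#'
#' Emulates the null hypothesis that calls carry no cohort- or unit-specific
#' signal: statuses are drawn uniformly with replacement from the pool of
#' all non-missing cells of the whole table (all cohorts, all units). For
#' each cohort, each iteration draws as many statuses as the cohort has
#' samples and averages them; the full vector of `n_iter` averages and its
#' median are retained per cohort.
#'
#' @param calls sample x unit matrix over {-1,0,1,NA}.
#' @param cohort_sizes named integer vector, cohort -> number of samples.
#' @param n_iter number of bootstrap iterations (10000 in the reference
#'   analysis).
#' @param seed integer seed; same seed gives bit-identical results.
#' @return an object of class `aneuploidy_null`: list with `averages`
#'   (n_iter x cohort matrix), `medians` (named vector), `n_iter`, `seed`.
#' @export
aneuploidy_bootstrap_null <- function(calls, cohort_sizes, n_iter = 10000L,
                                      seed = 1L) {
  pool <- calls[!is.na(calls)]
  if (length(pool) == 0L) stop("no non-missing calls to bootstrap from")
  cohorts <- names(cohort_sizes)
  averages <- matrix(NA_real_, n_iter, length(cohorts),
                     dimnames = list(NULL, cohorts))
  set.seed(seed)
  for (g in cohorts) {
    n <- cohort_sizes[[g]]
    draws <- matrix(pool[sample.int(length(pool), n * n_iter, replace = TRUE)],
                    nrow = n)
    averages[, g] <- colMeans(draws)
  }
  structure(list(averages = averages,
                 medians = apply(averages, 2L, stats::median),
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "aneuploidy_null")
}

#' Signed empirical p-value for one cohort average
#'
#' An observed cohort average is tested only in its own direction: a
#' positive average above the cohort's bootstrap median is scored as a gain
#' with magnitude `(# bootstrap averages > observed) / (n_iter/2)`; a
#' negative average below the median as a loss with the symmetric count of
#' smaller averages. Dividing the one-sided count by half the iteration
#' count (5000 for the reference 10000) doubles the tail, a two-sided
#' correction; magnitudes are capped at 1 before testing. All other cases
#' (zero averages, averages on the wrong side of the median) are not tested
#' and return NULL.
#'
#' @param observed the cohort x unit average.
#' @param null an `aneuploidy_null` object.
#' @param cohort cohort acronym present in `null`.
#' @return list with `magnitude` and `direction` ("gain"/"loss"), or NULL.
#' @export
signed_empirical_p <- function(observed, null, cohort) {
  if (!cohort %in% colnames(null$averages)) stop("unknown cohort: ", cohort)
  if (is.na(observed) || is.nan(observed)) return(NULL)
  med <- null$medians[[cohort]]
  vec <- null$averages[, cohort]
  half <- null$n_iter / 2
  if (observed > 0 && observed > med) {
    list(magnitude = sum(vec > observed) / half, direction = "gain")
  } else if (observed < 0 && observed < med) {
    list(magnitude = sum(vec < observed) / half, direction = "loss")
  } else {
    NULL
  }
}

#' All signed empirical p-values for a cohort x unit average matrix
#'
#' @param averages cohort x unit matrix from [aneuploidy_unit_averages()].
#' @param null an `aneuploidy_null` object.
#' @return data.frame with columns `cohort`, `unit`, `p` (capped at 1) and
#'   `direction`; untested cells are absent.
#' @export
aneuploidy_pvalues <- function(averages, null) {
  rows <- list()
  for (g in rownames(averages)) {
    for (u in colnames(averages)) {
      sp <- signed_empirical_p(averages[g, u], null, g)
      if (!is.null(sp)) {
        rows[[length(rows) + 1L]] <- data.frame(
          cohort = g, unit = u, p = min(sp$magnitude, 1),
          direction = sp$direction, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(cohort = character(), unit = character(),
                      p = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Benjamini-Hochberg selection of aneuploidy drivers
#'
#' BH step-up at level `q` applied separately within each cohort over its
#' tested units. Passing gains become DAG (arm scope) or DCG (chromosome
#' scope); passing losses DAL or DCL.
#'
#' @param pvals data.frame from [aneuploidy_pvalues()].
#' @param q FDR level (default 0.05).
#' @param scope "arm" or "chromosome".
#' @return data.frame `cohort`, `unit`, `label` for the selected drivers.
#' @export
bh_select_aneuploidy <- function(pvals, q = 0.05, scope = c("arm", "chromosome")) {
  scope <- match.arg(scope)
  out <- list()
  for (g in unique(pvals$cohort)) {
    sub <- pvals[pvals$cohort == g, , drop = FALSE]
    pass <- bh_pass(sub$p, q)
    if (!any(pass)) next
    sub <- sub[pass, , drop = FALSE]
    label <- ifelse(sub$direction == "gain",
                    if (scope == "arm") "DAG" else "DCG",
                    if (scope == "arm") "DAL" else "DCL")
    out[[g]] <- data.frame(cohort = sub$cohort, unit = sub$unit,
                           label = label, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(cohort = character(), unit = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Derive whole-chromosome calls from arm calls
#'
#' A chromosome is called 1 when both of its arms are 1, -1 when both are
#' -1, missing when either arm is missing, and 0 otherwise. The acrocentric
#' one-arm chromosomes (13, 14, 15, 21, 22) take their single arm's status
#' verbatim.
#'
#' @param arms sample x arm matrix; arm names like `"1p"`, `"13q"`.
#' @return sample x chromosome matrix over {-1,0,1,NA}; chromosome columns
#'   are named by the chromosome (e.g. `"1"`, `"13"`).
#' @export
chromosome_calls <- function(arms) {
  arm_names <- colnames(arms)
  if (!all(grepl("^[0-9XY]+[pq]$", arm_names))) {
    stop("unparseable arm name(s): ",
         paste(arm_names[!grepl("^[0-9XY]+[pq]$", arm_names)], collapse = ", "))
  }
  chrom <- sub("[pq]$", "", arm_names)
  chroms <- unique(chrom)
  out <- matrix(NA_integer_, nrow(arms), length(chroms),
                dimnames = list(rownames(arms), chroms))
  for (cc in chroms) {
    members <- which(chrom == cc)
    if (length(members) == 1L) {
      out[, cc] <- arms[, members]
    } else {
      p <- arms[, members[1L]]
      q <- arms[, members[2L]]
      val <- ifelse(is.na(p) | is.na(q), NA_integer_,
             ifelse(p == 1L & q == 1L, 1L,
             ifelse(p == -1L & q == -1L, -1L, 0L)))
      out[, cc] <- val
    }
  }
  out
}

#' Patient-level aneuploidy driver events
#'
#' A patient's -1 call on a unit labelled a driver loss in the patient's
#' cohort is one loss event; a +1 call on a driver gain is one gain event.
#' Chromosome-level events override arm-level events: when a patient has a
#' DCG/DCL event on a chromosome, no events are counted on that
#' chromosome's arms for that patient, preventing triple counting.
#'
#' @param arm_calls,chrom_calls sample x unit matrices.
#' @param arm_labels,chrom_labels data.frames from
#'   [bh_select_aneuploidy()].
#' @param cohort_of named vector, sample -> cohort.
#' @return data.frame `Tumor_Sample_Barcode`, `unit`, `label`; patients with
#'   zero events are absent.
#' @export
aneuploidy_patient_events <- function(arm_calls, chrom_calls,
                                      arm_labels, chrom_labels, cohort_of) {
  event_rows <- function(calls, labels) {
    rows <- list()
    for (j in seq_len(nrow(labels))) {
      g <- labels$cohort[j]; u <- labels$unit[j]; lab <- labels$label[j]
      if (!u %in% colnames(calls)) next
      want <- if (lab %in% c("DAG", "DCG")) 1L else -1L
      samples <- rownames(calls)[!is.na(calls[, u]) & calls[, u] == want &
                                 cohort_of[rownames(calls)] == g]
      if (length(samples) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          Tumor_Sample_Barcode = samples, unit = u, label = lab,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L) {
      return(data.frame(Tumor_Sample_Barcode = character(), unit = character(),
                        label = character(), stringsAsFactors = FALSE))
    }
    do.call(rbind, rows)
  }
  chrom_ev <- event_rows(chrom_calls, chrom_labels)
  arm_ev <- event_rows(arm_calls, arm_labels)
  if (nrow(arm_ev) > 0L && nrow(chrom_ev) > 0L) {
    arm_chrom <- sub("[pq]$", "", arm_ev$unit)
    suppressed <- paste(arm_ev$Tumor_Sample_Barcode, arm_chrom) %in%
      paste(chrom_ev$Tumor_Sample_Barcode, chrom_ev$unit)
    arm_ev <- arm_ev[!suppressed, , drop = FALSE]
  }
  out <- rbind(chrom_ev, arm_ev)
  out <- out[order(out$Tumor_Sample_Barcode, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the ANDRIF pipeline
#'
#' Arm-level and chromosome-level driver discovery on a filtered arm-call
#' table: cohort averages, pan-table bootstrap null, signed empirical
#' p-values, per-cohort BH selection, and patient-level event calling with
#' the chromosome-over-arm override. The chromosome analysis uses a seed
#' derived from `seed` so the two bootstrap streams are distinct but
#' jointly reproducible.
#'
#' @param arms filtered sample x arm call matrix.
#' @param cohort_of named vector, sample -> cohort acronym.
#' @param n_iter bootstrap iterations per cohort.
#' @param seed integer seed.
#' @param q FDR level.
#' @return list with `arm` and `chromosome` sublists (each `averages`,
#'   `null`, `pvalues`, `labels`), and `events` (patient-level data.frame).
#' @export
run_andrif <- function(arms, cohort_of, n_iter = 10000L, seed = 1L, q = 0.05) {
  cohorts <- cohort_of[rownames(arms)]
  sizes <- table(cohorts)
  cohort_sizes <- stats::setNames(as.integer(sizes), names(sizes))

  stage <- function(calls, stage_seed, scope) {
    averages <- aneuploidy_unit_averages(calls, cohort_of)
    null <- aneuploidy_bootstrap_null(calls, cohort_sizes, n_iter, stage_seed)
    pvalues <- aneuploidy_pvalues(averages, null)
    labels <- bh_select_aneuploidy(pvalues, q, scope)
    list(averages = averages, null = null, pvalues = pvalues, labels = labels)
  }

  arm_res <- stage(arms, seed, "arm")
  chroms <- chromosome_calls(arms)
  chrom_res <- stage(chroms, seed + 1L, "chromosome")
  events <- aneuploidy_patient_events(arms, chroms, arm_res$labels,
                                      chrom_res$labels, cohort_of)
  list(arm = arm_res, chromosome = chrom_res, events = events)
}

#' Summary counts of aneuploidy drivers
#'
#' Tabulates, for each direction, the number of units with a driver label
#' per cohort and the number of cohorts with a driver label per unit.
#'
#' @param labels data.frame from [bh_select_aneuploidy()].
#' @return list of four tables: `gains_per_cohort`, `losses_per_cohort`,
#'   `cohorts_with_gain_per_unit`, `cohorts_with_loss_per_unit`.
#' @export
andrif_summary <- function(labels) {
  gains <- labels[labels$label %in% c("DAG", "DCG"), , drop = FALSE]
  losses <- labels[labels$label %in% c("DAL", "DCL"), , drop = FALSE]
  list(gains_per_cohort = table(gains$cohort),
       losses_per_cohort = table(losses$cohort),
       cohorts_with_gain_per_unit = table(gains$unit),
       cohorts_with_loss_per_unit = table(losses$unit))
}
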