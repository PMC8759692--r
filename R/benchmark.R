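#' Prediction sets for benchmarking
#'
#' A prediction set is the deduplicated output of one driver-calling source
#' at either gene level (items are Entrez ids) or gene-cohort level (items
#' are "entrez|cohort" pairs).
#'
#' @param source_name label for the source.
#' @param level "gene" or "gene_cohort".
#' @param items character vector of items (deduplicated).
#' @return object of class `prediction_set`.
#' @export
prediction_set <- function(source_name, level = c("gene", "gene_cohort"),
                           items) {
  level <- match.arg(level)
  structure(list(source_name = source_name, level = level,
                 items = unique(as.character(items))),
            class = "prediction_set")
}

#' @rdname prediction_set
#' @param entrez,cohort vectors combined into gene-cohort items.
#' @export
gene_cohort_items <- function(entrez, cohort) {
  paste(entrez, cohort, sep = "|")
}

#' Overlap-of-k consensus of prediction sets
#'
#' Items predicted by at least `k` of the supplied sets; with `k = 1` this
#' is the union.
#'
#' @param sets list of `prediction_set`s at the same level.
#' @param k minimum number of supporting sets.
#' @return a `prediction_set` named "overlap_k".
#' @export
overlap_k <- function(sets, k) {
  levels <- unique(vapply(sets, function(s) s$level, ""))
  if (length(levels) != 1L) stop("prediction sets have mixed levels")
  counts <- table(unlist(lapply(sets, function(s) s$items)))
  prediction_set(paste0("overlap_", k), levels,
                 names(counts)[counts >= k])
}

#' Sensitivity against a positive-control list
#'
#' Percentage of the positive-control items recovered by the prediction:
#' 100 * TP / (TP + FN).
#'
#' @param pred,positive `prediction_set`s at the same level.
#' @return percentage in [0, 100].
#' @export
sensitivity <- function(pred, positive) {
  if (pred$level != positive$level) stop("prediction sets have mixed levels")
  if (length(positive$items) == 0L) stop("empty positive-control set")
  100 * length(intersect(pred$items, positive$items)) / length(positive$items)
}

#' Specificity against a positive-control list
#'
#' Percentage of non-positive items of the universe not predicted as
#' drivers: 100 * TN / (TN + FP). The universe pins down "all genes" (or
#' gene-cohort pairs), typically every gene observed in the filtered
#' mutation table.
#'
#' @param pred,positive,universe `prediction_set`s at the same level;
#'   `positive` and `pred` must be subsets of `universe`.
#' @return percentage in [0, 100].
#' @export
specificity <- function(pred, positive, universe) {
  if (length(unique(c(pred$level, positive$level, universe$level))) != 1L) {
    stop("prediction sets have mixed levels")
  }
  negatives <- setdiff(universe$items, positive$items)
  if (length(negatives) == 0L) stop("universe equals the positive set")
  tn <- setdiff(negatives, pred$items)
  100 * length(tn) / length(negatives)
}

#' Compare predictions to planted truth
#'
#' Per-class recall and precision of predicted items against the generator's
#' planted ground truth.
#'
#' @param predicted,truth character vectors of items (genes, gene-cohort
#'   pairs, or unit-cohort pairs).
#' @return list with `recall`, `precision`, `n_truth`, `n_predicted`,
#'   `true_positives`.
#' @export
truth_compare <- function(predicted, truth) {
  predicted <- unique(as.character(predicted))
  truth <- unique(as.character(truth))
  tp <- length(intersect(predicted, truth))
  list(recall = if (length(truth) == 0L) NA_real_ else tp / length(truth),
       precision = if (length(predicted) == 0L) NA_real_ else tp / length(predicted),
       n_truth = length(truth), n_predicted = length(predicted),
       true_positives = tp)
}
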