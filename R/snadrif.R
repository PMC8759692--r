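#' Functional classification of variant types
#'
#' Partitions MAF `Variant_Classification` strings into four categories:
#' truncating classes (`Frame_Shift_Del`, `Frame_Shift_Ins`,
#' `Nonsense_Mutation`, `Nonstop_Mutation`, `Translation_Start_Site`) are
#' potentially inactivating; protein-altering non-truncating classes
#' (`De_novo_Start_InFrame`, `In_Frame_Del`, `In_Frame_Ins`,
#' `Missense_Mutation`) are potentially hyperactivating;
#' `De_novo_Start_OutOfFrame` and `Silent` are passengers; everything else
#' (UTRs, flanks, introns, RNA) is unclear.
#'
#' @param variant_classification character vector.
#' @return character vector over
#'   `c("hyperactivating","inactivating","passenger","unclear")`.
#' @examples
#' classify_variant(c("Missense_Mutation", "Silent", "3'UTR"))
#' @export
classify_variant <- function(variant_classification) {
  inact <- c("Frame_Shift_Del", "Frame_Shift_Ins", "Nonsense_Mutation",
             "Nonstop_Mutation", "Translation_Start_Site")
  hyper <- c("De_novo_Start_InFrame", "In_Frame_Del", "In_Frame_Ins",
             "Missense_Mutation")
  pass <- c("De_novo_Start_OutOfFrame", "Silent")
  out <- rep("unclear", length(variant_classification))
  out[variant_classification %in% inact] <- "inactivating"
  out[variant_classification %in% hyper] <- "hyperactivating"
  out[variant_classification %in% pass] <- "passenger"
  out
}

NONSYNONYMOUS_CLASSES <- c("De_novo_Start_InFrame", "Frame_Shift_Del",
                           "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
                           "Missense_Mutation", "Nonsense_Mutation",
                           "Nonstop_Mutation", "Translation_Start_Site")

#' Per-patient, per-gene SNA category counts
#'
#' Tallies hyperactivating (H), inactivating (I), unclear (U) and passenger
#' (P) mutation counts for every (sample, gene) pair of an already filtered
#' MAF. Genes whose pan-dataset totals are unclear-only (H=I=P=0, U>0;
#' typically noncoding genes) are removed entirely.
#'
#' @param maf filtered MAF data.frame (PASS rows, primary samples).
#' @return data.frame `Tumor_Sample_Barcode`, `Entrez_Gene_Id`,
#'   `Hugo_Symbol`, `H`, `I`, `U`, `P`.
#' @export
tally_sna <- function(maf) {
  empty <- data.frame(Tumor_Sample_Barcode = character(),
                      Entrez_Gene_Id = integer(), Hugo_Symbol = character(),
                      H = integer(), I = integer(), U = integer(), P = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(maf) == 0L) return(empty)
  dt <- data.table::as.data.table(maf[c("Tumor_Sample_Barcode", "Entrez_Gene_Id",
                                        "Hugo_Symbol", "Variant_Classification")])
  dt[, category := classify_variant(Variant_Classification)]
  tal <- dt[, .(H = sum(category == "hyperactivating"),
                I = sum(category == "inactivating"),
                U = sum(category == "unclear"),
                P = sum(category == "passenger")),
            by = .(Tumor_Sample_Barcode, Entrez_Gene_Id, Hugo_Symbol)]
  totals <- tal[, .(H = sum(H), I = sum(I), P = sum(P)), by = Entrez_Gene_Id]
  keep_genes <- totals[H + I + P > 0L, Entrez_Gene_Id]
  tal <- tal[Entrez_Gene_Id %in% keep_genes]
  data.table::setorder(tal, Tumor_Sample_Barcode, Entrez_Gene_Id)
  out <- as.data.frame(tal)
  out$H <- as.integer(out$H); out$I <- as.integer(out$I)
  out$U <- as.integer(out$U); out$P <- as.integer(out$P)
  out
}

#' NSEI and HISR gene scores
#'
#' The Nonsynonymous SNA Enrichment Index, `NSEI = (H + I + 1) / (P + 1)`,
#' measures enrichment of protein-altering over silent mutations with +1
#' pseudocounts; the Hyperactivating-to-Inactivating SNA Ratio,
#' `HISR = (H + 1) / (I + 1)`, separates oncogene-like (HISR > 5) from
#' suppressor-like (HISR <= 5) mutation spectra.
#'
#' @param H,I,P non-negative counts (vectorized).
#' @return data.frame with columns `NSEI` and `HISR`.
#' @examples
#' score_gene(H = 9, I = 0, P = 0)   # NSEI 10, HISR 10
#' @export
score_gene <- function(H, I, P) {
  stopifnot(all(H >= 0), all(I >= 0), all(P >= 0))
  data.frame(NSEI = (H + I + 1) / (P + 1), HISR = (H + 1) / (I + 1))
}

#' Gene-level SNA totals and scores
#'
#' Sums the per-patient tallies over patients for each gene and attaches
#' NSEI and HISR.
#'
#' @param tally data.frame from [tally_sna()].
#' @return data.frame `Entrez_Gene_Id`, `Hugo_Symbol`, `H`, `I`, `U`, `P`,
#'   `NSEI`, `HISR`.
#' @export
sna_gene_scores <- function(tally) {
  dt <- data.table::as.data.table(tally)
  g <- dt[, .(Hugo_Symbol = Hugo_Symbol[1L], H = sum(H), I = sum(I),
              U = sum(U), P = sum(P)), by = Entrez_Gene_Id]
  data.table::setorder(g, Entrez_Gene_Id)
  g <- as.data.frame(g)
  cbind(g, score_gene(g$H, g$I, g$P))
}

#' Remove genes with too few informative mutations
#'
#' Genes whose pan-dataset hyperactivating + inactivating + passenger total
#' is below `min_sna` are dropped to ensure sufficient precision of NSEI
#' and HISR; unclear mutations do not count towards the total.
#'
#' @param gene_scores data.frame from [sna_gene_scores()].
#' @param min_sna minimum H+I+P (default 10; a total of exactly 10 is kept).
#' @return the filtered data.frame.
#' @export
filter_low_count <- function(gene_scores, min_sna = 10L) {
  out <- gene_scores[gene_scores$H + gene_scores$I + gene_scores$P >= min_sna, ,
                     drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dense patient x gene SNA count matrix
#'
#' Expands the tally into four dense patient x gene matrices (H, I, U, P),
#' zero-filling absent pairs — the dot-quadruple "0.0.0.0" cells of the
#' reference implementation, which are drawable by the bootstrap.
#'
#' @param tally data.frame from [tally_sna()].
#' @param barcodes,genes optional full axes; default the values observed in
#'   the tally.
#' @return list with integer matrices `H`, `I`, `U`, `P` (patients x genes).
#' @export
sna_count_matrix <- function(tally, barcodes = NULL, genes = NULL) {
  if (is.null(barcodes)) barcodes <- sort(unique(tally$Tumor_Sample_Barcode))
  if (is.null(genes)) genes <- sort(unique(tally$Entrez_Gene_Id))
  shape <- function() matrix(0L, length(barcodes), length(genes),
                             dimnames = list(barcodes, as.character(genes)))
  out <- list(H = shape(), I = shape(), U = shape(), P = shape())
  ri <- match(tally$Tumor_Sample_Barcode, barcodes)
  ci <- match(tally$Entrez_Gene_Id, genes)
  ok <- !is.na(ri) & !is.na(ci)
  idx <- cbind(ri[ok], ci[ok])
  for (comp in names(out)) out[[comp]][idx] <- tally[[comp]][ok]
  out
}

#' Bootstrap null distribution of NSEI and HISR
#'
#' Each iteration draws, for every patient, one cell uniformly with
#' replacement from the entire zero-filled patient x gene count matrix,
#' sums the H/I/U/P quadruples over patients, and scores the sums. The
#' resulting `n_iter` (NSEI, HISR) pairs form the empirical null for a gene
#' aggregating mutations over the same number of patients.
#'
#' @param counts list of matrices from [sna_count_matrix()].
#' @param n_iter iterations (10000 in the reference analysis).
#' @param seed integer seed; same seed gives identical output.
#' @return object of class `sna_null`: list with `NSEI`, `HISR` (numeric
#'   vectors of length `n_iter`), `n_iter`, `seed`.
#' @export
sna_bootstrap_null <- function(counts, n_iter = 10000L, seed = 1L) {
  n_cells <- length(counts$H)
  if (n_cells == 0L) stop("empty SNA count matrix")
  n_pat <- nrow(counts$H)
  set.seed(seed)
  idx <- sample.int(n_cells, n_pat * n_iter, replace = TRUE)
  sum_draws <- function(m) colSums(matrix(m[idx], nrow = n_pat))
  H <- sum_draws(counts$H); I <- sum_draws(counts$I); P <- sum_draws(counts$P)
  sc <- score_gene(H, I, P)
  structure(list(NSEI = sc$NSEI, HISR = sc$HISR,
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "sna_null")
}

#' Empirical gene p-value against the bootstrap null
#'
#' One-sided enrichment test: the fraction of null NSEI values strictly
#' greater than the gene's NSEI. A gene matching the null exactly gets a
#' p-value near the null's upper-tail mass; ties are not smoothed, so an
#' empirical p of 0 is reported as 0.
#'
#' @param nsei numeric vector of observed gene NSEI values.
#' @param null_nsei numeric vector of bootstrap NSEI values (or an
#'   `sna_null` object).
#' @return numeric vector of p-values in [0,1].
#' @export
gene_pvalue <- function(nsei, null_nsei) {
  if (inherits(null_nsei, "sna_null")) null_nsei <- null_nsei$NSEI
  n <- length(null_nsei)
  sorted <- sort(null_nsei)
  # count of null values strictly greater via binary search on sorted vector
  (n - findInterval(nsei, sorted)) / n
}

#' Uniformity diagnostic for the bootstrap null
#'
#' Scores every null iteration against the null itself (the fraction of
#' null NSEI values strictly greater than that iteration's NSEI) and
#' reports a Kolmogorov-Smirnov-style statistic: the maximum absolute
#' deviation of the empirical CDF of these p-values from the uniform CDF,
#' evaluated at the observed points. For an all-distinct null the p-values
#' are a permutation of {0, 1/n, ..., (n-1)/n} and the deviation is 1/n;
#' ties in the discrete NSEI statistic inflate it by the largest tie mass.
#'
#' @param null an `sna_null` object or numeric vector of null NSEI values.
#' @return list with `pvalues` (per-iteration) and `max_deviation`.
#' @export
null_uniformity_check <- function(null) {
  nsei <- if (inherits(null, "sna_null")) null$NSEI else null
  p <- gene_pvalue(nsei, nsei)
  n <- length(p)
  sp <- sort(p)
  ecdf_at <- (seq_len(n)) / n   # empirical CDF evaluated at sorted points
  dev <- max(abs(ecdf_at - sp), abs(sp - (seq_len(n) - 1L) / n))
  list(pvalues = p, max_deviation = dev)
}

#' Select SNA driver genes by BH
#'
#' Benjamini-Hochberg step-up across all tested genes at FDR `q`; passing
#' genes are returned with their scores and p-values.
#'
#' @param gene_scores data.frame with `NSEI`, `HISR` and `p` columns.
#' @param q FDR level (default 0.05).
#' @return the subset of `gene_scores` selected as drivers.
#' @export
select_sna_drivers <- function(gene_scores, q = 0.05) {
  out <- gene_scores[bh_pass(gene_scores$p, q), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the SNADRIF pipeline
#'
#' Tally, score, low-count filter, bootstrap null, empirical p-values and
#' BH selection, in one call. Cohort-specific analysis is obtained by
#' passing the cohort's MAF subset.
#'
#' @param maf filtered MAF data.frame.
#' @param n_iter bootstrap iterations.
#' @param seed integer seed.
#' @param q FDR level.
#' @param min_sna minimum informative mutations per gene.
#' @return list with `tally`, `gene_scores` (tested genes with `p`), `null`
#'   (`sna_null`), `uniformity`, `drivers`.
#' @export
run_snadrif <- function(maf, n_iter = 10000L, seed = 1L, q = 0.05,
                        min_sna = 10L) {
  tally <- tally_sna(maf)
  scores <- sna_gene_scores(tally)
  tested <- filter_low_count(scores, min_sna)
  counts <- sna_count_matrix(tally)
  null <- sna_bootstrap_null(counts, n_iter, seed)
  tested$p <- gene_pvalue(tested$NSEI, null)
  drivers <- select_sna_drivers(tested, q)
  list(tally = tally, gene_scores = tested, null = null,
       uniformity = null_uniformity_check(null), drivers = drivers)
}
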