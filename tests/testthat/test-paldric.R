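paldric_fixture <- function() {
  clinical <- make_clinical(c("TCGA-AA-0001", "TCGA-AA-0002", "TCGA-AB-0001"),
                            acronym = c("BRCA", "BRCA", "COAD"))
  maf <- rbind(
    make_maf("TCGA-AA-0001-01A", "ONC1", 101L, "Missense_Mutation",
             transcript = "ENST1", sub = "p.V600E"),
    make_maf("TCGA-AA-0001-01A", "ONC1", 101L, "Silent",
             transcript = "ENST1", sub = "p.L10L"),
    make_maf("TCGA-AA-0002-01A", "SUP1", 201L, "Nonsense_Mutation",
             transcript = "ENST2", sub = "p.R100X"),
    make_maf("TCGA-AB-0001-01A", "ONC1", 101L, "Missense_Mutation",
             transcript = "ENST1", sub = "p.G12D"))
  samples <- c("TCGA-AA-0001-01A", "TCGA-AA-0002-01A", "TCGA-AB-0001-01A")
  cna <- make_gene_matrix(c(2L, 0L, 0L, -1L, 0L, 0L), entrez = c(101, 201),
                          samples = samples, symbols = c("ONC1", "SUP1"))
  list(clinical = clinical, maf = maf, cna = cna)
}

test_that("gene-level list matching gates on gene, cohort and variant class", {
  fx <- paldric_fixture()
  dl <- make_driver_list("alg", "gene", "cohort", "BRCA", "ONC1", 101L)
  pairs <- match_gene_list(dl, fx$maf, fx$clinical)
  # BRCA missense row matches; the Silent row never does; COAD patient gated out
  expect_equal(pairs$Tumor_Sample_Barcode, "TCGA-AA-0001-01A")
  expect_equal(pairs$Entrez_Gene_Id, 101L)
  # pancancer scope lifts the cohort gate
  dl_pan <- make_driver_list("alg", "gene", "pancancer", NA_character_, "ONC1", 101L)
  expect_equal(nrow(match_gene_list(dl_pan, fx$maf, fx$clinical)), 2L)
  # silent-only genes yield nothing
  dl_sil <- make_driver_list("alg", "gene", "pancancer", NA_character_, "X", 555L)
  expect_equal(nrow(match_gene_list(dl_sil, fx$maf, fx$clinical)), 0L)
})

test_that("mutation-level matching joins on transcript and substitution", {
  fx <- paldric_fixture()
  dl <- make_driver_list("alg", "mutation", "pancancer", NA_character_,
                         "ONC1", 101L, transcript = "ENST1", sub = "p.V600E")
  pairs <- match_mutation_list(dl, fx$maf, fx$clinical)
  expect_equal(pairs$Tumor_Sample_Barcode, "TCGA-AA-0001-01A")
  # same gene, different substitution: no pair
  dl2 <- make_driver_list("alg", "mutation", "pancancer", NA_character_,
                          "ONC1", 101L, transcript = "ENST1", sub = "p.Q61H")
  expect_equal(nrow(match_mutation_list(dl2, fx$maf, fx$clinical)), 0L)
  expect_equal(nrow(match_mutation_list(dl[0, ], fx$maf, fx$clinical)), 0L)
})

test_that("CNA matching requires a nonzero thresholded call on a listed gene", {
  fx <- paldric_fixture()
  dl <- make_driver_list("alg", "gene", "cohort", c("BRCA", "BRCA"),
                         c("ONC1", "SUP1"), c(101L, 201L))
  pairs <- match_cna(dl, fx$cna, fx$clinical)
  expect_equal(nrow(pairs), 2L)
  expect_setequal(paste(pairs$Tumor_Sample_Barcode, pairs$Entrez_Gene_Id),
                  c("TCGA-AA-0001-01A 101", "TCGA-AA-0002-01A 201"))
  dl_unlisted <- make_driver_list("alg", "gene", "cohort", "BRCA", "Z", 999L)
  expect_equal(nrow(match_cna(dl_unlisted, fx$cna, fx$clinical)), 0L)
})

test_that("per-source union and cross-source consensus deduplicate pairs", {
  a <- data.frame(Tumor_Sample_Barcode = c("S1", "S2"),
                  Entrez_Gene_Id = c(1L, 1L), Hugo_Symbol = "A")
  b <- data.frame(Tumor_Sample_Barcode = "S1", Entrez_Gene_Id = 1L,
                  Hugo_Symbol = "A")
  expect_equal(nrow(combine_source(a, b)), 2L)      # duplicate collapses
  expect_equal(nrow(combine_source(a[0, ], b[0, ])), 0L)

  c3 <- data.frame(Tumor_Sample_Barcode = "S9", Entrez_Gene_Id = 5L,
                   Hugo_Symbol = "E")
  cons <- consensus_pairs(list(a, b, c3), min_sources = 2L)
  expect_equal(cons$Tumor_Sample_Barcode, "S1")
  expect_equal(cons$source_count, 2L)
  expect_error(consensus_pairs(list(a), min_sources = 2L), "at least 2")
  # k = 1 is the union; consensus shrinks as min_sources grows
  expect_equal(nrow(consensus_pairs(list(a, b, c3), 1L)), 3L)
  expect_gte(nrow(consensus_pairs(list(a, b, c3), 1L)),
             nrow(consensus_pairs(list(a, b, c3), 2L)))
  expect_gte(nrow(consensus_pairs(list(a, b, c3), 2L)),
             nrow(consensus_pairs(list(a, b, c3), 3L)))
})

test_that("annotation zero-fills counts, leaves HISR missing, defaults cna to 0", {
  pairs <- data.frame(Tumor_Sample_Barcode = c("TCGA-AA-0001-01A", "TCGA-AA-0002-01A"),
                      Entrez_Gene_Id = c(101L, 201L), Hugo_Symbol = c("A", "B"),
                      source_count = 2L)
  tal <- data.frame(Tumor_Sample_Barcode = "TCGA-AA-0001-01A",
                    Entrez_Gene_Id = 101L, Hugo_Symbol = "A",
                    H = 2L, I = 1L, U = 0L, P = 0L)
  gs <- data.frame(Entrez_Gene_Id = 101L, HISR = 7.5)
  vc <- make_gene_matrix(c(2L, 0L, 0L, 0L), entrez = c(101, 201),
                         samples = c("TCGA-AA-0001-01A", "TCGA-AA-0002-01A"))
  ann <- annotate_pairs(pairs, tal, gs, vc)
  expect_equal(ann$H, c(2L, 0L))
  expect_equal(ann$I, c(1L, 0L))
  expect_equal(ann$HISR, c(7.5, NA))
  expect_equal(ann$cna, c(2L, 0L))
})

test_that("event classification reproduces every rule of the table", {
  check <- function(H, I, HISR, cna, class, count) {
    got <- classify_pair(H, I, HISR, cna)
    expect_equal(got$event_class, class)
    expect_equal(got$event_count, count)
  }
  check(1, 0, 8, 0, "SNA_oncogene", 1L)
  check(0, 0, 8, 1, "CNA_oncogene", 1L)
  check(0, 0, 8, 2, "CNA_oncogene", 1L)
  check(1, 0, 8, 2, "mixed_oncogene", 1L)
  check(1, 0, 3, 0, "SNA_suppressor", 1L)
  check(0, 1, 3, 0, "SNA_suppressor", 1L)    # truncating-only still N >= 1
  check(0, 0, 3, -1, "CNA_suppressor", 1L)
  check(0, 1, 3, -2, "mixed_suppressor", 1L)
  check(2, 1, 3, -1, "mixed_suppressor", 1L)
  check(0, 0, 2, 0, "passenger", 0L)
  check(0, 0, NA, 0, "passenger", 0L)
  # "all the rest" fall through to low-probability
  check(1, 1, 8, 0, "low_probability", 0L)   # oncogene-like but I > 0
  check(0, 0, 8, -1, "low_probability", 0L)  # oncogene-like with a deletion
  check(1, 0, NA, 1, "low_probability", 0L)  # unscored gene with alterations
})

test_that("classification is total over an exhaustive grid", {
  grid <- expand.grid(H = 0:3, I = 0:3, HISR = c(NA, 1, 5, 5.01, 10),
                      cna = -2:2)
  got <- classify_pair(grid$H, grid$I, grid$HISR, grid$cna)
  expect_equal(nrow(got), nrow(grid))
  expect_true(all(got$event_class %in%
                  c("SNA_oncogene", "CNA_oncogene", "mixed_oncogene",
                    "SNA_suppressor", "CNA_suppressor", "mixed_suppressor",
                    "passenger", "low_probability")))
  expect_identical(got$event_count,
                   as.integer(!got$event_class %in% c("passenger", "low_probability")))
})

test_that("stage and age normalization collapse substages and decades", {
  expect_equal(normalize_stage(c("Stage IA", "Stage II", "Stage IIIB", "Stage IV",
                                 "T2b", "T4", "X", NA)),
               c("I", "II", "III", "IV", "II", "IV", NA, NA))
  expect_equal(age_bin(c(15, 20, 47, 85, NA)),
               c("<20", "20-29", "40-49", ">=80", NA))
})

test_that("per-patient counts zero-fill clinical patients and honour stage fallback", {
  clinical <- make_clinical(c("TCGA-AA-0001", "TCGA-AA-0002"), "BRCA")
  clinical$pathologic_stage[2] <- NA
  clinical$clinical_stage[2] <- "Stage IVB"
  classified <- data.frame(Tumor_Sample_Barcode = "TCGA-AA-0001-01A",
                           Entrez_Gene_Id = 101L,
                           event_class = "SNA_oncogene", stringsAsFactors = FALSE)
  an_ev <- data.frame(Tumor_Sample_Barcode = c("TCGA-AA-0001-01A", "TCGA-AA-0001-01A"),
                      unit = c("3p", "5q"), label = "DAL", stringsAsFactors = FALSE)
  counts <- count_events(classified, an_ev, clinical)
  expect_equal(counts$total, c(3L, 0L))          # 1 SNA_oncogene + 2 DAL; zero-fill
  expect_equal(counts$DAL, c(2L, 0L))
  expect_equal(counts$stage, c("II", "IV"))      # fallback to clinical_stage
})

test_that("aggregation averages per group and drops empty groups", {
  clinical <- make_clinical(paste0("TCGA-AA-000", 1:4), "BRCA",
                            gender = c("MALE", "MALE", "FEMALE", "FEMALE"))
  classified <- data.frame(
    Tumor_Sample_Barcode = c("TCGA-AA-0001-01A", "TCGA-AA-0002-01A",
                             "TCGA-AA-0002-01A"),
    Entrez_Gene_Id = c(1L, 1L, 2L),
    event_class = "SNA_oncogene", stringsAsFactors = FALSE)
  no_an <- data.frame(Tumor_Sample_Barcode = character(), unit = character(),
                      label = character(), stringsAsFactors = FALSE)
  counts <- count_events(classified, no_an, clinical)
  agg <- aggregate_events(counts, "gender")
  expect_equal(agg$SNA_oncogene[agg$group == "male"], 1.5)   # totals 1 and 2
  expect_equal(agg$SNA_oncogene[agg$group == "female"], 0)
  # total_events grouping: patients with exactly one event average 1
  agg_t <- aggregate_events(counts, "total_events")
  expect_equal(agg_t$SNA_oncogene[agg_t$group == "1"], 1)
  expect_false("0" %in% agg_t$group)
})

test_that("event histograms bin exact totals and preserve the patient sum", {
  clinical <- make_clinical(paste0("TCGA-AA-000", 1:3), "BRCA",
                            gender = c("MALE", "FEMALE", "FEMALE"))
  cls <- data.frame(
    Tumor_Sample_Barcode = c("TCGA-AA-0001-01A", rep("TCGA-AA-0002-01A", 7)),
    Entrez_Gene_Id = 1:8, event_class = "SNA_suppressor",
    stringsAsFactors = FALSE)
  no_an <- data.frame(Tumor_Sample_Barcode = character(), unit = character(),
                      label = character(), stringsAsFactors = FALSE)
  counts <- count_events(cls, no_an, clinical)
  h <- event_histogram(counts)
  expect_equal(unname(h[c("0", "1", "7")]), c(1L, 1L, 1L))
  expect_equal(sum(h), nrow(clinical))
  by_g <- event_histogram(counts, by_gender = TRUE)
  expect_equal(sum(by_g$male) + sum(by_g$female), sum(h))
})

test_that("Welch t-test matches its closed-form behaviour", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  w <- welch_t(c(10, 10, 10, 10.1), c(0, 0, 0, 0))
  expect_lt(w$p, 0.01)
  two <- welch_t(c(5, 6, 7), c(1, 2, 3), tails = 2L)
  one <- welch_t(c(5, 6, 7), c(1, 2, 3), tails = 1L)
  expect_equal(one$p, two$p / 2)
  expect_error(welch_t(c(1), c(1, 2)), "at least 2")
  expect_error(welch_t(c(1, 1), c(2, 2)), "constant")
})
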