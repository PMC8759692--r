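test_that("variant classes partition into the four functional categories", {
  expect_equal(classify_variant("Missense_Mutation"), "hyperactivating")
  expect_equal(classify_variant(c("In_Frame_Del", "In_Frame_Ins",
                                  "De_novo_Start_InFrame")),
               rep("hyperactivating", 3))
  expect_equal(classify_variant(c("Frame_Shift_Del", "Frame_Shift_Ins",
                                  "Nonsense_Mutation", "Nonstop_Mutation",
                                  "Translation_Start_Site")),
               rep("inactivating", 5))
  expect_equal(classify_variant(c("Silent", "De_novo_Start_OutOfFrame")),
               rep("passenger", 2))
  expect_equal(classify_variant(c("3'UTR", "Intron", "RNA", "")),
               rep("unclear", 4))
})

test_that("per-patient tally counts categories and drops unclear-only genes", {
  maf <- rbind(
    make_maf("TCGA-AA-0001-01A", "KRAS", 3845L,
             c("Missense_Mutation", "Missense_Mutation", "Silent")),
    make_maf("TCGA-AA-0002-01A", "NCRNA", 999L, c("5'Flank", "3'UTR")))
  tal <- tally_sna(maf)
  expect_equal(nrow(tal), 1L)
  expect_equal(tal$H, 2L); expect_equal(tal$I, 0L)
  expect_equal(tal$U, 0L); expect_equal(tal$P, 1L)
  expect_equal(nrow(tally_sna(make_maf(character(), character(), integer(),
                                       character()))), 0L)
})

test_that("NSEI and HISR follow the pseudocount formulas", {
  expect_equal(score_gene(0, 0, 0), data.frame(NSEI = 1, HISR = 1))
  expect_equal(score_gene(4, 5, 9), data.frame(NSEI = 1, HISR = 5 / 6))
  expect_equal(score_gene(9, 0, 0), data.frame(NSEI = 10, HISR = 10))
  # monotonicity: one more hyperactivating SNA never lowers either index
  set.seed(8)
  for (k in 1:50) {
    H <- sample(0:20, 1); I <- sample(0:20, 1); P <- sample(0:20, 1)
    s0 <- score_gene(H, I, P); s1 <- score_gene(H + 1, I, P)
    expect_gte(s1$NSEI, s0$NSEI)
    expect_gte(s1$HISR, s0$HISR)
  }
})

test_that("low-count filter uses H+I+P with a strict threshold, excluding U", {
  g <- data.frame(Entrez_Gene_Id = 1:3, H = c(4, 5, 4), I = c(4, 5, 4),
                  P = c(1, 0, 1), U = c(0, 0, 100))
  g$NSEI <- 1; g$HISR <- 1
  kept <- filter_low_count(g, 10L)
  expect_equal(kept$Entrez_Gene_Id, 2L)   # 9 removed, 10 kept, U never counts
})

test_that("the dense count matrix zero-fills absent patient-gene pairs", {
  tal <- data.frame(Tumor_Sample_Barcode = "S1", Entrez_Gene_Id = 1L,
                    Hugo_Symbol = "A", H = 2L, I = 0L, U = 1L, P = 1L)
  cm <- sna_count_matrix(tal, barcodes = c("S1", "S2"), genes = c(1L, 2L))
  expect_equal(cm$H["S1", "1"], 2L)
  expect_equal(sum(cm$H) + sum(cm$I) + sum(cm$U) + sum(cm$P), 4L)
  expect_equal(cm$P["S2", "2"], 0L)
})

test_that("bootstrap null sums drawn quadruples and is seed-deterministic", {
  # all cells zero: every null NSEI is exactly 1
  zero <- sna_count_matrix(data.frame(Tumor_Sample_Barcode = character(),
                                      Entrez_Gene_Id = integer(),
                                      Hugo_Symbol = character(),
                                      H = integer(), I = integer(),
                                      U = integer(), P = integer()),
                           barcodes = c("S1", "S2", "S3"), genes = 1:2)
  n0 <- sna_bootstrap_null(zero, n_iter = 20L, seed = 1L)
  expect_true(all(n0$NSEI == 1))
  # single-cell matrix "1.0.0.1" over 3 patients: forced sums (3,0,0,3)
  tal <- data.frame(Tumor_Sample_Barcode = c("S1", "S2", "S3"),
                    Entrez_Gene_Id = 1L, Hugo_Symbol = "A",
                    H = 1L, I = 0L, U = 0L, P = 1L)
  cm <- sna_count_matrix(tal)
  n1 <- sna_bootstrap_null(cm, n_iter = 20L, seed = 1L)
  expect_true(all(n1$NSEI == 1))          # (3+0+1)/(3+1)
  expect_true(all(n1$HISR == 4))          # (3+1)/(0+1)
  # determinism
  cm2 <- sna_count_matrix(data.frame(Tumor_Sample_Barcode = c("S1", "S2"),
                                     Entrez_Gene_Id = c(1L, 2L),
                                     Hugo_Symbol = "A",
                                     H = c(3L, 0L), I = c(0L, 2L),
                                     U = 0L, P = c(1L, 4L)),
                          barcodes = c("S1", "S2"), genes = 1:2)
  expect_identical(sna_bootstrap_null(cm2, 100L, 9L),
                   sna_bootstrap_null(cm2, 100L, 9L))
})

test_that("gene p-values count strictly greater null values", {
  expect_equal(gene_pvalue(10, c(1, 2, 3, 4)), 0)
  expect_equal(gene_pvalue(0.5, c(1, 2, 3, 4)), 1)
  expect_equal(gene_pvalue(2.5, c(1, 2, 3, 4)), 0.5)
  expect_equal(gene_pvalue(2, c(1, 2, 3, 4)), 0.5)   # ties are not "greater"
})

test_that("null self-p-values are uniform ranks for distinct nulls", {
  u <- null_uniformity_check(c(4, 1, 3, 2))
  expect_setequal(u$pvalues, c(0, 0.25, 0.5, 0.75))
  expect_lte(u$max_deviation, 1 / 4 + 1e-12)
  # constant null: all p-values 0
  uc <- null_uniformity_check(rep(2, 10))
  expect_true(all(uc$pvalues == 0))
})

test_that("driver selection applies BH across all tested genes", {
  g <- data.frame(Entrez_Gene_Id = 1:4, NSEI = 2, HISR = 2,
                  p = c(0.001, 0.012, 0.02, 0.8))
  expect_equal(select_sna_drivers(g, 0.05)$Entrez_Gene_Id, 1:3)
  expect_equal(nrow(select_sna_drivers(transform(g, p = 1), 0.05)), 0L)
  expect_equal(nrow(select_sna_drivers(g[g$p == 0.001, , drop = FALSE], 0.05)), 1L)
})

test_that("gene scores agree with a brute-force recomputation from raw rows", {
  ds <- generate_dataset(truth_config(cohorts = c(BRCA = 15L), n_genes = 40L,
                                      seed = 21L))
  maf <- filter_maf(keep_primary(ds$maf))
  scores <- sna_gene_scores(tally_sna(maf))
  ref <- brute_gene_scores(maf)
  ref <- ref[ref$H + ref$I + ref$P > 0, ]   # unclear-only genes are dropped
  m <- match(scores$Entrez_Gene_Id, ref$Entrez_Gene_Id)
  expect_false(anyNA(m))
  expect_equal(scores$NSEI, ref$NSEI[m], tolerance = 1e-14)
  expect_equal(scores$HISR, ref$HISR[m], tolerance = 1e-14)
})
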