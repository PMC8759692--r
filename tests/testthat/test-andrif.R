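arm_fixture <- function(calls, arms = c("1p", "1q"), prefix = "TCGA-AA") {
  m <- matrix(calls, ncol = length(arms),
              dimnames = list(sprintf("%s-%04d-01A", prefix, seq_len(length(calls) / length(arms))),
                              arms))
  storage.mode(m) <- "integer"
  m
}

test_that("cohort averages ignore missing calls and flag unknown cohorts", {
  m <- arm_fixture(c(1L, 1L, 0L, -1L,  1L, NA, 1L, 0L))
  cohort_of <- stats::setNames(rep("BRCA", 4), rownames(m))
  avg <- aneuploidy_unit_averages(m, cohort_of)
  expect_equal(avg["BRCA", "1p"], 0.25)
  expect_equal(avg["BRCA", "1q"], 2 / 3)      # missing excluded
  expect_equal(unname(aneuploidy_unit_averages(
    arm_fixture(rep(0L, 8)), cohort_of)["BRCA", ]), c(0, 0))
  expect_error(aneuploidy_unit_averages(m, cohort_of[-1]), "TCGA-AA-0001")
})

test_that("bootstrap null reflects the pooled cell distribution", {
  # degenerate pools
  zeros <- arm_fixture(rep(0L, 8))
  null0 <- aneuploidy_bootstrap_null(zeros, c(BRCA = 4L), n_iter = 50L, seed = 1L)
  expect_true(all(null0$averages == 0))
  expect_equal(unname(null0$medians["BRCA"]), 0)
  ones <- arm_fixture(rep(1L, 8))
  null1 <- aneuploidy_bootstrap_null(ones, c(BRCA = 4L), n_iter = 50L, seed = 1L)
  expect_true(all(null1$averages == 1))
  # symmetric half +1 / half -1 pool: median of averages near 0
  sym <- arm_fixture(rep(c(1L, -1L), 100))
  nulls <- aneuploidy_bootstrap_null(sym, c(BRCA = 100L), n_iter = 10000L, seed = 2L)
  expect_lt(abs(nulls$medians[["BRCA"]]), 0.02)
  # missing cells never enter the pool
  expect_error(aneuploidy_bootstrap_null(arm_fixture(rep(NA_integer_, 8)),
                                         c(BRCA = 4L), 10L, 1L),
               "no non-missing")
  # determinism: same seed, identical object
  expect_identical(aneuploidy_bootstrap_null(sym, c(BRCA = 100L), 200L, 7L),
                   aneuploidy_bootstrap_null(sym, c(BRCA = 100L), 200L, 7L))
})

test_that("signed empirical p tests only the matching direction", {
  null <- structure(list(averages = matrix(seq(-0.1, 0.1, length.out = 100),
                                           100, 1, dimnames = list(NULL, "BRCA")),
                         medians = c(BRCA = 0), n_iter = 100L, seed = 1L),
                    class = "aneuploidy_null")
  above_all <- signed_empirical_p(0.5, null, "BRCA")
  expect_equal(above_all$magnitude, 0)
  expect_equal(above_all$direction, "gain")
  expect_null(signed_empirical_p(0, null, "BRCA"))
  # positive but not above the median is ignored
  null$medians <- c(BRCA = 0.05)
  expect_null(signed_empirical_p(0.01, null, "BRCA"))
  # loss side symmetric, count divided by n_iter/2
  null$medians <- c(BRCA = 0)
  loss <- signed_empirical_p(-0.09, null, "BRCA")
  expect_equal(loss$direction, "loss")
  expect_equal(loss$magnitude, sum(null$averages[, 1] < -0.09) / 50)
})

test_that("per-cohort BH selection matches the step-up oracle and maps labels", {
  pv <- data.frame(cohort = "BRCA", unit = c("1p", "2p", "3p", "4p"),
                   p = c(0.001, 0.012, 0.02, 0.8),
                   direction = c("gain", "loss", "gain", "gain"),
                   stringsAsFactors = FALSE)
  sel <- bh_select_aneuploidy(pv, q = 0.05, scope = "arm")
  expect_equal(sort(sel$unit), c("1p", "2p", "3p"))
  expect_equal(sel$label[sel$unit == "2p"], "DAL")
  expect_equal(sel$label[sel$unit == "1p"], "DAG")
  chrom_sel <- bh_select_aneuploidy(transform(pv, unit = c("1", "2", "3", "4")),
                                    q = 0.05, scope = "chromosome")
  expect_equal(sort(chrom_sel$label), c("DCG", "DCG", "DCL"))
  # single p = 0 selected; all p = 1 none
  expect_equal(nrow(bh_select_aneuploidy(transform(pv[1, ], p = 0), 0.05, "arm")), 1L)
  expect_equal(nrow(bh_select_aneuploidy(transform(pv, p = 1), 0.05, "arm")), 0L)
})

test_that("chromosome calls require both arms to agree", {
  arms <- arm_fixture(c(1L, 1L, 0L, NA,  1L, -1L, 0L, 1L),
                      arms = c("2p", "2q"))
  ch <- chromosome_calls(arms)
  expect_identical(unname(ch[, "2"]), c(1L, 0L, 0L, NA))
  both_loss <- chromosome_calls(arm_fixture(c(-1L, -1L), arms = c("5p", "5q")))
  expect_identical(unname(both_loss[1, "5"]), -1L)
  # one-arm chromosomes take the arm status verbatim
  acro <- chromosome_calls(arm_fixture(c(-1L, 1L), arms = "13q"))
  expect_identical(unname(acro[, "13"]), c(-1L, 1L))
  expect_error(chromosome_calls(arm_fixture(0L, arms = "weird")), "unparseable")
})

test_that("patient events honour labels, signs and the chromosome override", {
  arms <- arm_fixture(c(-1L, 1L, 0L,  1L, 1L, 0L,  1L, 0L, 0L),
                      arms = c("3p", "7p", "7q"))
  chroms <- chromosome_calls(arms)
  cohort_of <- stats::setNames(rep("BRCA", 3), rownames(arms))
  arm_labels <- data.frame(cohort = "BRCA", unit = c("3p", "7p"),
                           label = c("DAL", "DAG"), stringsAsFactors = FALSE)
  chrom_labels <- data.frame(cohort = "BRCA", unit = "7",
                             label = "DCG", stringsAsFactors = FALSE)
  ev <- aneuploidy_patient_events(arms, chroms, arm_labels, chrom_labels, cohort_of)
  p1 <- ev[ev$Tumor_Sample_Barcode == "TCGA-AA-0001-01A", ]
  # patient 1: 3p=-1 on DAL -> event; chr7 gained (7p=7q=1) -> DCG, 7p DAG suppressed
  expect_setequal(p1$label, c("DAL", "DCG"))
  expect_false(any(p1$unit == "7p"))
  # patient 2: 3p=+1 on DAL -> no event (sign mismatch); 7p=1 DAG but 7q=0 -> arm event kept
  p2 <- ev[ev$Tumor_Sample_Barcode == "TCGA-AA-0002-01A", ]
  expect_equal(p2$label, "DAG")
  expect_equal(p2$unit, "7p")
  # patient 3: nothing
  expect_false("TCGA-AA-0003-01A" %in% ev$Tumor_Sample_Barcode)
})

test_that("summary counts tally driver gains and losses per cohort and unit", {
  labels <- data.frame(cohort = c("BRCA", "BRCA", "COAD"),
                       unit = c("1q", "8p", "1q"),
                       label = c("DAG", "DAL", "DAG"), stringsAsFactors = FALSE)
  s <- andrif_summary(labels)
  expect_equal(as.integer(s$gains_per_cohort[c("BRCA", "COAD")]), c(1L, 1L))
  expect_equal(as.integer(s$cohorts_with_gain_per_unit[["1q"]]), 2L)
  expect_equal(as.integer(s$losses_per_cohort[["BRCA"]]), 1L)
})
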