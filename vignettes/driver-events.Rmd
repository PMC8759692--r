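---
title: "Predicting and classifying patient-level cancer driver events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and classifying patient-level cancer driver events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverscape)
```

## The problem

Most cancer driver prediction works at the cohort level and on point
mutations only. `driverscape` implements a workflow that covers three
molecular classes of driver events — single nucleotide alterations (SNAs),
copy-number alterations (CNAs) and aneuploidy (arm and whole-chromosome
gains/losses) — and converts cohort-level calls into classified,
countable events for each individual patient. The inputs are
TCGA-PanCanAtlas-style TSV files: an mc3-dialect somatic mutation table, a
GISTIC-thresholded gene×sample CNA matrix, gene and miRNA expression
matrices, a sample×arm aneuploidy call table, a clinical patient table,
sample-quality annotations and ABSOLUTE purity calls, plus driver
gene/mutation lists from external algorithms.

Four pipelines are composable behind one interface:

* **GECNAV** — validates thresholded CNA calls against relative expression.
* **ANDRIF** — calls driver arm/chromosome gains and losses per cohort
  against a bootstrap null.
* **SNADRIF** — discovers SNA driver genes from nonsynonymous/silent
  enrichment and labels them oncogene- or suppressor-like.
* **PALDRIC** — converts cohort-level driver lists to patient-level pairs,
  classifies each pair, merges aneuploidy events and aggregates counts by
  clinical groups.

## Initial filtering

All files are first restricted to primary-tumour samples (TCGA sample type
codes 01, 03, 09) and samples flagged `Do_not_use` in the quality
annotations are removed. Mutation rows must carry `FILTER == "PASS"`; zero
Entrez ids are repaired from the Ensembl gene id where a mapping is
available. The aneuploidy table alone is additionally filtered on ABSOLUTE
purity: samples with Cancer DNA fraction `< 0.5` or unknown, or Subclonal
genome fraction `> 0.5` or unknown, are dropped. Both thresholds are read
as strict inequalities, so a fraction of exactly 0.5 passes — the literal
reading of the printed rules. The clinical table keeps patients with
ICD-O-3 histology `*/3` (primary malignant neoplasm) that are present in
all three molecular data types.

Two joining conventions are needed because TCGA files carry barcodes of
different depths: clinical joins use the 12-character patient id, and
molecular joins truncate both barcode sets to their shared prefix length.
When several primary samples of one patient survive filtering, the
lexicographically smallest barcode is kept — an arbitrary but deterministic
tie-break.

## GECNAV: expression-validated copy number

For each gene the median expression *m* across patients is the reference.
Expression *x* is encoded on the CNA scale:

| code | band |
|------|---------------------------|
| −2 | *x* < 0.05 *m* |
| −1 | 0.05 *m* ≤ *x* < 0.75 *m* |
| 0 | 0.75 *m* ≤ *x* ≤ 1.25 *m* |
| 1 | 1.25 *m* < *x* ≤ 1.75 *m* |
| 2 | *x* > 1.75 *m* |

The published thresholds (0.05/0.75/1.25/1.75) leave boundary membership
open; the bands above are closed so that they partition the axis totally
and deterministically, with the median itself always coding 0. A zero
median is degenerate and codes the whole row 0.

A nonzero CNA call survives validation only when the expression code of
that gene in that sample is nonzero with the same sign; the cell then
takes the expression code itself (an amplification "2" may become "1").
Discordant cells become 0. Genes with no expression row — and samples
absent from the expression matrices — pass through unchanged, since
absence of evidence is not discordance. A gene is routed to the miRNA code
matrix exactly when its symbol appears there.

## ANDRIF: aneuploidy drivers

Per cohort and chromosomal unit, the observed statistic is the mean of the
non-missing {−1, 0, 1} calls. The null is built by drawing, for each
cohort, `n` statuses (its sample count) uniformly with replacement from
the pool of **all** non-missing cells of the whole table — all cohorts and
all units pooled, the literal reading of "from any cell" — 10 000 times by
default. Missing calls never enter the pool or the averages.

A cohort average is tested only in its own direction: a positive average
above the cohort's bootstrap median scores `(# averages > observed) /
(n_iter/2)` as a gain (5 000 for the reference 10 000 iterations);
negative averages below the median are scored symmetrically as losses.
Dividing a one-sided count by half the iterations doubles the tail — a
two-sided correction retained for fidelity; magnitudes are capped at 1 so
Benjamini–Hochberg (applied per cohort, FDR 5%) stays well defined.
Passing gains/losses become DAG/DAL at arm scope and DCG/DCL at chromosome
scope.

Whole-chromosome calls require both arms to agree (both 1 → 1, both −1 →
−1, any missing arm → missing, else 0); the acrocentric chromosomes 13,
14, 15, 21 and 22 take their single (q) arm verbatim. A patient's −1 call
on a DAL/DCL unit, or +1 on a DAG/DCG unit, is one event; a patient's
chromosome event suppresses that patient's events on both arms of the
same chromosome, preventing triple counting. The suppression is applied at
the patient-event level: an arm event survives when the patient's own
chromosome call did not fire, even if the cohort carries a chromosome
label.

One caveat follows from the pan-table pool: single-arm chromosomes keep
the full per-arm call variance while two-arm chromosomes are near zero
unless both arms agree, so at chromosome scope the acrocentrics are
overdispersed relative to the pooled null and attract more labels than the
nominal FDR suggests. The arm scope, where all units are exchangeable
under the null, is well calibrated; the test suite checks the combined
labelled fraction on null data.

## SNADRIF: SNA drivers

Variant classifications partition into four categories: truncating classes
(`Frame_Shift_Del/Ins`, `Nonsense_Mutation`, `Nonstop_Mutation`,
`Translation_Start_Site`) are potentially **inactivating** (I);
protein-altering non-truncating classes (`Missense_Mutation`,
`In_Frame_Del/Ins`, `De_novo_Start_InFrame`) potentially
**hyperactivating** (H); `Silent` and `De_novo_Start_OutOfFrame` are
**passengers** (P); everything else is **unclear** (U) and never enters a
score. Genes observed only with unclear mutations (typically noncoding)
are removed.

Two indices summarize a gene's pan-dataset counts:

$$\mathrm{NSEI} = \frac{H + I + 1}{P + 1}, \qquad
  \mathrm{HISR} = \frac{H + 1}{I + 1}$$

NSEI measures enrichment of protein-altering over silent mutations
(pseudocounts keep it defined at zero counts); HISR > 5 marks an
oncogene-like spectrum, HISR ≤ 5 suppressor-like. Genes with
H + I + P < 10 are dropped for precision (U does not count).

The empirical null draws, for each patient, one cell uniformly from the
**entire** zero-filled patient×gene count matrix (absent pairs are
drawable zero quadruples), sums the H/I/U/P quadruples across patients and
scores the sums; 10 000 iterations by default. A gene's p-value is the
fraction of null NSEI values strictly greater than its own — a one-sided
enrichment test, so depletion is never called — reported without
smoothing, so an empirical p of 0 stays 0 (a known granularity limitation
for BH). BH at FDR 5% across all tested genes yields the driver list;
cohort-specific analysis reruns the whole pipeline on the cohort's rows.

### Null p-value uniformity and its limits

A diagnostic scores every null iteration against the null itself and
reports the maximum deviation of the p-value ECDF from the uniform CDF.
For an all-distinct null this deviation is exactly 1/n. The NSEI of summed
counts is, however, a discrete statistic: with a few thousand informative
mutations the hyperactivating+inactivating and passenger sums are
moderate-mean counts, and the probability that an iteration lands exactly
on NSEI = 1 (equal sums) is of order 10%. Every tied iteration shares one
p-value, so the ECDF necessarily jumps by the tie mass and the deviation
cannot approach the 1.36·2/√n bound of a continuous Kolmogorov–Smirnov
comparison at any iteration count — the deviation shrinks only like
1/√(mutation count), not with iterations. The diagnostic is therefore
reported for inspection (as a histogram would be) rather than used as a
gate; the FDR calibration of the final driver list is checked directly on
null data instead.

## PALDRIC: patient-level classification

Cohort-level driver lists are converted to (patient, gene) pairs three
ways: gene-level lists match MAF rows by Entrez id, mutation-level lists
by (Ensembl transcript, substitution) — preserving mutation-level
granularity — and every gene-level list also matches nonzero thresholded
CNA calls. Only protein-altering variant classes count, and cohort-scope
entries require the patient's cohort (via the clinical acronym) to match.
Each source's SNA- and CNA-derived pairs are unioned; pairs present in
fewer than `min_sources` (default 2) of the sources are discarded.

Each surviving pair is annotated with its H and I counts (0 when absent),
the gene's HISR (missing when the gene was not scored) and the
expression-validated CNA status (0 when absent), then classified with
N = H + I:

| class | N | I | HISR | CNA | events |
|---|---|---|---|---|---|
| SNA-based oncogene | ≥1 | 0 | >5 | 0 | 1 |
| CNA-based oncogene | 0 | 0 | >5 | 1, 2 | 1 |
| Mixed oncogene | ≥1 | 0 | >5 | 1, 2 | 1 |
| SNA-based suppressor | ≥1 | ≥0 | ≤5 | 0 | 1 |
| CNA-based suppressor | 0 | 0 | ≤5 | −1, −2 | 1 |
| Mixed suppressor | ≥1 | ≥0 | ≤5 | −1, −2 | 1 |
| Passenger | 0 | 0 | | 0 | 0 |
| Low-probability driver | all the rest | | | | 0 |

The first column is read as the **total** nonsynonymous count H + I: that
is the only reading under which a gene whose pairs carry only truncating
SNAs classifies as an SNA-based suppressor, consistent with the suppressor
rows' I ≥ 0. An alternative reading (hyperactivating-only) would push
I-only pairs into the low-probability class; the chosen reading keeps the
table internally consistent. A missing HISR fails both the ">5" and "≤5"
tests, so unscored genes yield passengers (no alteration) or
low-probability drivers (any alteration).

Per patient, the six gene-level driver classes plus DCL/DCG/DAL/DAG are
counted; passengers and low-probability pairs are tallied for reference
but excluded from the total. Clinical patients with no events appear with
all-zero counts. The stage is `pathologic_stage` with fallbacks
`clinical_stage`, `pathologic_T`, `clinical_T`, normalized to I–IV by
stripping sub-stage letters and mapping T1–T4 to I–IV (anything else is
missing, matching the stage-level resolution of the aggregated outputs).
Ages bin into decades (<20, 20–29, …, ≥80) — a conventional choice where
no exact edges are published. Aggregations report per-group arithmetic
means by gender, age bin, stage, cohort, or each integer total 1–100;
histograms count patients at each integer total 0–100 (larger totals clamp
into the last bin with a message). Group comparisons use Welch's
heteroscedastic t-test with Welch–Satterthwaite degrees of freedom, one-
or two-tailed.

## Benchmarking

Prediction sets at gene or gene-cohort level support overlap-of-k
consensus, sensitivity (percentage of a positive-control list recovered)
and specificity (percentage of non-positive universe items not predicted).
The universe must be supplied explicitly — in practice all genes observed
in the filtered mutation table — because "all genes" is otherwise
unpinned; any fixed universe makes the quantity well defined and
comparable across algorithms.

## The synthetic-data generator

`truth_config()` / `generate_dataset()` produce a complete, internally
consistent dataset with planted ground truth, so every stage is testable
offline. The defaults describe the null study conditions used throughout
the test suite: four cohorts of 50 patients over a 500-gene panel; a
background SNA probability of 0.1 per patient-gene, giving roughly 50
somatic SNAs per patient in the panel (a mutation-rich exome scaled to
panel size) and about 20 informative mutations per gene so genes clear the
H+I+P ≥ 10 filter; a silent fraction of 0.5 among informative mutations so
neutral genes sit at NSEI ≈ 1; symmetric arm-call noise of 0.05 with 2%
missing calls; a 2% background CNA rate; 90% expression–copy-number
concordance; and a small rate of non-PASS mutation rows that the filters
must remove. SNA categories are planted directly at the
`Variant_Classification` level — the pipelines consume classifications,
not sequences, so no codon model is simulated.

Planted oncogenes receive missense SNAs and +2 amplifications in their
cohort at configurable per-patient probabilities, suppressors truncating
SNAs and −2 deletions; planted genes carry exactly their planted spectrum
(background mutations go to background genes only). Planted arm events set
the configured direction at the configured frequency over the noise.
Concordant expression is shifted beyond the ±coding thresholds
(2.5–3.5× the baseline for gains, 0.2–0.5× for losses), discordant cells
stay in the neutral band.

The generator does **not** emulate mutational signatures, gene length or
replication-timing covariates, correlated CNA segments, subclonal
structure, or real purity effects. Passing recovery and calibration tests
on these data therefore demonstrates that the pipelines implement their
rules correctly and are calibrated under exchangeable nulls — not that
they are robust to the covariate structure of real tumours, which is
precisely what the third-party algorithms ingested by PALDRIC model.

## Numerical choices and reproducibility

* Every random stage takes an explicit integer seed; the generator is a
  deterministic function of its configuration, and a pipeline run derives
  distinct sub-seeds for the arm, chromosome and SNA bootstraps so the
  whole run is reproducible bit for bit.
* BH selection is `stats::p.adjust(method = "BH")`; the test suite pins it
  exactly against an independent step-up implementation.
* Empirical p-values use strict inequalities and no smoothing; bootstrap
  magnitudes are capped at 1 before BH.
* Missing cells are empty strings on disk and `NA` in memory, never 0.
* The test suite runs the bootstraps at 2 000 iterations and calibration
  over 20 replicates of the default 200-patient configuration — sizes at
  which every check is stable from run to run while the suite stays fast.

## Known limitations

* The pooled SNADRIF null is gene-unspecific: genes near the count
  threshold with a chance excess of nonsynonymous mutations can reach
  p = 0, and the granularity of count/10 000 p-values limits BH. The
  realized false-discovery fraction on null data is nonetheless far below
  5% (checked in the test suite).
* The KS-style uniformity bound is unattainable for the discrete NSEI
  statistic (see above); the diagnostic is informative, not a gate.
* Chromosome-scope ANDRIF inherits acrocentric overdispersion from the
  pan-table pool; interpret acrocentric chromosome labels with care.
* Epigenetic drivers and driver-strength estimation are out of scope.
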