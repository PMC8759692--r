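Package: driverscape
Title: Patient-Level Prediction and Classification of Cancer Driver Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts, classifies and quantifies per-patient cancer driver
    events from TCGA-PanCanAtlas-style inputs. Implements four composable
    pipelines: expression-based validation of GISTIC-thresholded copy-number
    calls (GECNAV), bootstrap-calibrated driver calling for chromosome-arm
    and whole-chromosome aneuploidy (ANDRIF), single-nucleotide-alteration
    driver gene discovery from nonsynonymous/silent enrichment with an
    empirical bootstrap null and Benjamini-Hochberg selection (SNADRIF), and
    conversion of cohort-level driver lists into classified patient-level
    driver events with clinical aggregation (PALDRIC). Includes benchmarking
    against positive-control gene lists and a synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
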