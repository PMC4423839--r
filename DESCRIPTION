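Package: pdxfidelity
Title: Transcriptome Fidelity Analysis for Patient-Derived Xenografts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how faithfully patient-derived xenografts (PDX)
    preserve the expression profile of the originating tumor biopsy. Builds
    patient/xenograft comparison pairs, scores them by Spearman rank correlation
    with a mean-minus-k-SD outlier rule, screens fold-change differential genes
    per pair and combines them into a cross-dataset consensus with leave-one-out
    stability, tests consensus sets for gene-set enrichment with a per-pair
    robustness score, compares biopsies against PDX, cell-line and other-patient
    reference panels after empirical-Bayes batch adjustment, and runs a
    ridge-regression simulation mapping expression perturbation to drug-response
    prediction change. A synthetic-data module generates PDX cohorts and
    cell-line drug-response panels with known ground truth so the whole pipeline
    is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    stats,
    utils
Suggests:
    sva,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
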