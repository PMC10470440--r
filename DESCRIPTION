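Package: ctdnawatch
Title: Longitudinal Tumor-Agnostic ctDNA Panel Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Background-aware beta-binomial variant calling for deep targeted
    panel sequencing of circulating tumor DNA (ctDNA), together with the
    downstream analytics needed to monitor checkpoint-inhibitor response in
    metastatic melanoma without a matched tumor biopsy: germline SNP exclusion
    and cancer-driver annotation filters, per-patient longitudinal
    mutant-allele-frequency and detection summaries, nonparametric group
    comparisons and Kaplan-Meier survival analysis, an in-silico spike-in
    limit-of-detection benchmark, and a seeded synthetic cohort generator with
    truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, survival, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
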