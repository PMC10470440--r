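mk_calls <- function(p_series, patient = "P01", maf = 0.02) {
  data.frame(patient_id = patient, sample_id = paste0(patient, "_t",
                                                      seq_along(p_series)),
             timepoint_day = 21 * (seq_along(p_series) - 1),
             chromosome = "chr1", coordinate = 100, gene = "GENE01",
             ref = "A", alt = "T", maf = maf, p_value = p_series,
             stringsAsFactors = FALSE)
}

test_that("significance retention is any-timepoint with inclusive boundary", {
  expect_equal(nrow(filter_significant(mk_calls(c(0.20, 0.04, 0.60)))), 1)
  expect_equal(nrow(filter_significant(mk_calls(c(0.051, 0.10)))), 0)
  expect_equal(nrow(filter_significant(mk_calls(c(0.05, 0.9)))), 1)
  expect_equal(nrow(filter_significant(mk_calls(0.5)[0, ])), 0)
})

test_that("SNP rules fire in their documented order", {
  expect_equal(snp_filter(0.45)$reason, "maf_gt_0.4")
  r <- snp_filter(c(0.01, 0.02), gnomad_af = 0.02)
  expect_true(r$excluded)
  expect_equal(r$reason, "popfreq_gt_0.01")
  expect_equal(snp_filter(c(0.12, 0.11, 0.13))$reason, "likely_snp_constant")
  # first matching rule wins: a MAF > 0.4 series that is also popfreq-high
  expect_equal(snp_filter(c(0.45, 0.46), exac_af = 0.3)$reason, "maf_gt_0.4")
  # boundary cases are exclusive (strictly greater than)
  expect_false(snp_filter(c(0.4), gnomad_af = 0.01)$excluded)
  # constancy rule needs at least two timepoints
  expect_false(snp_filter(0.2)$excluded)
  # varying high MAF is not a likely SNP
  expect_false(snp_filter(c(0.12, 0.30))$excluded)
  # widening the tolerance can only add constant-SNP exclusions
  expect_true(snp_filter(c(0.12, 0.30), constant_tol = 0.2)$excluded)
})

test_that("driver classification implements both census rules", {
  d <- classify_driver("missense", TRUE, TRUE, FALSE, "tumor_suppressor", 0)
  expect_true(d$is_driver)
  expect_equal(d$rule, "tsg_2of3")
  expect_true(classify_driver("missense", NA, NA, NA, "oncogene", 3)$is_driver)
  expect_false(classify_driver("missense", NA, NA, NA, "oncogene", 2)$is_driver)
  # stop-gain counts as deleterious wherever a predictor made no call
  expect_true(classify_driver("stopgain", NA, NA, NA,
                              "tumor_suppressor", 0)$is_driver)
  expect_true(classify_driver("frameshift", TRUE, NA, NA,
                              "tumor_suppressor", 0)$is_driver)
  # but missing verdicts never count for non-truncating variants
  expect_false(classify_driver("missense", TRUE, NA, NA,
                               "tumor_suppressor", 0)$is_driver)
  # "both" genes qualify under either rule
  expect_true(classify_driver("missense", TRUE, TRUE, NA, "both", 0)$is_driver)
  expect_true(classify_driver("missense", FALSE, FALSE, NA, "both", 5)$is_driver)
  # unlisted or "other" genes never qualify
  expect_false(classify_driver("stopgain", TRUE, TRUE, TRUE, NA, 99)$is_driver)
  expect_false(classify_driver("stopgain", TRUE, TRUE, TRUE, "other", 99)$is_driver)
})

test_that("the cascade keeps injected drivers and drops injected SNPs", {
  coh <- small_cohort()
  vt <- small_vt()
  tt <- truth_table(coh)
  ret <- unique(paste(vt$patient_id, vt$key))
  snps <- unique(paste(tt$patient_id, tt$key)[tt$kind == "germline_snp"])
  expect_length(intersect(snps, ret), 0)
  drivers <- unique(paste(tt$patient_id, tt$key)[tt$kind == "somatic_driver"])
  expect_gt(length(intersect(drivers, ret)) / length(drivers), 0.5)
  # retained drivers carry rows for every timepoint the caller scored
  one <- vt[vt$patient_id == vt$patient_id[1] & vt$key == vt$key[1], ]
  clin <- coh$clinical
  expect_equal(sort(one$timepoint_day),
               clin$sample_days[[match(one$patient_id[1],
                                       clin$patient_id)]])
})

test_that("the cascade is idempotent and monotone in alpha", {
  coh <- small_cohort()
  calls <- small_calls()
  vt1 <- suppressMessages(build_variant_table(calls, coh$annotation,
                                              coh$drivers, alpha = 0.05))
  # idempotent: re-filtering the output's calls yields the same key set
  sub <- calls[paste(calls$patient_id,
                     variant_key(calls$chromosome, calls$coordinate,
                                 calls$ref, calls$alt)) %in%
                 paste(vt1$patient_id, vt1$key), , drop = FALSE]
  attr(sub, "all_alts") <- NULL
  vt2 <- suppressMessages(build_variant_table(sub, coh$annotation,
                                              coh$drivers, alpha = 0.05))
  expect_setequal(unique(paste(vt2$patient_id, vt2$key)),
                  unique(paste(vt1$patient_id, vt1$key)))
  # lowering alpha never adds variants
  vt_lo <- suppressMessages(build_variant_table(calls, coh$annotation,
                                                coh$drivers, alpha = 0.01))
  expect_true(all(paste(vt_lo$patient_id, vt_lo$key) %in%
                    paste(vt1$patient_id, vt1$key)))
})

test_that("unannotated calls are flagged and classified non-driver", {
  calls <- mk_calls(c(0.01, 0.2))
  ann <- small_cohort()$annotation[0, ]
  drv <- small_cohort()$drivers
  expect_message(vt <- build_variant_table(calls, ann, drv),
                 "missing from the annotation")
  expect_equal(nrow(vt), 0)
  aud <- attr(vt, "audit")
  expect_false(aud$annotated)
  expect_false(aud$is_driver)
})

test_that("variant_key is exported and stable", {
  expect_equal(variant_key("chr7", 140753336, "A", "T"),
               "chr7:140753336:A>T")
})
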