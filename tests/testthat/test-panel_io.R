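test_that("count matrix round-trips bit-exactly through TSV", {
  set.seed(5)
  cm <- small_cohort()$counts
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, f)
  cm2 <- read_count_matrix(f)
  expect_identical(cm2$sample_ids, cm$sample_ids)
  expect_equal(cm2$positions, cm$positions)
  expect_identical(unname(cm2$counts), unname(cm$counts))
})

test_that("single-position multi-sample and degenerate count files parse", {
  src <- lod_background(n_samples = 93, depth = 500, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(src, f)
  cm <- read_count_matrix(f)
  expect_equal(n_samples(cm), 93)
  expect_equal(n_positions(cm), 1)

  # header-only file -> 0 samples
  writeLines(readLines(f)[1], f)
  cm0 <- read_count_matrix(f)
  expect_equal(n_samples(cm0), 0)

  # zero coverage is written as zeros, not blanks
  z <- count_matrix(array(0L, c(1, 1, 10)), "s1",
                    data.frame(chromosome = "chr1", coordinate = 1,
                               gene = "TERT", region_class = "promoter"))
  write_count_matrix(z, f)
  row <- strsplit(readLines(f)[2], "\t")[[1]]
  expect_identical(row[6:15], rep("0", 10))
  expect_equal(sum(read_count_matrix(f)$counts), 0)
})

test_that("count matrix reader rejects malformed input with file context", {
  cm <- lod_background(n_samples = 3, depth = 100, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, f)
  lines <- readLines(f)
  # negative count
  writeLines(c(lines[1], sub("\t\\d+$", "\t-4", lines[2]), lines[3:4]), f)
  expect_error(read_count_matrix(f), "non-negative integer")
  # duplicated (sample, position) row
  writeLines(c(lines, lines[2]), f)
  expect_error(read_count_matrix(f), "duplicate")
  # missing channel column
  df <- read.delim(f)
  df$X_rev <- NULL
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_count_matrix(f), "missing required column")
})

test_that("clinical table round-trips and rejects invalid records", {
  clin <- small_cohort()$clinical
  f <- withr::local_tempfile(fileext = ".tsv")
  write_clinical_table(clin, f)
  clin2 <- read_clinical_table(f)
  expect_equal(clin2$patient_id, clin$patient_id)
  expect_equal(clin2$metastatic_load, clin$metastatic_load)
  expect_equal(clin2$sample_days, clin$sample_days)

  lines <- readLines(f)
  writeLines(sub("\tresponse\t", "\tresponder\t", lines), f)
  expect_error(read_clinical_table(f), "unknown category")

  writeLines(sub("0;21;42", "0;42;21", lines), f)
  expect_error(read_clinical_table(f), "strictly increasing")

  writeLines(sub("0;21;42", "21;42;63", lines), f)
  expect_error(read_clinical_table(f), "day 0")
})

test_that("single-baseline-sample patients are valid clinical records", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("patient_id", "response_category", "n_metastatic_sites",
                     "survival_days", "death_observed", "sample_days",
                     sep = "\t"),
               paste("P01", "response", "2", "410", "FALSE", "0",
                     sep = "\t")), f)
  clin <- read_clinical_table(f)
  expect_equal(clin$sample_days[[1]], 0)
  expect_equal(clin$metastatic_load, "low")
})

test_that("annotation table keeps missing verdicts and rejects duplicates", {
  ann <- small_cohort()$annotation
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(ann, f)
  ann2 <- read_annotation_table(f)
  expect_equal(ann2$key, ann$key)
  expect_equal(ann2$gnomad_af, ann$gnomad_af)
  expect_equal(ann2$sift_deleterious, ann$sift_deleterious)

  # all three predictors missing stays tri-state missing
  one <- as.data.frame(ann)[1, ]
  one$sift_deleterious <- NA
  one$polyphen_damaging <- NA
  one$mutationtaster_deleterious <- NA
  write.table(one[setdiff(names(one), "key")], f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  a3 <- read_annotation_table(f)
  expect_true(is.na(a3$sift_deleterious) && is.na(a3$polyphen_damaging) &&
                is.na(a3$mutationtaster_deleterious))

  dup <- rbind(as.data.frame(ann), as.data.frame(ann)[1, ])
  write.table(dup[setdiff(names(dup), "key")], f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_annotation_table(f), "duplicate variant key")
})

test_that("driver gene list round-trips, allows empty, rejects re-listing", {
  drv <- small_cohort()$drivers
  f <- withr::local_tempfile(fileext = ".tsv")
  write_driver_genes(drv, f)
  drv2 <- read_driver_genes(f)
  expect_equal(as.data.frame(drv2), as.data.frame(drv))
  expect_true("TERT" %in% drv2$gene)

  writeLines(c("gene\trole"), f)
  expect_equal(nrow(read_driver_genes(f)), 0)

  writeLines(c("gene\trole", "TERT\toncogene", "TERT\ttumor_suppressor"), f)
  expect_error(read_driver_genes(f), "more than once")
})

test_that("variant table writes TSV and structurally valid sorted VCF 4.2", {
  vt <- small_vt()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(vt, f, format = "tsv")
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(vt))

  # empty table -> header-only file
  write_variant_table(vt[0, ], f, format = "tsv")
  expect_equal(length(readLines(f)), 1L)

  v <- withr::local_tempfile(fileext = ".vcf")
  write_variant_table(vt, v, format = "vcf")
  lines <- readLines(v)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "##")]
  expect_true(startsWith(body[1], "#CHROM"))
  fields <- strsplit(body[-1], "\t")
  expect_true(all(lengths(fields) == 8L))
  pos <- data.frame(chrom = vapply(fields, `[`, "", 1),
                    pos = as.numeric(vapply(fields, `[`, "", 2)))
  expect_false(is.unsorted(order(pos$chrom, pos$pos)))
  by_chrom <- split(pos$pos, pos$chrom)
  expect_true(all(vapply(by_chrom, function(p) !is.unsorted(p), TRUE)))
  expect_true(all(grepl("MAF=", vapply(fields, `[`, "", 8))))
})
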