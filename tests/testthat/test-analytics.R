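mk_timelines <- function(df, clin_extra = NULL) {
  # df: patient_id, timepoint_day, mean_driver_maf, detected + patient labels
  class(df) <- c("patient_timelines", "data.frame")
  attr(df, "alpha") <- 0.05
  df
}

tl_row <- function(pid, day, maf, det, cat = "response", load = "low",
                   surv = 500, death = FALSE) {
  data.frame(patient_id = pid, timepoint_day = day, mean_driver_maf = maf,
             detected = det, n_driver_variants = as.integer(det),
             response_category = cat, metastatic_load = load,
             survival_days = surv, death_observed = death,
             stringsAsFactors = FALSE)
}

test_that("mean driver MAF and detection follow the zero conventions", {
  expect_equal(mean_driver_maf(c(0.1, 0.3)), 0.2)
  expect_equal(mean_driver_maf(numeric(0)), 0)
  expect_equal(mean_driver_maf(0.07), 0.07)
  expect_true(detection_status(c(0.01, 0.4)))
  expect_false(detection_status(0.3))     # significant only elsewhere
  expect_false(detection_status(numeric(0)))
})

test_that("timelines impute zero when nothing is significant at a timepoint", {
  coh <- small_cohort()
  tl <- patient_timelines(small_vt(), coh$clinical)
  expect_equal(nrow(tl), sum(lengths(coh$clinical$sample_days)))
  zero <- tl$mean_driver_maf == 0
  expect_true(all(tl$n_driver_variants[zero] == 0))
  expect_true(all(tl$mean_driver_maf[!tl$detected] == 0))
  # row order invariance of the per-timepoint mean
  vt <- small_vt()
  tl2 <- patient_timelines(vt[rev(seq_len(nrow(vt))), ], coh$clinical)
  expect_equal(tl2$mean_driver_maf[order(tl2$patient_id, tl2$timepoint_day)],
               tl$mean_driver_maf[order(tl$patient_id, tl$timepoint_day)])
})

test_that("two-group MAF comparison is an exact two-sided rank-sum", {
  tl <- mk_timelines(rbind(
    tl_row("A1", 0, 0.0, FALSE, load = "low"),
    tl_row("A2", 0, 0.0, FALSE, load = "low"),
    tl_row("A3", 0, 0.0, FALSE, load = "low"),
    tl_row("B1", 0, 0.2, TRUE, load = "high"),
    tl_row("B2", 0, 0.3, TRUE, load = "high"),
    tl_row("B3", 0, 0.4, TRUE, load = "high")))
  gs <- compare_maf_groups(tl, "metastatic_load")
  # frozen from the full permutation enumeration oracle: C(6,3) = 20
  # assignments, the two extreme rank sums each with probability 1/20
  expect_equal(gs$p_value, 0.1)
  expect_equal(gs$p_value, oracle_rank_sum(c(0, 0, 0), c(0.2, 0.3, 0.4)))
  expect_equal(gs$test, "wilcoxon_rank_sum")
  # identical value multisets -> p = 1
  tl2 <- mk_timelines(rbind(
    tl_row("A1", 0, 0.1, TRUE, load = "low"),
    tl_row("A2", 0, 0.2, TRUE, load = "low"),
    tl_row("B1", 0, 0.1, TRUE, load = "high"),
    tl_row("B2", 0, 0.2, TRUE, load = "high")))
  expect_equal(compare_maf_groups(tl2, "metastatic_load")$p_value, 1)
})

test_that("exact rank-sum agrees with wilcox.test on tie-free data", {
  set.seed(14)
  for (r in 1:10) {
    x <- round(runif(4), 6); y <- round(runif(5) + 0.2, 6)
    tl <- mk_timelines(rbind(
      do.call(rbind, lapply(seq_along(x), function(i)
        tl_row(paste0("A", i), 0, x[i], TRUE, load = "low"))),
      do.call(rbind, lapply(seq_along(y), function(i)
        tl_row(paste0("B", i), 0, y[i], TRUE, load = "high")))))
    expect_equal(compare_maf_groups(tl, "metastatic_load")$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("three response groups fall through to Kruskal-Wallis", {
  tl <- mk_timelines(rbind(
    tl_row("A1", 0, 0.01, TRUE, cat = "response"),
    tl_row("A2", 0, 0.02, TRUE, cat = "response"),
    tl_row("B1", 0, 0.2, TRUE, cat = "resistance"),
    tl_row("B2", 0, 0.25, TRUE, cat = "resistance"),
    tl_row("C1", 0, 0.1, TRUE, cat = "acquired_resistance"),
    tl_row("C2", 0, 0.15, TRUE, cat = "acquired_resistance")))
  gs <- compare_maf_groups(tl, "response_category")
  expect_equal(gs$test, "kruskal_wallis")
  vals <- c(0.01, 0.02, 0.2, 0.25, 0.1, 0.15)
  grp <- rep(c("r", "res", "acq"), each = 2)
  expect_equal(gs$p_value, kruskal.test(vals, factor(grp))$p.value)
})

test_that("the baseline-detection exact test reproduces known tables", {
  # the three-category baseline detection table: 4/11, 7/9, 4/4 detected
  tab <- matrix(c(4, 7, 7, 2, 4, 0), nrow = 2,
                dimnames = list(c("detected", "not_detected"),
                                c("response", "resistance", "acquired")))
  gs <- detection_table_test(tab)
  expect_equal(gs$p_value, 0.0464, tolerance = 1e-3)
  expect_equal(gs$p_value, oracle_ffh_exact(tab), tolerance = 1e-8)
  # equal proportions -> p = 1
  expect_equal(detection_table_test(matrix(c(2, 2, 2, 2), 2))$p_value, 1)
  # 2x2 case equals the hypergeometric two-sided Fisher p
  t22 <- matrix(c(8, 2, 3, 9), 2)
  expect_equal(detection_table_test(t22)$p_value,
               fisher.test(t22)$p.value)
  expect_equal(detection_table_test(t22)$p_value, oracle_ffh_exact(t22),
               tolerance = 1e-8)
  # degenerate margin -> warning and p = 1
  expect_warning(gd <- detection_table_test(matrix(c(0, 3, 0, 4), 2)),
                 "degenerate")
  expect_equal(gd$p_value, 1)
})

test_that("2xK exact p agrees with full enumeration on all small tables", {
  set.seed(77)
  for (r in 1:25) {
    K <- sample(2:4, 1)
    tab <- matrix(rpois(2 * K, 1.5), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || sum(tab) > 12)
      next
    expect_equal(detection_table_test(tab)$p_value, oracle_ffh_exact(tab),
                 tolerance = 1e-7, label = paste(tab, collapse = ","))
  }
})

test_that("gene frequency matrices divide patient counts by group sizes", {
  # construct a variant table reproducing the published TERT fractions:
  # 5 of 13 resistant/acquired patients and 1 of 11 responders mutated
  res_ids <- sprintf("R%02d", 1:13)
  rsp_ids <- sprintf("S%02d", 1:11)
  rows <- function(pids, gene) {
    do.call(rbind, lapply(pids, function(p)
      data.frame(patient_id = p, sample_id = paste0(p, "_t1"),
                 timepoint_day = 0, chromosome = "chr5", coordinate = 1295,
                 gene = gene, ref = "G", alt = "A",
                 key = paste0("chr5:1295:G>A"), maf = 0.1, p_value = 0.01,
                 significant = TRUE, driver_rule = "oncogene_cosmic3",
                 stringsAsFactors = FALSE)))
  }
  vt <- rbind(rows(res_ids[1:5], "TERT"), rows(rsp_ids[1], "TERT"))
  tl <- mk_timelines(rbind(
    do.call(rbind, lapply(res_ids, function(p)
      tl_row(p, 0, 0.1, TRUE, cat = "resistance"))),
    do.call(rbind, lapply(rsp_ids, function(p)
      tl_row(p, 0, 0, FALSE, cat = "response")))))
  gf <- gene_mutation_frequency(vt, tl, genes = c("TERT", "GENE01"))
  expect_equal(gf$percent["TERT", "resistance"], 100 * 5 / 13,
               tolerance = 1e-10)
  expect_equal(gf$percent["TERT", "response"], 100 * 1 / 11,
               tolerance = 1e-10)
  expect_true(all(gf$percent["GENE01", ] == 0))
  # per-(gene, group) patient counts never exceed the group size
  expect_true(all(sweep(gf$count, 2, gf$group_sizes, "<=")))
  expect_equal(unname(gf$group_sizes), c(13, 11))
  # baseline vs later split
  expect_true(all(gf$first_seen$first_significant == "baseline"))
})

test_that("Kaplan-Meier matches the empirical survivor function and log-rank
           behaves at its degenerate limits", {
  set.seed(19)
  t1 <- sample(50:500, 20)
  fit <- os_survival_records(t1, rep(TRUE, 20), rep("all", 20))
  s <- summary(fit$fit)
  expect_equal(s$surv, oracle_ecdf_survivor(t1, s$time), tolerance = 1e-12)
  expect_true(all(diff(s$surv) <= 0))
  # no deaths -> survival constant at 1, p = 1 with warning
  expect_warning(f0 <- os_survival_records(t1, rep(FALSE, 20),
                                           rep(c("a", "b"), 10)), "no events")
  expect_true(all(f0$fit$surv == 1))
  expect_equal(f0$logrank_p, 1)
  # duplicated strata -> log-rank p = 1
  fdup <- os_survival_records(c(t1, t1), rep(c(TRUE, FALSE), each = 20),
                              rep(c("a", "b"), each = 20))
  t2 <- c(100, 200, 300, 400)
  fid <- os_survival_records(c(t2, t2), rep(TRUE, 8),
                             rep(c("a", "b"), each = 4))
  expect_equal(fid$logrank_p, 1, tolerance = 1e-12)
})

test_that("log-rank detects a threefold hazard ratio in simulation", {
  set.seed(23)
  hits <- 0
  for (r in 1:100) {
    ta <- rexp(200, 1 / 300); tb <- rexp(200, 3 / 300)
    f <- os_survival_records(c(ta, tb), rep(TRUE, 400),
                             rep(c("a", "b"), each = 200))
    hits <- hits + (f$logrank_p < 0.01)
  }
  expect_gte(hits / 100, 0.95)
})
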