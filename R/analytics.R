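# Per-patient longitudinal summaries and cohort-level statistics.

#' Mean driver MAF at one timepoint
#'
#' Arithmetic mean of the MAFs of a patient's retained driver variants at
#' one timepoint; 0 when the set is empty (undetected samples are imputed
#' to 0, at baseline and at every later timepoint alike).
#'
#' @param mafs numeric vector of driver-variant MAFs (possibly empty).
#' @return scalar fraction.
#' @export
mean_driver_maf <- function(mafs) if (length(mafs) == 0L) 0 else mean(mafs)

#' ctDNA detection status at one timepoint
#'
#' TRUE when at least one retained driver variant is significant (p at or
#' below \code{alpha}) in that sample. A variant retained because it was
#' significant at another timepoint does not make this sample detected.
#'
#' @param p_values p-values of the patient's retained driver variants in
#'   this sample.
#' @param alpha significance threshold.
#' @return logical scalar.
#' @export
detection_status <- function(p_values, alpha = 0.05) {
  length(p_values) > 0L && any(p_values <= alpha)
}

#' Per-patient longitudinal timelines
#'
#' For every patient and sampling timepoint: the mean MAF of the driver
#' variants significant in that sample (0 when none), the detection status,
#' and the number of detected driver variants, joined to the clinical
#' labels.
#'
#' @param variants a \code{\link{build_variant_table}} result.
#' @param clinical a \code{clinical_table}.
#' @param alpha per-sample significance threshold for detection.
#' @return data.frame of class \code{patient_timelines}, one row per
#'   (patient, timepoint).
#' @export
patient_timelines <- function(variants, clinical, alpha = 0.05) {
  vt <- as.data.frame(variants)
  rows <- do.call(rbind, lapply(seq_len(nrow(clinical)), function(i) {
    pid <- clinical$patient_id[i]
    days <- clinical$sample_days[[i]]
    per_tp <- lapply(days, function(d) {
      v <- vt[vt$patient_id == pid & vt$timepoint_day == d, , drop = FALSE]
      sig <- v[v$p_value <= alpha, , drop = FALSE]
      data.frame(patient_id = pid, timepoint_day = d,
                 mean_driver_maf = mean_driver_maf(sig$maf),
                 detected = detection_status(v$p_value, alpha),
                 n_driver_variants = nrow(sig), stringsAsFactors = FALSE)
    })
    do.call(rbind, per_tp)
  }))
  idx <- match(rows$patient_id, clinical$patient_id)
  rows$response_category <- clinical$response_category[idx]
  rows$metastatic_load <- clinical$metastatic_load[idx]
  rows$survival_days <- clinical$survival_days[idx]
  rows$death_observed <- clinical$death_observed[idx]
  rownames(rows) <- NULL
  class(rows) <- c("patient_timelines", "data.frame")
  attr(rows, "alpha") <- alpha
  rows
}

#' One row per patient with baseline and whole-course summaries
#'
#' @param timelines a \code{\link{patient_timelines}} result.
#' @return data.frame with clinical labels plus \code{baseline_maf},
#'   \code{baseline_detected}, \code{ever_detected}, \code{last_detected}.
#' @export
patient_summary <- function(timelines) {
  tl <- as.data.frame(timelines)
  sp <- split(tl, tl$patient_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$timepoint_day), ]
    data.frame(patient_id = d$patient_id[1],
               response_category = d$response_category[1],
               metastatic_load = d$metastatic_load[1],
               survival_days = d$survival_days[1],
               death_observed = d$death_observed[1],
               baseline_maf = d$mean_driver_maf[1],
               baseline_detected = d$detected[1],
               ever_detected = any(d$detected),
               last_detected = d$detected[nrow(d)],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# two-sided rank-sum p-value: full permutation enumeration on midranks when
# feasible (handles the cohort's zero-inflated ties exactly), otherwise the
# normal approximation with tie correction via wilcox.test
rank_sum_p <- function(x, y, max_comb = 2e5) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  if (choose(n, nx) <= max_comb) {
    W <- sum(r[seq_len(nx)])
    cmb <- utils::combn(n, nx)
    Ws <- colSums(matrix(r[cmb], nrow = nx))
    E <- nx * (n + 1) / 2
    mean(abs(Ws - E) >= abs(W - E) - 1e-9)
  } else {
    suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
}

#' Compare mean driver MAF between patient groups
#'
#' Two groups: two-sided Wilcoxon rank-sum on the selected timepoint's mean
#' driver MAF, with an exact permutation p-value (midranks) for small
#' cohorts and the tie-corrected normal approximation otherwise. Three or
#' more groups: Kruskal-Wallis.
#'
#' @param timelines a \code{\link{patient_timelines}} result.
#' @param grouping name of a patient-level grouping column:
#'   \code{"response_category"}, \code{"metastatic_load"},
#'   \code{"death_observed"} or \code{"baseline_detected"}.
#' @param timepoint day of the compared sample (default 0, the baseline).
#' @return list of class \code{group_summary}: grouping, per-group values
#'   and sizes, test name and two-sided p-value.
#' @export
compare_maf_groups <- function(timelines, grouping = "metastatic_load",
                               timepoint = 0) {
  ps <- patient_summary(timelines)
  tl <- as.data.frame(timelines)
  val <- tl$mean_driver_maf[tl$timepoint_day == timepoint]
  pid <- tl$patient_id[tl$timepoint_day == timepoint]
  g <- ps[[grouping]][match(pid, ps$patient_id)]
  groups <- split(val, g)
  if (length(groups) < 2L)
    stop("grouping yields fewer than 2 groups", call. = FALSE)
  empty <- names(groups)[vapply(groups, length, 0L) == 0L]
  if (length(empty))
    stop("empty group: ", paste(empty, collapse = ", "), call. = FALSE)
  if (length(groups) == 2L) {
    p <- rank_sum_p(groups[[1]], groups[[2]])
    test <- "wilcoxon_rank_sum"
  } else {
    p <- kruskal.test(val, factor(g))$p.value
    test <- "kruskal_wallis"
  }
  structure(list(grouping = grouping, timepoint = timepoint,
                 values = groups,
                 n = vapply(groups, length, 0L),
                 test = test, p_value = p),
            class = "group_summary")
}

#' Baseline detection by category (exact 2 x K test)
#'
#' Builds the detected / not-detected by group contingency table at the
#' selected timepoint and tests it with the Fisher-Freeman-Halton exact
#' test (via the network algorithm); a chi-square alternative is available.
#' A degenerate table (zero margin) returns p = 1 with a warning.
#'
#' @param timelines a \code{\link{patient_timelines}} result.
#' @param grouping patient-level grouping column (default
#'   \code{"response_category"}).
#' @param timepoint day of the assessed sample (default 0).
#' @param method \code{"exact"} or \code{"chisq"}.
#' @return \code{group_summary} with the table in \code{$table}.
#' @export
detection_by_category <- function(timelines, grouping = "response_category",
                                  timepoint = 0,
                                  method = c("exact", "chisq")) {
  method <- match.arg(method)
  tl <- as.data.frame(timelines)
  sel <- tl$timepoint_day == timepoint
  det <- factor(tl$detected[sel], levels = c(TRUE, FALSE),
                labels = c("detected", "not_detected"))
  g <- tl[[grouping]][sel]
  tab <- table(det, g)
  detection_table_test(tab, method = method, grouping = grouping,
                       timepoint = timepoint)
}

#' @rdname detection_by_category
#' @param tab a 2 x K contingency table (rows: detected / not detected).
#' @export
detection_table_test <- function(tab, method = c("exact", "chisq"),
                                 grouping = "category", timepoint = 0) {
  method <- match.arg(method)
  tab <- as.table(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate contingency table (zero margin); p = 1")
    p <- 1
    test <- "degenerate"
  } else if (method == "exact") {
    p <- fisher.test(tab, workspace = 2e7)$p.value
    test <- "fisher_freeman_halton"
  } else {
    p <- suppressWarnings(chisq.test(tab)$p.value)
    test <- "chi_square"
  }
  structure(list(grouping = grouping, timepoint = timepoint, table = tab,
                 n = colSums(tab), test = test, p_value = min(p, 1)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s (timepoint day %s)\n", x$grouping,
              format(x$timepoint)))
  if (!is.null(x$table)) print(x$table)
  cat(sprintf("  test: %s, two-sided p = %.4g\n", x$test, x$p_value))
  invisible(x)
}

#' Per-gene driver mutation frequency by patient group
#'
#' For every panel gene and patient group: the percentage of the group's
#' patients with at least one retained driver variant in that gene at any
#' timepoint. Also reports, per (gene, patient), whether the variant was
#' first significant at baseline or only in a later sample.
#'
#' @param variants a \code{\link{build_variant_table}} result.
#' @param timelines a \code{\link{patient_timelines}} result (supplies the
#'   cohort and groups).
#' @param grouping patient-level grouping column.
#' @param genes optional character vector fixing the gene universe (defaults
#'   to the genes present in \code{variants}).
#' @return list of class \code{gene_frequency}: \code{percent} and
#'   \code{count} (gene x group matrices), \code{group_sizes}, and
#'   \code{first_seen} (gene, patient, baseline vs later).
#' @export
gene_mutation_frequency <- function(variants, timelines,
                                    grouping = "response_category",
                                    genes = NULL) {
  ps <- patient_summary(timelines)
  vt <- as.data.frame(variants)
  genes <- genes %||% sort(unique(vt$gene))
  groups <- sort(unique(ps[[grouping]]))
  sizes <- table(factor(ps[[grouping]], levels = groups))
  cnt <- matrix(0L, length(genes), length(groups),
                dimnames = list(genes, groups))
  first_seen <- NULL
  if (nrow(vt)) {
    sig <- vt[vt$significant, , drop = FALSE]
    gp <- unique(sig[c("gene", "patient_id")])
    gp$group <- ps[[grouping]][match(gp$patient_id, ps$patient_id)]
    gp <- gp[gp$gene %in% genes, , drop = FALSE]
    if (nrow(gp)) {
      t2 <- table(factor(gp$gene, levels = genes),
                  factor(gp$group, levels = groups))
      cnt <- cnt + unclass(t2)
      first_day <- tapply(sig$timepoint_day,
                          paste(sig$gene, sig$patient_id, sep = "\r"), min)
      parts <- strsplit(names(first_day), "\r", fixed = TRUE)
      first_seen <- data.frame(
        gene = vapply(parts, `[`, "", 1L),
        patient_id = vapply(parts, `[`, "", 2L),
        first_significant = ifelse(first_day == 0, "baseline", "later"),
        stringsAsFactors = FALSE)
    }
  }
  pct <- sweep(cnt, 2, as.numeric(sizes), "/") * 100
  pct[, sizes == 0] <- 0
  structure(list(percent = pct, count = cnt,
                 group_sizes = as.numeric(sizes), groups = groups,
                 first_seen = first_seen),
            class = "gene_frequency")
}

#' @export
print.gene_frequency <- function(x, ...) {
  cat("<gene_frequency> percent of patients mutated, by group\n")
  print(round(x$percent, 1))
  invisible(x)
}

#' Overall survival by stratum
#'
#' Kaplan-Meier product-limit estimate per stratum with right censoring, and
#' a two-sided log-rank test across strata. Overall survival runs from
#' treatment initiation to death from any cause; patients alive at last
#' follow-up are censored there. With no events anywhere the log-rank test
#' is undefined and p is reported as 1 with a warning.
#'
#' @param timelines a \code{\link{patient_timelines}} result.
#' @param strata patient-level stratifying column (default
#'   \code{"baseline_detected"}).
#' @return list of class \code{os_fit}: the \code{survfit} object, the
#'   log-rank p, and the patient-level data used.
#' @export
os_survival <- function(timelines, strata = "baseline_detected") {
  ps <- patient_summary(timelines)
  os_survival_records(ps$survival_days, ps$death_observed, ps[[strata]],
                      strata_name = strata)
}

#' @rdname os_survival
#' @param time,event,group survival time (days), death indicator, stratum
#'   label per patient.
#' @param strata_name label for printing.
#' @export
os_survival_records <- function(time, event, group, strata_name = "stratum") {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time < 0)) stop("negative survival time", call. = FALSE)
  df <- data.frame(time = time, event = as.integer(event),
                   group = as.character(group), stringsAsFactors = FALSE)
  if (any(table(df$group) == 0L) || length(unique(df$group)) < 1L)
    stop("each stratum needs at least one record", call. = FALSE)
  fit <- survfit(Surv(time, event) ~ group, data = df)
  if (sum(df$event) == 0L || length(unique(df$group)) < 2L) {
    if (sum(df$event) == 0L)
      warning("no events in any stratum; log-rank p reported as 1")
    p <- 1
  } else {
    sd <- survdiff(Surv(time, event) ~ group, data = df)
    p <- 1 - pchisq(sd$chisq, df = length(sd$n) - 1)
    if (!is.finite(p)) {
      warning("log-rank statistic undefined; p reported as 1")
      p <- 1
    }
  }
  structure(list(fit = fit, logrank_p = p, data = df,
                 strata_name = strata_name),
            class = "os_fit")
}

#' @export
print.os_fit <- function(x, ...) {
  cat(sprintf("<os_fit> Kaplan-Meier by %s; log-rank two-sided p = %.4g\n",
              x$strata_name, x$logrank_p))
  print(x$fit)
  invisible(x)
}

#' @export
plot.patient_timelines <- function(x, ...) {
  tl <- as.data.frame(x)
  cats <- RESPONSE_CATEGORIES
  cols <- setNames(c("#2166ac", "#b2182b", "#f4a582"), cats)
  plot(range(tl$timepoint_day), range(tl$mean_driver_maf),
       type = "n", xlab = "days since baseline", ylab = "mean driver MAF",
       ...)
  for (pid in unique(tl$patient_id)) {
    d <- tl[tl$patient_id == pid, ]
    d <- d[order(d$timepoint_day), ]
    lines(d$timepoint_day, d$mean_driver_maf,
          col = cols[d$response_category[1]])
    points(d$timepoint_day, d$mean_driver_maf,
           pch = ifelse(d$detected, 19, 1),
           col = cols[d$response_category[1]])
  }
  legend("topright", legend = cats, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' @export
plot.os_fit <- function(x, ...) {
  plot(x$fit, col = seq_along(x$fit$strata %||% 1), xlab = "days",
       ylab = "overall survival", ...)
  invisible(x)
}
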