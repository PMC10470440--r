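# Retention -> SNP exclusion -> driver classification cascade.

#' Retain variants significant at any timepoint
#'
#' A variant key is retained for a patient when the minimum p-value over that
#' patient's timepoints is at or below \code{alpha} (inclusive). Retained
#' variants keep their whole per-timepoint series downstream, including
#' non-significant timepoints.
#'
#' @param calls a \code{\link{call_variants}} result (or any data.frame with
#'   \code{patient_id, chromosome, coordinate, ref, alt, p_value}).
#' @param alpha significance threshold, default 0.05.
#' @param method \code{"none"} (raw p-values, the default) or \code{"BH"}
#'   (Benjamini-Hochberg within patient before retention).
#' @return data.frame with one row per retained (patient, variant key).
#' @export
filter_significant <- function(calls, alpha = 0.05,
                               method = c("none", "BH")) {
  method <- match.arg(method)
  df <- as.data.frame(calls)
  if (nrow(df) == 0L)
    return(data.frame(patient_id = character(0), key = character(0),
                      min_p = numeric(0)))
  p <- df$p_value
  if (method == "BH")
    p <- stats::ave(p, df$patient_id, FUN = function(v) p.adjust(v, "BH"))
  key <- variant_key(df$chromosome, df$coordinate, df$ref, df$alt)
  grp <- paste(df$patient_id, key, sep = "\r")
  minp <- tapply(p, grp, min)
  keep <- names(minp)[minp <= alpha]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  data.frame(patient_id = vapply(parts, `[`, "", 1L),
             key = vapply(parts, `[`, "", 2L),
             min_p = as.numeric(minp[keep]),
             stringsAsFactors = FALSE)
}

#' Germline SNP exclusion
#'
#' A variant is excluded as a presumed germline polymorphism when, in order:
#' any timepoint MAF exceeds 0.4 (\code{maf_gt_0.4}); its ExAC or gnomAD
#' population frequency exceeds 0.01 (\code{popfreq_gt_0.01}); or its MAF is
#' high (all timepoints above 0.1) and constant over time, i.e. max - min at
#' most \code{constant_tol} across at least two timepoints
#' (\code{likely_snp_constant}). The first matching rule is reported.
#'
#' @param maf_series numeric vector of the variant's MAFs over the patient's
#'   timepoints (non-empty).
#' @param exac_af,gnomad_af population allele frequencies, NA when unknown.
#' @param constant_tol constancy tolerance for the likely-SNP rule.
#' @return list with \code{excluded} (logical) and \code{reason}
#'   (\code{"maf_gt_0.4"}, \code{"popfreq_gt_0.01"},
#'   \code{"likely_snp_constant"} or \code{NA}).
#' @examples
#' snp_filter(c(0.45))$reason                 # "maf_gt_0.4"
#' snp_filter(c(0.01, 0.02), gnomad_af = 0.02)$reason  # "popfreq_gt_0.01"
#' snp_filter(c(0.12, 0.11, 0.13))$reason     # "likely_snp_constant"
#' @export
snp_filter <- function(maf_series, exac_af = NA, gnomad_af = NA,
                       constant_tol = 0.05) {
  stopifnot(length(maf_series) >= 1L)
  if (any(maf_series > 0.4))
    return(list(excluded = TRUE, reason = "maf_gt_0.4"))
  if ((!is.na(exac_af) && exac_af > 0.01) ||
      (!is.na(gnomad_af) && gnomad_af > 0.01))
    return(list(excluded = TRUE, reason = "popfreq_gt_0.01"))
  if (length(maf_series) >= 2L && all(maf_series > 0.1) &&
      diff(range(maf_series)) <= constant_tol)
    return(list(excluded = TRUE, reason = "likely_snp_constant"))
  list(excluded = FALSE, reason = NA_character_)
}

#' Driver-mutation classification
#'
#' A variant is a likely driver when either: its gene is listed as a tumor
#' suppressor (role \code{tumor_suppressor} or \code{both}) and at least two
#' of the three computational predictors (SIFT, PolyPhen, MutationTaster)
#' call it deleterious -- for stop-gain/frameshift consequences a predictor
#' without a call counts as deleterious, since truncating variants are
#' routinely unscored; or its gene is listed as an oncogene (role
#' \code{oncogene} or \code{both}) and the exact variant has at least three
#' COSMIC matches. Missing predictor verdicts never count affirmatively for
#' non-truncating variants. A gene absent from the role list is never a
#' driver.
#'
#' @param consequence one of \code{stopgain, frameshift, missense,
#'   synonymous, other}.
#' @param sift_deleterious,polyphen_damaging,mutationtaster_deleterious
#'   tri-state predictor verdicts (TRUE/FALSE/NA).
#' @param role gene role (\code{tumor_suppressor}, \code{oncogene},
#'   \code{both}, \code{other}) or NA when the gene is not listed.
#' @param cosmic_count exact-match recurrence count in COSMIC.
#' @return list with \code{is_driver} and \code{rule}
#'   (\code{"tsg_2of3"}, \code{"oncogene_cosmic3"} or \code{"none"}).
#' @export
classify_driver <- function(consequence, sift_deleterious, polyphen_damaging,
                            mutationtaster_deleterious, role, cosmic_count) {
  if (is.na(role) || !role %in% c("tumor_suppressor", "oncogene", "both"))
    return(list(is_driver = FALSE, rule = "none"))
  verdicts <- c(sift_deleterious, polyphen_damaging,
                mutationtaster_deleterious)
  truncating <- isTRUE(consequence %in% c("stopgain", "frameshift"))
  verdicts[is.na(verdicts)] <- truncating
  if (role %in% c("tumor_suppressor", "both") && sum(verdicts) >= 2L)
    return(list(is_driver = TRUE, rule = "tsg_2of3"))
  if (role %in% c("oncogene", "both") && !is.na(cosmic_count) &&
      cosmic_count >= 3L)
    return(list(is_driver = TRUE, rule = "oncogene_cosmic3"))
  list(is_driver = FALSE, rule = "none")
}

#' Build the filtered per-patient driver variant table
#'
#' Applies the full cascade to a caller result: retention of variants
#' significant (p at or below \code{alpha}) at any timepoint per patient,
#' then germline SNP exclusion, then driver classification. The output
#' contains exactly the retained, non-SNP driver variants, one row per
#' (patient, variant, timepoint); MAF/p series are completed from the
#' caller's per-allele table when available so non-top timepoints are not
#' lost. Calls at variants missing from the annotation table are retained
#' through the significance step, flagged unannotated, classified
#' non-driver, and reported via a message.
#'
#' @param calls a \code{\link{call_variants}} result.
#' @param annotation an \code{annotation_table}.
#' @param drivers a \code{driver_genes} role list.
#' @param alpha retention threshold (inclusive).
#' @param constant_tol constancy tolerance of the likely-SNP rule.
#' @param method p-value adjustment passed to
#'   \code{\link{filter_significant}}.
#' @return data.frame of class \code{variant_table}: columns
#'   \code{patient_id, sample_id, timepoint_day, chromosome, coordinate,
#'   gene, ref, alt, key, maf, p_value, significant, driver_rule}. The full
#'   audit of retained variants (SNP flags, driver outcomes, annotation
#'   status) is in \code{attr(, "audit")}.
#' @export
build_variant_table <- function(calls, annotation, drivers, alpha = 0.05,
                                constant_tol = 0.05,
                                method = c("none", "BH")) {
  retained <- filter_significant(calls, alpha = alpha, method = method)
  empty <- data.frame(patient_id = character(0), sample_id = character(0),
                      timepoint_day = numeric(0), chromosome = character(0),
                      coordinate = numeric(0), gene = character(0),
                      ref = character(0), alt = character(0),
                      key = character(0), maf = numeric(0),
                      p_value = numeric(0), significant = logical(0),
                      driver_rule = character(0), stringsAsFactors = FALSE)
  if (nrow(retained) == 0L) {
    class(empty) <- c("variant_table", "data.frame")
    attr(empty, "audit") <- data.frame()
    return(empty)
  }
  series_src <- attr(calls, "all_alts") %||% as.data.frame(calls)
  series_src$key <- variant_key(series_src$chromosome, series_src$coordinate,
                                series_src$ref, series_src$alt)
  pk <- paste(series_src$patient_id, series_src$key, sep = "\r")
  rk <- paste(retained$patient_id, retained$key, sep = "\r")
  rows <- series_src[pk %in% rk, , drop = FALSE]
  rows <- rows[order(rows$patient_id, rows$key, rows$timepoint_day), ]

  ann <- as.data.frame(annotation)
  grp <- paste(rows$patient_id, rows$key, sep = "\r")
  first <- !duplicated(grp)
  audit <- rows[first, c("patient_id", "key", "chromosome", "coordinate",
                         "gene", "ref", "alt")]
  aidx <- match(audit$key, ann$key)
  audit$annotated <- !is.na(aidx)
  n_unann <- sum(!audit$annotated)
  if (n_unann > 0)
    message(n_unann, " retained variant(s) missing from the annotation ",
            "table; classified non-driver")
  role <- drivers$role[match(audit$gene, drivers$gene)]

  maf_split <- split(rows$maf, grp)[unique(grp)]
  snp <- mapply(function(mafs, i) {
    snp_filter(mafs,
               exac_af = if (is.na(i)) NA else ann$exac_af[i],
               gnomad_af = if (is.na(i)) NA else ann$gnomad_af[i],
               constant_tol = constant_tol)
  }, maf_split, aidx, SIMPLIFY = FALSE)
  audit$snp_excluded <- vapply(snp, `[[`, TRUE, "excluded")
  audit$snp_reason <- vapply(snp, `[[`, "", "reason")

  drv <- mapply(function(i, r) {
    if (is.na(i)) return(list(is_driver = FALSE, rule = "none"))
    classify_driver(ann$consequence[i], ann$sift_deleterious[i],
                    ann$polyphen_damaging[i],
                    ann$mutationtaster_deleterious[i], r,
                    ann$cosmic_exact_match_count[i])
  }, aidx, role, SIMPLIFY = FALSE)
  audit$is_driver <- vapply(drv, `[[`, TRUE, "is_driver")
  audit$driver_rule <- vapply(drv, `[[`, "", "rule")
  rownames(audit) <- NULL

  keep_keys <- paste(audit$patient_id, audit$key, sep = "\r")[
    !audit$snp_excluded & audit$is_driver]
  out <- rows[grp %in% keep_keys,
              c("patient_id", "sample_id", "timepoint_day", "chromosome",
                "coordinate", "gene", "ref", "alt", "key", "maf", "p_value")]
  out$significant <- out$p_value <= alpha
  out$driver_rule <- audit$driver_rule[match(
    paste(out$patient_id, out$key, sep = "\r"),
    paste(audit$patient_id, audit$key, sep = "\r"))]
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "audit") <- audit
  out
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d driver variant(s) across %d patient(s), %d rows\n",
              length(unique(x$key)), length(unique(x$patient_id)), nrow(x)))
  invisible(x)
}
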