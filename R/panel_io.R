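# Readers and writers for every file the pipeline touches. All readers
# validate on the way in and reject with the offending file, line and field;
# nothing is silently coerced.

COUNT_COLS <- c("sample", "chromosome", "coordinate", "gene", "region_class",
                CHANNELS)

#' Read or write a stranded count matrix
#'
#' On-disk dialect: tab-separated, one row per (sample, position), header
#' columns \code{sample, chromosome, coordinate, gene, region_class} followed
#' by the 10 channel columns \code{A_fwd ... X_fwd, A_rev ... X_rev}. Every
#' sample must cover the same positions; write/read round-trips are exact.
#'
#' @param path file path.
#' @return \code{read_count_matrix}: a \code{\link{count_matrix}}.
#' @examples
#' cm <- simulate_cohort(cohort_config(n_patients = 3,
#'   group_sizes = c(response = 1, resistance = 1, acquired_resistance = 1),
#'   n_positions = 5, n_genes = 2, depth_mean = 200,
#'   n_snps_per_patient = 0, seed = 1))$counts
#' f <- tempfile(fileext = ".tsv")
#' write_count_matrix(cm, f)
#' cm2 <- read_count_matrix(f)
#' identical(cm$counts, cm2$counts)
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv_checked(path, COUNT_COLS)
  if (nrow(df) == 0L) {
    return(count_matrix(array(integer(0), c(0, 0, 10)), character(0),
                        data.frame(chromosome = character(0),
                                   coordinate = integer(0),
                                   gene = character(0),
                                   region_class = character(0))))
  }
  for (ch in CHANNELS) {
    v <- df[[ch]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop_parse(path, bad[1] + 1L, ch, "count must be a non-negative integer")
  }
  poskey <- paste(df$chromosome, df$coordinate, sep = ":")
  rowkey <- paste(df$sample, poskey)
  dup <- which(duplicated(rowkey))
  if (length(dup))
    stop_parse(path, dup[1] + 1L, "sample",
               sprintf("duplicate (sample, position) row '%s'", rowkey[dup[1]]))
  sample_ids <- unique(df$sample)
  upos <- !duplicated(poskey)
  positions <- data.frame(chromosome = df$chromosome[upos],
                          coordinate = df$coordinate[upos],
                          gene = df$gene[upos],
                          region_class = df$region_class[upos],
                          stringsAsFactors = FALSE)
  pkeys <- poskey[upos]
  if (nrow(df) != length(sample_ids) * length(pkeys))
    stop_parse(path, nrow(df) + 1L, "sample",
               "every sample must cover every position exactly once")
  counts <- array(0L, c(length(sample_ids), length(pkeys), 10L))
  si <- match(df$sample, sample_ids)
  pi <- match(poskey, pkeys)
  for (c_idx in seq_along(CHANNELS))
    counts[cbind(si, pi, c_idx)] <- as.integer(df[[CHANNELS[c_idx]]])
  count_matrix(counts, sample_ids, positions)
}

#' @rdname read_count_matrix
#' @param x a \code{\link{count_matrix}}.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  s <- n_samples(x); p <- n_positions(x)
  df <- data.frame(
    sample = rep(x$sample_ids, each = p),
    chromosome = rep(x$positions$chromosome, times = s),
    coordinate = rep(x$positions$coordinate, times = s),
    gene = rep(x$positions$gene, times = s),
    region_class = rep(x$positions$region_class, times = s),
    stringsAsFactors = FALSE)
  for (c_idx in seq_along(CHANNELS)) {
    m <- x$counts[, , c_idx, drop = TRUE]
    df[[CHANNELS[c_idx]]] <- as.integer(t(matrix(m, s, p)))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  miss <- setdiff(required_cols, names(df))
  if (length(miss))
    stop_parse(path, 1L, miss[1], "missing required column")
  df
}

#' Read the clinical table
#'
#' Tab-separated, one row per patient: \code{patient_id},
#' \code{response_category} (\code{response}, \code{resistance} or
#' \code{acquired_resistance}), \code{n_metastatic_sites},
#' \code{survival_days} (from treatment initiation), \code{death_observed}
#' (TRUE/FALSE) and \code{sample_days} (semicolon-separated days since
#' baseline, starting at 0, strictly increasing). Metastatic load is derived:
#' high when at least 3 metastatic sites.
#'
#' @param path file path.
#' @return data.frame of class \code{clinical_table} with a list-column
#'   \code{sample_days} and a derived \code{metastatic_load} column.
#' @export
read_clinical_table <- function(path) {
  df <- read_tsv_checked(path, c("patient_id", "response_category",
                                 "n_metastatic_sites", "survival_days",
                                 "death_observed", "sample_days"))
  dup <- which(duplicated(df$patient_id))
  if (length(dup))
    stop_parse(path, dup[1] + 1L, "patient_id", "duplicate patient")
  bad <- which(!df$response_category %in% RESPONSE_CATEGORIES)
  if (length(bad))
    stop_parse(path, bad[1] + 1L, "response_category",
               sprintf("unknown category '%s'", df$response_category[bad[1]]))
  bad <- which(is.na(df$survival_days) | df$survival_days < 0)
  if (length(bad))
    stop_parse(path, bad[1] + 1L, "survival_days", "must be non-negative")
  if (!is.logical(df$death_observed)) {
    v <- as.logical(df$death_observed)
    if (anyNA(v))
      stop_parse(path, which(is.na(v))[1] + 1L, "death_observed",
                 "must be TRUE or FALSE")
    df$death_observed <- v
  }
  days <- lapply(strsplit(as.character(df$sample_days), ";", fixed = TRUE),
                 as.numeric)
  for (i in seq_along(days)) {
    d <- days[[i]]
    if (length(d) == 0L || anyNA(d))
      stop_parse(path, i + 1L, "sample_days", "malformed day list")
    if (d[1] != 0)
      stop_parse(path, i + 1L, "sample_days", "baseline sample must be day 0")
    if (length(d) > 1L && any(diff(d) <= 0))
      stop_parse(path, i + 1L, "sample_days",
                 "sample days must be strictly increasing")
  }
  out <- data.frame(patient_id = as.character(df$patient_id),
                    response_category = df$response_category,
                    n_metastatic_sites = as.integer(df$n_metastatic_sites),
                    survival_days = as.numeric(df$survival_days),
                    death_observed = df$death_observed,
                    stringsAsFactors = FALSE)
  out$metastatic_load <- ifelse(out$n_metastatic_sites >= 3, "high", "low")
  out$sample_days <- days
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' @rdname read_clinical_table
#' @param clinical a \code{clinical_table}.
#' @export
write_clinical_table <- function(clinical, path) {
  df <- as.data.frame(clinical)[c("patient_id", "response_category",
                                  "n_metastatic_sites", "survival_days",
                                  "death_observed")]
  df$sample_days <- vapply(clinical$sample_days,
                           function(d) paste(d, collapse = ";"), "")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the variant annotation table
#'
#' One row per variant key (chromosome, coordinate, ref, alt):
#' functional consequence, tri-state predictor verdicts
#' (\code{sift_deleterious}, \code{polyphen_damaging},
#' \code{mutationtaster_deleterious}; TRUE/FALSE/NA, where NA means the
#' predictor made no call), population allele frequencies (\code{exac_af},
#' \code{gnomad_af}, in [0,1] or NA) and \code{cosmic_exact_match_count}.
#' Duplicate variant keys are rejected.
#'
#' @param path file path.
#' @return data.frame of class \code{annotation_table}, keyed by column
#'   \code{key}.
#' @export
read_annotation_table <- function(path) {
  cols <- c("chromosome", "coordinate", "ref", "alt", "gene", "consequence",
            "sift_deleterious", "polyphen_damaging",
            "mutationtaster_deleterious", "exac_af", "gnomad_af",
            "cosmic_exact_match_count")
  df <- read_tsv_checked(path, cols)
  df <- df[cols]
  df$key <- variant_key(df$chromosome, df$coordinate, df$ref, df$alt)
  dup <- which(duplicated(df$key))
  if (length(dup))
    stop_parse(path, dup[1] + 1L, "key",
               sprintf("duplicate variant key '%s'", df$key[dup[1]]))
  bad <- which(!df$consequence %in% CONSEQUENCES)
  if (length(bad))
    stop_parse(path, bad[1] + 1L, "consequence",
               sprintf("unknown consequence '%s'", df$consequence[bad[1]]))
  for (v in c("sift_deleterious", "polyphen_damaging",
              "mutationtaster_deleterious"))
    df[[v]] <- as.logical(df[[v]])
  for (v in c("exac_af", "gnomad_af")) {
    af <- df[[v]]
    bad <- which(!is.na(af) & (af < 0 | af > 1))
    if (length(bad))
      stop_parse(path, bad[1] + 1L, v, "allele frequency outside [0, 1]")
  }
  bad <- which(is.na(df$cosmic_exact_match_count) |
                 df$cosmic_exact_match_count < 0)
  if (length(bad))
    stop_parse(path, bad[1] + 1L, "cosmic_exact_match_count",
               "must be a non-negative integer")
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' @rdname read_annotation_table
#' @param annotation an \code{annotation_table}.
#' @export
write_annotation_table <- function(annotation, path) {
  df <- as.data.frame(annotation)
  df$key <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the driver-gene role list
#'
#' Tab-separated with columns \code{gene} and \code{role}
#' (\code{tumor_suppressor}, \code{oncogene}, \code{both} or \code{other}),
#' one row per gene; duplicated genes are rejected. An empty list is valid
#' and classifies nothing as a driver downstream.
#'
#' @param path file path.
#' @return data.frame of class \code{driver_genes}.
#' @export
read_driver_genes <- function(path) {
  df <- read_tsv_checked(path, c("gene", "role"))
  dup <- which(duplicated(df$gene))
  if (length(dup))
    stop_parse(path, dup[1] + 1L, "gene",
               sprintf("gene '%s' listed more than once", df$gene[dup[1]]))
  bad <- which(!df$role %in% GENE_ROLES)
  if (length(bad))
    stop_parse(path, bad[1] + 1L, "role",
               sprintf("unknown role '%s'", df$role[bad[1]]))
  df <- df[c("gene", "role")]
  class(df) <- c("driver_genes", "data.frame")
  df
}

#' @rdname read_driver_genes
#' @param drivers a \code{driver_genes} table.
#' @export
write_driver_genes <- function(drivers, path) {
  write.table(as.data.frame(drivers)[c("gene", "role")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a filtered variant table
#'
#' Writes the per-(patient, variant, timepoint) driver variant table either
#' as TSV (columns as in \code{\link{build_variant_table}}) or as a minimal
#' VCF 4.2 file with one record per variant and sample, MAF and p-value in
#' INFO, records sorted by chromosome and position.
#'
#' @param variants a \code{variant_table} (or plain data.frame with its
#'   columns).
#' @param path output path.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @export
write_variant_table <- function(variants, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  df <- as.data.frame(variants)
  if (format == "tsv") {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ctdnawatch",
           "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Mutant allele frequency\">",
           "##INFO=<ID=PVAL,Number=1,Type=Float,Description=\"Variant test p-value\">",
           "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample identifier\">",
           "##INFO=<ID=PATIENT,Number=1,Type=String,Description=\"Patient identifier\">",
           "##INFO=<ID=DAY,Number=1,Type=Integer,Description=\"Days since baseline\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  lines <- hdr
  if (nrow(df)) {
    ord <- order(df$chromosome, df$coordinate, df$sample_id)
    df <- df[ord, , drop = FALSE]
    info <- sprintf("MAF=%.6g;PVAL=%.6g;SAMPLE=%s;PATIENT=%s;DAY=%d",
                    df$maf, df$p_value, df$sample_id, df$patient_id,
                    as.integer(df$timepoint_day))
    lines <- c(lines,
               paste(df$chromosome, df$coordinate,
                     variant_key(df$chromosome, df$coordinate, df$ref, df$alt),
                     df$ref, df$alt, ".", "PASS", info, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
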