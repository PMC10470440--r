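#' Call variants against a patient-independent background
#'
#' For every tested sample, position and non-reference nucleotide, tests
#' whether the sample's stranded variant counts exceed the background error
#' distribution estimated from all samples of \emph{other} patients, using
#' the beta-binomial likelihood-ratio test of \code{\link{lrt_site}} with a
#' per-(position, allele) overdispersion estimated by
#' \code{\link{estimate_rho}} from the same background.
#'
#' Per position, the reference allele is the nucleotide with the largest
#' strand-summed count across the background samples (ties broken
#' alphabetically), so no reference genome is needed. Every position of every
#' tested sample is reported with the most significant alteration (smallest
#' p-value; ties broken by larger MAF, then alphabetically); no threshold is
#' applied at this stage -- \code{alpha} is only recorded for downstream
#' filters.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param sample_info data.frame with columns \code{sample_id},
#'   \code{patient_id}, \code{timepoint_day} covering every sample in
#'   \code{counts} (see \code{\link{sample_map}}).
#' @param alpha significance level recorded for downstream filtering.
#' @param rho_bounds truncation interval for the overdispersion estimate.
#' @param include_deletions if TRUE the deletion channel X is testable as an
#'   alteration; by default it only contributes to coverage.
#' @param keep_all_alts if TRUE (default) the per-allele test table is kept
#'   in \code{attr(, "all_alts")}, which downstream filtering uses to
#'   complete per-timepoint MAF series.
#' @param samples optional character vector restricting which samples are
#'   tested (their patients' other samples are still excluded from their
#'   background).
#' @return data.frame of class \code{ctdna_calls}, one row per (sample,
#'   position): stranded counts, MAF, LRT statistic and p-value of the top
#'   alteration.
#' @export
call_variants <- function(counts, sample_info, alpha = 0.05,
                          rho_bounds = c(1e-6, 0.1),
                          include_deletions = FALSE, keep_all_alts = TRUE,
                          samples = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  sample_info <- validate_sample_info(sample_info, counts)
  test_ids <- samples %||% counts$sample_ids
  miss <- setdiff(test_ids, counts$sample_ids)
  if (length(miss))
    stop("sample(s) absent from count matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)

  s_all <- counts$sample_ids
  patient <- sample_info$patient_id[match(s_all, sample_info$sample_id)]
  day <- sample_info$timepoint_day[match(s_all, sample_info$sample_id)]
  p_n <- n_positions(counts)

  # per-channel (sample x position) slabs and strand coverages
  K <- lapply(seq_along(CHANNELS), function(ch) {
    m <- counts$counts[, , ch, drop = TRUE]
    matrix(as.numeric(m), length(s_all), p_n)
  })
  names(K) <- CHANNELS
  NF <- Reduce(`+`, K[1:5])
  NR <- Reduce(`+`, K[6:10])
  TOT <- NF + NR

  alts <- NUCLEOTIDES
  if (include_deletions) alts <- c(alts, "X")
  fwd_ch <- setNames(match(paste0(c(NUCLEOTIDES, "X"), "_fwd"), CHANNELS),
                     c(NUCLEOTIDES, "X"))
  rev_ch <- setNames(match(paste0(c(NUCLEOTIDES, "X"), "_rev"), CHANNELS),
                     c(NUCLEOTIDES, "X"))

  per_patient <- list()
  for (pt in unique(patient[s_all %in% test_ids])) {
    bg_idx <- which(patient != pt)
    if (length(bg_idx) < 2L)
      stop("patient '", pt, "' has fewer than 2 background samples",
           call. = FALSE)
    t_idx <- which(s_all %in% test_ids & patient == pt)
    nt_sum <- matrix(0, p_n, 4, dimnames = list(NULL, sort(NUCLEOTIDES)))
    for (nt in colnames(nt_sum))
      nt_sum[, nt] <- colSums(K[[fwd_ch[nt]]][bg_idx, , drop = FALSE]) +
        colSums(K[[rev_ch[nt]]][bg_idx, , drop = FALSE])
    ref <- colnames(nt_sum)[max.col(nt_sum, ties.method = "first")]

    chunks <- list()
    for (alt in alts) {
      pos_sel <- which(ref != alt)
      if (!length(pos_sel)) next
      bkf <- t(K[[fwd_ch[alt]]][bg_idx, pos_sel, drop = FALSE])
      bkr <- t(K[[rev_ch[alt]]][bg_idx, pos_sel, drop = FALSE])
      bnf <- t(NF[bg_idx, pos_sel, drop = FALSE])
      bnr <- t(NR[bg_idx, pos_sel, drop = FALSE])
      skf <- t(K[[fwd_ch[alt]]][t_idx, pos_sel, drop = FALSE])
      skr <- t(K[[rev_ch[alt]]][t_idx, pos_sel, drop = FALSE])
      snf <- t(NF[t_idx, pos_sel, drop = FALSE])
      snr <- t(NR[t_idx, pos_sel, drop = FALSE])
      rho <- estimate_rho_rows(cbind(bkf, bkr), cbind(bnf, bnr), rho_bounds)
      res <- bb_lrt_batch_cpp(bkf, bnf, bkr, bnr, skf, snf, skr, snr, rho)
      stot <- t(TOT[t_idx, pos_sel, drop = FALSE])
      nt <- length(t_idx)
      chunks[[alt]] <- data.frame(
        s_idx = rep(t_idx, each = length(pos_sel)),
        p_idx = rep(pos_sel, times = nt),
        ref = rep(ref[pos_sel], times = nt),
        alt = alt,
        k_fwd = as.vector(skf), k_rev = as.vector(skr),
        n_fwd = as.vector(snf), n_rev = as.vector(snr),
        maf = as.vector((skf + skr) / ifelse(stot > 0, stot, 1)),
        statistic = as.vector(res$statistic),
        p_value = as.vector(res$p_value),
        stringsAsFactors = FALSE)
    }
    per_patient[[pt]] <- do.call(rbind, chunks)
  }

  all_alts <- do.call(rbind, per_patient)
  rownames(all_alts) <- NULL
  cell <- all_alts$s_idx * (p_n + 1L) + all_alts$p_idx
  ord <- order(cell, all_alts$p_value, -all_alts$maf, all_alts$alt)
  top <- all_alts[ord, ][!duplicated(cell[ord]), ]
  top <- top[order(top$s_idx, top$p_idx), ]

  decorate <- function(df) {
    out <- data.frame(
      sample_id = s_all[df$s_idx],
      patient_id = patient[df$s_idx],
      timepoint_day = day[df$s_idx],
      chromosome = counts$positions$chromosome[df$p_idx],
      coordinate = counts$positions$coordinate[df$p_idx],
      gene = counts$positions$gene[df$p_idx],
      region_class = counts$positions$region_class[df$p_idx],
      stringsAsFactors = FALSE)
    cbind(out, df[!(names(df) %in% c("s_idx", "p_idx"))])
  }
  calls <- decorate(top)
  rownames(calls) <- NULL
  attr(calls, "alpha") <- alpha
  attr(calls, "all_alts") <- if (keep_all_alts) decorate(all_alts) else NULL
  class(calls) <- c("ctdna_calls", "data.frame")
  calls
}

#' @rdname call_variants
#' @param sample_id one sample to test.
#' @export
call_sample <- function(sample_id, counts, sample_info, ...) {
  call_variants(counts, sample_info, samples = sample_id, ...)
}

validate_sample_info <- function(sample_info, counts) {
  req <- c("sample_id", "patient_id", "timepoint_day")
  miss <- setdiff(req, names(sample_info))
  if (length(miss))
    stop("sample_info missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(counts$sample_ids, sample_info$sample_id)
  if (length(absent))
    stop("sample_info lacks sample(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  sample_info
}

#' Map count-matrix samples to patients and timepoints
#'
#' Builds the sample -> (patient, timepoint day) map from a clinical table,
#' assuming the convention that sample identifiers are
#' \code{<patient_id>_t<k>} with \code{k} indexing the patient's ordered
#' sample days.
#'
#' @param clinical a \code{clinical_table}.
#' @return data.frame with \code{sample_id}, \code{patient_id},
#'   \code{timepoint_day}.
#' @export
sample_map <- function(clinical) {
  do.call(rbind, lapply(seq_len(nrow(clinical)), function(i) {
    d <- clinical$sample_days[[i]]
    data.frame(sample_id = paste0(clinical$patient_id[i], "_t", seq_along(d)),
               patient_id = clinical$patient_id[i],
               timepoint_day = d, stringsAsFactors = FALSE)
  }))
}

#' @export
print.ctdna_calls <- function(x, ...) {
  a <- attr(x, "alpha")
  cat(sprintf("<ctdna_calls> %d samples x %d positions (alpha = %g)\n",
              length(unique(x$sample_id)),
              length(unique(paste(x$chromosome, x$coordinate))), a))
  cat(sprintf("  top-alteration tests with p <= alpha: %d\n",
              sum(x$p_value <= a)))
  invisible(x)
}

#' @export
summary.ctdna_calls <- function(object, ...) {
  a <- attr(object, "alpha")
  agg <- aggregate(p_value ~ sample_id + patient_id, data = object,
                   FUN = function(p) sum(p <= a))
  names(agg)[3] <- "n_significant"
  agg[order(agg$patient_id, agg$sample_id), ]
}
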