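# In-silico spike-in limit-of-detection benchmark: inject increasing variant
# counts into one row of a background-matched single-position matrix, re-run
# the caller at every step, and summarise the smallest MAF reaching
# significance.

#' Build the injection matrix series
#'
#' From a single-position source matrix: the target row's reference channels
#' are fixed at the maximum reference count observed per strand in the
#' source; the variant channels take each grid value in turn, split evenly
#' across strands (odd remainder to the forward strand); all other rows are
#' carried over unchanged as background.
#'
#' @param source a \code{\link{count_matrix}} with at least 3 samples.
#' @param position index of the injected position (default 1).
#' @param target_sample sample id of the injected row.
#' @param ref,var reference and variant nucleotide (default A and T).
#' @param var_grid strictly increasing integer grid of injected total variant
#'   counts, starting at 0; defaults to 0..(maximum variant count observed in
#'   the source at this position).
#' @return list of \code{count_matrix} objects, one per grid value, with
#'   attributes \code{injected_count} and \code{injected_maf}.
#' @export
injection_series <- function(source, position = 1L, target_sample,
                             ref = "A", var = "T", var_grid = NULL) {
  stopifnot(inherits(source, "count_matrix"), n_samples(source) >= 3L)
  t_idx <- match(target_sample, source$sample_ids)
  if (is.na(t_idx)) stop("target sample not found", call. = FALSE)
  rf <- match(paste0(ref, "_fwd"), CHANNELS)
  rr <- match(paste0(ref, "_rev"), CHANNELS)
  vf <- match(paste0(var, "_fwd"), CHANNELS)
  vr <- match(paste0(var, "_rev"), CHANNELS)
  ref_f <- max(source$counts[, position, rf])
  ref_r <- max(source$counts[, position, rr])
  if (is.null(var_grid))
    var_grid <- 0:max(source$counts[, position, vf] +
                        source$counts[, position, vr])
  if (var_grid[1] != 0 || (length(var_grid) > 1 && any(diff(var_grid) <= 0)))
    stop("var_grid must start at 0 and be strictly increasing", call. = FALSE)
  if (max(var_grid) > 10 * max(ref_f + ref_r, 1))
    stop("injected counts exceed plausibility bound (10x reference)",
         call. = FALSE)
  lapply(var_grid, function(v) {
    m <- source
    row <- m$counts[t_idx, position, ]
    v_f <- ceiling(v / 2)          # odd remainder to the forward strand
    v_r <- v - v_f
    row[rf] <- ref_f; row[rr] <- ref_r
    row[vf] <- v_f; row[vr] <- v_r
    m$counts[t_idx, position, ] <- as.integer(row)
    attr(m, "injected_count") <- v
    attr(m, "injected_maf") <- v / sum(row)
    m
  })
}

#' Run the caller along an injection series
#'
#' Each matrix in the series is analysed with the beta-binomial LRT of the
#' target row against all other rows; the MAF is the injected variant count
#' divided by the target row sum.
#'
#' @param series result of \code{\link{injection_series}}.
#' @param target_sample sample id of the injected row.
#' @param var variant nucleotide.
#' @param rho_bounds truncation interval for the overdispersion estimate.
#' @return data.frame with one row per iteration: \code{injected_count},
#'   \code{maf}, \code{statistic}, \code{p_value}.
#' @export
run_injection_series <- function(series, target_sample, var = "T",
                                 rho_bounds = c(1e-6, 0.1)) {
  vf <- match(paste0(var, "_fwd"), CHANNELS)
  vr <- match(paste0(var, "_rev"), CHANNELS)
  out <- lapply(series, function(m) {
    t_idx <- match(target_sample, m$sample_ids)
    bg_idx <- setdiff(seq_len(n_samples(m)), t_idx)
    kf <- m$counts[, 1, vf]; kr <- m$counts[, 1, vr]
    nf <- rowSums(m$counts[, 1, 1:5, drop = FALSE])
    nr <- rowSums(m$counts[, 1, 6:10, drop = FALSE])
    rho <- estimate_rho(c(kf[bg_idx], kr[bg_idx]), c(nf[bg_idx], nr[bg_idx]),
                        bounds = rho_bounds)
    res <- lrt_site(list(k_fwd = kf[t_idx], n_fwd = nf[t_idx],
                         k_rev = kr[t_idx], n_rev = nr[t_idx]),
                    data.frame(k_fwd = kf[bg_idx], n_fwd = nf[bg_idx],
                               k_rev = kr[bg_idx], n_rev = nr[bg_idx]),
                    rho)
    data.frame(injected_count = attr(m, "injected_count"),
               maf = (kf[t_idx] + kr[t_idx]) / (nf[t_idx] + nr[t_idx]),
               statistic = res$statistic, p_value = res$p_value)
  })
  do.call(rbind, out)
}

#' Summarise the MAF limit of detection
#'
#' Per repeat, the LOD is the smallest injected MAF (injected count > 0)
#' whose p-value is at or below \code{alpha}, or missing if the series never
#' reaches significance. The median and interquartile range are taken over
#' the non-missing repeats with linear (type-7) quantile interpolation.
#'
#' @param series_list list of \code{\link{run_injection_series}} results.
#' @param alpha significance threshold.
#' @return list of class \code{lod_summary}: per-repeat LODs,
#'   \code{median_lod}, \code{iqr_lod} (25th and 75th percentiles), and the
#'   number of repeats that never reached significance.
#' @export
summarize_lod <- function(series_list, alpha = 0.05) {
  stopifnot(length(series_list) >= 1L)
  lods <- vapply(series_list, function(s) {
    hit <- s$injected_count > 0 & s$p_value <= alpha
    if (any(hit)) min(s$maf[hit]) else NA_real_
  }, numeric(1))
  ok <- lods[!is.na(lods)]
  if (length(ok) == 0L) {
    warning("no repeat reached significance; LOD summary is missing")
    med <- NA_real_; iqr <- c(NA_real_, NA_real_)
  } else {
    med <- median(ok)
    iqr <- quantile(ok, c(0.25, 0.75), names = FALSE, type = 7)
  }
  structure(list(lods = lods, median_lod = med, iqr_lod = iqr,
                 n_missing = sum(is.na(lods)), alpha = alpha),
            class = "lod_summary")
}

#' Synthetic single-position background for the LOD benchmark
#'
#' Beta-binomial background noise at one position: per row, a lognormal
#' depth around \code{depth} split evenly in expectation across strands,
#' reference counts on A, error counts on T, G, C with mean fraction
#' \code{mu} and overdispersion \code{rho}.
#'
#' @param n_samples number of rows (the study design used 93).
#' @param depth mean row coverage.
#' @param mu mean background error fraction per alternative nucleotide.
#' @param rho beta-binomial overdispersion of the background.
#' @param seed RNG seed.
#' @return single-position \code{\link{count_matrix}} with samples
#'   \code{bg_1 ... bg_n}.
#' @export
lod_background <- function(n_samples = 93, depth = 15000, mu = 2e-4,
                           rho = 1e-3, seed = 1) {
  with_seed(seed, {
    n_tot <- round(rlnorm(n_samples, log(depth) - 0.15^2 / 2, 0.15))
    n_f <- rbinom(n_samples, n_tot, 0.5)
    n_r <- n_tot - n_f
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    counts <- array(0L, c(n_samples, 1, 10))
    for (ch in c(2:4, 7:9)) {   # T, G, C errors on each strand
      n_s <- if (ch <= 5) n_f else n_r
      counts[, 1, ch] <- rbinom(n_samples, n_s, rbeta(n_samples, a, b))
    }
    counts[, 1, 1] <- n_f - rowSums(counts[, 1, 2:5, drop = FALSE])
    counts[, 1, 6] <- n_r - rowSums(counts[, 1, 7:10, drop = FALSE])
    count_matrix(counts, paste0("bg_", seq_len(n_samples)),
                 data.frame(chromosome = "chr7", coordinate = 140753336,
                            gene = "BRAF", region_class = "exonic"))
  })
}

#' Spike-in limit-of-detection benchmark
#'
#' Repeats the injection experiment \code{n_repeats} times: each repeat
#' draws a target row at random, bootstrap-resamples the remaining rows as
#' background, builds the injection series (variant counts from 0 upward),
#' runs the caller at every step, and records the smallest significant MAF.
#' The summary is the median and interquartile range over repeats.
#'
#' @param source single-position \code{\link{count_matrix}}; default is
#'   \code{\link{lod_background}()} regenerated per repeat seed.
#' @param ref,var reference and variant nucleotide.
#' @param alpha significance threshold.
#' @param n_repeats number of independent repeats.
#' @param var_grid optional injected-count grid (see
#'   \code{\link{injection_series}}).
#' @param seed RNG seed controlling target choice and background resampling.
#' @param mode \code{"repeats"} (default; the estimand is over repeated
#'   random draws) or \code{"single"} (one series from one random target,
#'   summarised over its grid crossings -- degenerate single-value summary).
#' @return \code{lod_summary}; the per-repeat series are in
#'   \code{attr(, "series")}.
#' @export
lod_benchmark <- function(source = NULL, ref = "A", var = "T", alpha = 0.05,
                          n_repeats = 50, var_grid = NULL, seed = 7,
                          mode = c("repeats", "single")) {
  mode <- match.arg(mode)
  src <- source %||% lod_background(seed = derive_seed(seed, 0))
  if (mode == "single") n_repeats <- 1L
  draws <- with_seed(derive_seed(seed, 1), {
    lapply(seq_len(n_repeats), function(r) {
      n <- n_samples(src)
      t_idx <- sample.int(n, 1)
      m <- src
      if (mode == "repeats") {
        bg_idx <- setdiff(seq_len(n), t_idx)
        res <- sample_from(bg_idx, length(bg_idx), replace = TRUE)
        m$counts[bg_idx, , ] <- src$counts[res, , , drop = FALSE]
      }
      list(source = m, target = m$sample_ids[t_idx])
    })
  })
  series_list <- lapply(draws, function(d) {
    ser <- injection_series(d$source, 1L, d$target, ref = ref, var = var,
                            var_grid = var_grid)
    run_injection_series(ser, d$target, var = var)
  })
  out <- summarize_lod(series_list, alpha = alpha)
  attr(out, "series") <- series_list
  attr(out, "draws") <- draws
  out
}

#' @export
print.lod_summary <- function(x, ...) {
  cat(sprintf(
    "<lod_summary> median MAF limit of detection %.4g (IQR %.4g-%.4g)\n",
    x$median_lod, x$iqr_lod[1], x$iqr_lod[2]))
  cat(sprintf("  %d repeat(s), %d never significant, alpha = %g\n",
              length(x$lods), x$n_missing, x$alpha))
  invisible(x)
}
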