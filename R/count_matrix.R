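#' Stranded nucleotide count matrix over panel positions
#'
#' The caller's sole sequencing-data input: for each sample and panel
#' position, read counts over 10 channels -- A, T, G, C and X (deletion) on
#' the forward strand, then the same five on the reverse strand. Per-strand
#' coverage is the sum of that strand's five channels; the row total (both
#' strands) is the denominator of the mutant allele frequency.
#'
#' @param counts integer array of dimension (samples, positions, 10), channel
#'   order \code{A_fwd, T_fwd, G_fwd, C_fwd, X_fwd, A_rev, T_rev, G_rev,
#'   C_rev, X_rev}; all entries non-negative.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   array row.
#' @param positions data.frame with columns \code{chromosome},
#'   \code{coordinate} (1-based, hg38 labels carried as opaque strings),
#'   \code{gene} and \code{region_class} (\code{"exonic"} or
#'   \code{"promoter"}), one row per array column.
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts}, \code{sample_ids}, \code{positions}.
#' @examples
#' cm <- count_matrix(
#'   counts = array(c(100L, 2L, 0L, 1L, 0L, 98L, 1L, 0L, 0L, 0L), c(1, 1, 10)),
#'   sample_ids = "s1",
#'   positions = data.frame(chromosome = "chr7", coordinate = 140753336,
#'                          gene = "BRAF", region_class = "exonic"))
#' coverage_total(cm)
#' @export
count_matrix <- function(counts, sample_ids, positions) {
  if (length(dim(counts)) != 3L || dim(counts)[3] != 10L)
    stop("'counts' must be a (samples x positions x 10) array", call. = FALSE)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != dim(counts)[1])
    stop("length(sample_ids) must match nrow(counts)", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids", call. = FALSE)
  positions <- validate_positions(positions)
  if (nrow(positions) != dim(counts)[2])
    stop("nrow(positions) must match the position dimension of counts",
         call. = FALSE)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, NULL, CHANNELS)
  structure(list(counts = counts, sample_ids = sample_ids,
                 positions = positions),
            class = "count_matrix")
}

validate_positions <- function(positions) {
  req <- c("chromosome", "coordinate", "gene", "region_class")
  miss <- setdiff(req, names(positions))
  if (length(miss))
    stop("positions missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  positions <- as.data.frame(positions)[req]
  positions$chromosome <- as.character(positions$chromosome)
  positions$gene <- as.character(positions$gene)
  positions$region_class <- as.character(positions$region_class)
  if (any(positions$coordinate < 1) ||
      any(positions$coordinate != floor(positions$coordinate)))
    stop("position coordinates must be 1-based positive integers",
         call. = FALSE)
  bad <- !positions$region_class %in% c("exonic", "promoter")
  if (any(bad))
    stop("unknown region_class: ",
         paste(unique(positions$region_class[bad]), collapse = ", "),
         call. = FALSE)
  rownames(positions) <- NULL
  positions
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d samples x %d positions x 10 channels\n",
              n_samples(x), n_positions(x)))
  cat(sprintf("  genes: %d | median row coverage: %s\n",
              length(unique(x$positions$gene)),
              format(median(coverage_total(x)))))
  invisible(x)
}

#' @rdname count_matrix
#' @param x a \code{count_matrix}.
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @rdname count_matrix
#' @export
n_positions <- function(x) nrow(x$positions)

#' Per-strand and total coverage
#'
#' Coverage of one strand is the sum of its five channels (A, T, G, C, X);
#' the row total sums all 10 channels and is the MAF denominator.
#'
#' @param x a \code{count_matrix}.
#' @return samples x positions numeric matrix.
#' @export
coverage_fwd <- function(x) strand_coverage(x, 1:5)

strand_coverage <- function(x, channels) {
  s <- n_samples(x); p <- n_positions(x)
  out <- matrix(0, s, p)
  for (ch in channels) out <- out + x$counts[, , ch, drop = TRUE]
  if (s == 1L || p == 1L) out <- matrix(out, s, p)
  out
}

#' @rdname coverage_fwd
#' @export
coverage_rev <- function(x) strand_coverage(x, 6:10)

#' @rdname coverage_fwd
#' @export
coverage_total <- function(x) strand_coverage(x, 1:10)

#' Mutant allele frequency from stranded counts
#'
#' The MAF is the variant count (both strands) divided by the corresponding
#' row sum over all 10 channels; it is 0 by convention at zero coverage.
#'
#' @param k_fwd,k_rev variant counts on the forward and reverse strand.
#' @param row_total total coverage over all 10 channels.
#' @return numeric vector of fractions in [0, 1].
#' @examples
#' compute_maf(375, 375, 15000)  # 0.05
#' @export
compute_maf <- function(k_fwd, k_rev, row_total) {
  k <- k_fwd + k_rev
  if (any(k > row_total))
    stop("variant count exceeds row total", call. = FALSE)
  ifelse(row_total > 0, k / row_total, 0)
}
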