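#' Beta-binomial log-likelihood
#'
#' Log probability mass of observing \code{k} variant reads in \code{n} under
#' a beta-binomial with mean error fraction \code{mu} and overdispersion
#' \code{rho}, parameterised as \code{alpha = mu (1 - rho) / rho},
#' \code{beta = (1 - mu) (1 - rho) / rho}. As \code{rho} approaches 0 this
#' converges to the binomial log pmf; the empty observation (k = 0, n = 0)
#' has log-likelihood 0.
#'
#' @param k,n non-negative counts with \code{k <= n} (vectorised).
#' @param mu mean fraction, in (0, 1).
#' @param rho overdispersion, in (0, 1).
#' @return numeric vector of log-likelihoods.
#' @examples
#' bb_loglik(5, 100, 0.05, 1e-9)  # ~ dbinom(5, 100, 0.05, log = TRUE)
#' @export
bb_loglik <- function(k, n, mu, rho) {
  if (length(mu) != 1L || length(rho) != 1L)
    stop("'mu' and 'rho' must be scalars", call. = FALSE)
  if (is.na(mu) || mu <= 0 || mu >= 1)
    stop("'mu' must lie in (0, 1)", call. = FALSE)
  if (is.na(rho) || rho <= 0 || rho >= 1)
    stop("'rho' must lie in (0, 1)", call. = FALSE)
  if (any(k < 0) || any(n < 0) || any(k > n))
    stop("need 0 <= k <= n", call. = FALSE)
  kn <- cbind(k, n)
  bb_loglik_cpp(kn[, 1], kn[, 2], mu, rho)
}

#' Method-of-moments overdispersion estimate
#'
#' Estimates the beta-binomial overdispersion rho from per-observation
#' variant counts (one observation per background sample and strand) using
#' the ANOVA-type binary intraclass-correlation estimator: the
#' between-observation mean square of the variant fractions is compared with
#' the within-observation binomial mean square. The estimate is truncated to
#' \code{bounds} (default [1e-6, 0.1]), which prevents degenerate fits at
#' low coverage. Deterministic given its inputs.
#'
#' @param k,n variant count and coverage per observation.
#' @param bounds truncation interval for rho.
#' @return scalar rho estimate within \code{bounds}.
#' @export
estimate_rho <- function(k, n, bounds = c(1e-6, 0.1)) {
  stopifnot(length(k) == length(n))
  keep <- !is.na(n) & n > 0
  k <- k[keep]; n <- n[keep]
  m <- length(k)
  if (m < 2L) {
    warning("fewer than 2 observations with coverage; returning rho lower bound")
    return(bounds[1])
  }
  N <- sum(n)
  p <- sum(k) / N
  if (p <= 0 || p >= 1 || N - m <= 0) return(bounds[1])
  bms <- sum(n * (k / n - p)^2) / (m - 1)
  wms <- sum(k * (n - k) / n) / (N - m)
  n0 <- (N - sum(n^2) / N) / (m - 1)
  denom <- bms + (n0 - 1) * wms
  rho <- if (denom <= 0) bounds[1] else (bms - wms) / denom
  min(max(rho, bounds[1]), bounds[2])
}

# vectorised across positions: K, N are (positions x observations) matrices;
# returns one truncated rho per position
estimate_rho_rows <- function(K, N, bounds = c(1e-6, 0.1)) {
  has <- N > 0
  m <- rowSums(has)
  Ntot <- rowSums(N)
  Ktot <- rowSums(K)
  p <- ifelse(Ntot > 0, Ktot / Ntot, 0)
  frac <- ifelse(has, K / ifelse(N > 0, N, 1), 0)
  bms <- rowSums(has * N * (frac - p)^2) / pmax(m - 1, 1)
  wms <- rowSums(ifelse(has, K * (N - K) / ifelse(N > 0, N, 1), 0)) /
    pmax(Ntot - m, 1)
  n0 <- (Ntot - rowSums(N^2) / pmax(Ntot, 1)) / pmax(m - 1, 1)
  denom <- bms + (n0 - 1) * wms
  rho <- ifelse(denom > 0, (bms - wms) / denom, bounds[1])
  rho[p <= 0 | p >= 1 | m < 2 | (Ntot - m) <= 0] <- bounds[1]
  pmin(pmax(rho, bounds[1]), bounds[2])
}

#' Likelihood-ratio site test against a background
#'
#' Tests whether one sample's variant fraction at a site exceeds the
#' error distribution of a set of background samples, under a beta-binomial
#' model with fixed overdispersion \code{rho}. Per strand, the test compares
#' the alternative (sample and background each with their own mean fraction,
#' both maximised by Brent search on (1e-8, 0.5)) against the null (one
#' shared mean); a strand contributes 0 when the sample's fraction does not
#' exceed the background's pooled fraction. The two strand statistics are
#' summed and referred to chi-square with 1 df with the one-sided halving:
#' \code{p = 0.5 * P(chisq_1 >= T)} when the sample's pooled fraction (both
#' strands) exceeds the background's, else \code{p = 1}.
#'
#' @param sample list or one-row data.frame with \code{k_fwd}, \code{n_fwd},
#'   \code{k_rev}, \code{n_rev}.
#' @param background data.frame with the same four columns, one row per
#'   background sample; must be non-empty.
#' @param rho overdispersion, typically from \code{\link{estimate_rho}}.
#' @return list with \code{statistic} (non-negative) and \code{p_value}.
#' @export
lrt_site <- function(sample, background, rho) {
  if (is.null(background) || nrow(as.data.frame(background)) == 0L)
    stop("empty background: cannot form the null error model", call. = FALSE)
  bg <- as.data.frame(background)
  if (is.na(rho) || rho <= 0 || rho >= 1)
    stop("'rho' must lie in (0, 1)", call. = FALSE)
  res <- bb_lrt_site_cpp(sample$k_fwd, sample$n_fwd, sample$k_rev,
                         sample$n_rev, bg$k_fwd, bg$n_fwd, bg$k_rev,
                         bg$n_rev, rho)
  list(statistic = res$statistic, p_value = res$p_value)
}
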