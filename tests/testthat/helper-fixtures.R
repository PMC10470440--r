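# Shared fixtures (memoised so expensive cohorts are built once per run)
# and independent oracle implementations used to cross-check the package.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a fast 6-patient cohort for unit-level checks; ... overrides any default
small_config <- function(seed = 101, ...) {
  args <- list(
    n_patients = 6,
    group_sizes = c(response = 2, resistance = 3, acquired_resistance = 1),
    baseline_shedders = c(response = 1, resistance = 2,
                          acquired_resistance = 1),
    n_positions = 80, n_genes = 10, depth_mean = 4000,
    n_snps_per_patient = 1, n_decoy_annotations = 4, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

small_cohort <- function() fixture("small_cohort", function()
  simulate_cohort(small_config()))

small_calls <- function() fixture("small_calls", function()
  suppressMessages(call_variants(small_cohort()$counts,
                                 small_cohort()$sample_info)))

small_vt <- function() fixture("small_vt", function()
  suppressMessages(build_variant_table(small_calls(),
                                       small_cohort()$annotation,
                                       small_cohort()$drivers)))

# the full-scale study-design cohort (24 patients, 1500 positions, 15000x)
default_cohort <- function() fixture("default_cohort", function()
  simulate_cohort(cohort_config(seed = 11)))

default_calls <- function() fixture("default_calls", function()
  suppressMessages(call_variants(default_cohort()$counts,
                                 default_cohort()$sample_info)))

default_vt <- function() fixture("default_vt", function()
  suppressMessages(build_variant_table(default_calls(),
                                       default_cohort()$annotation,
                                       default_cohort()$drivers)))

default_tl <- function() fixture("default_tl", function()
  patient_timelines(default_vt(), default_cohort()$clinical))

# the 50-repeat LOD benchmark on the default synthetic background
lod_bench_fixture <- function() fixture("lod_bench", function()
  lod_benchmark(n_repeats = 50, seed = 7))

# 3x3 depth-by-error-rate grid of median LODs (matched seeds)
lod_grid_fixture <- function() fixture("lod_grid", function() {
  depths <- c(7500, 15000, 30000)
  mus <- c(1e-4, 2e-4, 4e-4)
  meds <- matrix(NA_real_, 3, 3, dimnames = list(depths, mus))
  for (i in seq_along(depths)) {
    for (j in seq_along(mus)) {
      src <- lod_background(n_samples = 93, depth = depths[i], mu = mus[j],
                            rho = 1e-3, seed = 99)
      meds[i, j] <- lod_benchmark(source = src, n_repeats = 25,
                                  seed = 5)$median_lod
    }
  }
  meds
})

# a zero-injection cohort for the false-positive alpha-budget check: decoy
# driver-style annotation gives the cascade 10 qualifying keys per patient
null_cohort <- function() fixture("null_cohort", function()
  simulate_cohort(cohort_config(
    n_positions = 400, n_snps_per_patient = 0,
    baseline_shedders = c(response = 0, resistance = 0,
                          acquired_resistance = 0),
    n_decoy_annotations = 10, seed = 13)))

null_vt <- function() fixture("null_vt", function() {
  coh <- null_cohort()
  calls <- suppressMessages(call_variants(coh$counts, coh$sample_info))
  suppressMessages(build_variant_table(calls, coh$annotation, coh$drivers))
})

# Monte-Carlo per-timepoint detection power of each injected driver, using
# the caller itself on matched single-site simulations (actual background
# and depths of the cohort at that site)
driver_power_table <- function(coh, alpha = 0.05, n_rep = 60, seed = 17) {
  tt <- truth_table(coh)
  cm <- coh$counts
  info <- coh$sample_info
  drv <- tt[tt$kind == "somatic_driver", ]
  keys <- unique(paste(drv$patient_id, drv$key, sep = "\r"))
  pt_of <- info$patient_id[match(cm$sample_ids, info$sample_id)]
  ch <- dimnames(cm$counts)[[3]]
  set.seed(seed)
  power <- vapply(keys, function(kk) {
    rows <- drv[paste(drv$patient_id, drv$key, sep = "\r") == kk, ]
    p_idx <- which(cm$positions$chromosome == rows$chromosome[1] &
                     cm$positions$coordinate == rows$coordinate[1])
    af <- match(paste0(rows$alt[1], "_fwd"), ch)
    ar <- match(paste0(rows$alt[1], "_rev"), ch)
    bg_idx <- which(pt_of != rows$patient_id[1])
    nf <- rowSums(cm$counts[, p_idx, 1:5, drop = FALSE])
    nr <- rowSums(cm$counts[, p_idx, 6:10, drop = FALSE])
    bg <- data.frame(k_fwd = cm$counts[bg_idx, p_idx, af],
                     n_fwd = nf[bg_idx],
                     k_rev = cm$counts[bg_idx, p_idx, ar],
                     n_rev = nr[bg_idx])
    rho <- estimate_rho(c(bg$k_fwd, bg$k_rev), c(bg$n_fwd, bg$n_rev))
    s_idx <- match(paste0(rows$patient_id[1], "_t",
                          seq_along(rows$timepoint_day)), cm$sample_ids)
    tp_power <- vapply(seq_along(rows$timepoint_day), function(t) {
      m <- rows$true_maf[t]
      if (m == 0) return(0)
      nfs <- nf[s_idx[t]]; nrs <- nr[s_idx[t]]
      hits <- vapply(seq_len(n_rep), function(r) {
        lrt_site(list(k_fwd = rbinom(1, nfs, m), n_fwd = nfs,
                      k_rev = rbinom(1, nrs, m), n_rev = nrs),
                 bg, rho)$p_value <= alpha
      }, TRUE)
      mean(hits)
    }, numeric(1))
    max(tp_power)
  }, numeric(1))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(patient_id = vapply(parts, `[`, "", 1),
             key = vapply(parts, `[`, "", 2),
             power = unname(power), stringsAsFactors = FALSE)
}

# stack two (samples x positions x 10) count arrays by sample
abind_rows <- function(a, b) {
  out <- array(0L, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# ---- independent oracles ------------------------------------------------

# beta-binomial log pmf coded directly from the density definition
oracle_bb_logpmf <- function(k, n, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

# one-sided two-proportion binomial LRT (the rho -> 0 limit of the site test)
oracle_two_prop_lrt <- function(ks, ns, kb, nb) {
  sp <- function(p) max(min(p, 1 - 1e-12), 1e-12)
  ll <- function(k, n, p) if (n == 0) 0 else k * log(p) + (n - k) * log1p(-p)
  l1 <- ll(ks, ns, sp(ks / ns)) + ll(kb, nb, sp(kb / nb))
  ph <- sp((ks + kb) / (ns + nb))
  l0 <- ll(ks, ns, ph) + ll(kb, nb, ph)
  t <- max(0, 2 * (l1 - l0))
  if (ks / ns > kb / nb) 0.5 * pchisq(t, 1, lower.tail = FALSE) else 1
}

# independently coded beta-binomial site LRT: same model, but maximised with
# stats::optimize in R rather than the package's compiled Brent search
oracle_site_lrt <- function(skf, snf, skr, snr, bk, bn, rho) {
  bg_ll <- function(mu) {
    a <- mu * (1 - rho) / rho; b <- (1 - mu) * (1 - rho) / rho
    sum(lbeta(bk + a, bn - bk + b) - lbeta(a, b))
  }
  s_ll <- function(mu) {
    a <- mu * (1 - rho) / rho; b <- (1 - mu) * (1 - rho) / rho
    lb <- lbeta(a, b)
    (if (snf > 0) lbeta(skf + a, snf - skf + b) - lb else 0) +
      (if (snr > 0) lbeta(skr + a, snr - skr + b) - lb else 0)
  }
  both <- function(mu) bg_ll(mu) + s_ll(mu)
  mx <- function(f) optimize(f, c(1e-8, 0.5), maximum = TRUE,
                             tol = 1e-10)$objective
  fb <- sum(bk) / sum(bn)
  fs <- (skf + skr) / (snf + snr)
  if (!(fs > fb)) return(list(statistic = 0, p_value = 1))
  t <- max(0, 2 * (mx(bg_ll) + mx(s_ll) - mx(both)))
  list(statistic = t, p_value = 0.5 * pchisq(t, 1, lower.tail = FALSE))
}

# oracle LOD of one injection series, recomputing every p from the raw
# matrices with oracle_site_lrt
oracle_series_lod <- function(source, target, alpha = 0.05) {
  ser <- injection_series(source, 1L, target)
  t_idx <- match(target, source$sample_ids)
  lod <- NA_real_
  for (m in ser) {
    if (attr(m, "injected_count") == 0) next
    kf <- m$counts[, 1, 2]; kr <- m$counts[, 1, 7]
    nf <- rowSums(m$counts[, 1, 1:5, drop = FALSE])
    nr <- rowSums(m$counts[, 1, 6:10, drop = FALSE])
    bg <- setdiff(seq_along(kf), t_idx)
    rho <- estimate_rho(c(kf[bg], kr[bg]), c(nf[bg], nr[bg]))
    res <- oracle_site_lrt(kf[t_idx], nf[t_idx], kr[t_idx], nr[t_idx],
                           c(kf[bg], kr[bg]), c(nf[bg], nr[bg]), rho)
    if (res$p_value <= alpha) {
      lod <- (kf[t_idx] + kr[t_idx]) / (nf[t_idx] + nr[t_idx])
      break
    }
  }
  lod
}

# full-enumeration Fisher-Freeman-Halton exact test for a 2 x K table:
# p = sum of probabilities (under fixed margins) of tables no more probable
# than the observed one
oracle_ffh_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2)
  cs <- colSums(tab); r1 <- sum(tab[1, ]); N <- sum(tab)
  rows <- list(integer(0))
  for (j in seq_along(cs)) {
    rows <- do.call(c, lapply(rows, function(x) {
      lapply(0:cs[j], function(v) c(x, v))
    }))
  }
  rows <- Filter(function(x) sum(x) == r1, rows)
  logp <- vapply(rows, function(x)
    sum(lchoose(cs, x)) - lchoose(N, r1), numeric(1))
  obs <- sum(lchoose(cs, tab[1, ])) - lchoose(N, r1)
  sum(exp(logp[logp <= obs + 1e-7]))
}

# exact two-sided rank-sum p by full enumeration over group assignments
oracle_rank_sum <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  E <- nx * (n + 1) / 2
  cmb <- utils::combn(n, nx)
  Ws <- colSums(matrix(r[cmb], nrow = nx))
  mean(abs(Ws - E) >= abs(W - E) - 1e-9)
}

# empirical survivor function (no censoring)
oracle_ecdf_survivor <- function(times, at) {
  vapply(at, function(t) mean(times > t), numeric(1))
}
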