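# Seeded synthetic cohort generator: background sequencing error, private
# germline SNPs, and response-group-dependent somatic driver trajectories,
# with a truth table so every pipeline stage can be validated end to end.

#' Synthetic cohort configuration
#'
#' Defaults emulate the study design the pipeline targets: 24 melanoma
#' patients (11 response / 9 resistance / 4 acquired resistance), 4-6 plasma
#' samples at 21-day intervals, a 40-gene panel sequenced at 15000x
#' (scaled to 1500 positions for desk-scale runs; pass
#' \code{n_positions = 150000} for a panel-scale cohort), per-position
#' background error rates lognormal around 2e-4 with beta-binomial
#' overdispersion 1e-3, three private germline SNPs per patient at MAF 0.5,
#' and baseline ctDNA shedding in 4/11, 7/9 and 4/4 patients of the three
#' response groups. Group survival is exponential with medians 639, 121 and
#' 200 days, censored administratively at day 1460.
#'
#' @param n_patients cohort size.
#' @param group_sizes named sizes of the three response groups (must sum to
#'   \code{n_patients}).
#' @param timepoints_range min and max samples per patient.
#' @param visit_interval_days days between consecutive samples.
#' @param n_positions,n_genes panel size.
#' @param depth_mean,depth_sdlog lognormal row-coverage model.
#' @param mu_meanlog,mu_sdlog,mu_max lognormal per-position background error
#'   fraction (truncated at \code{mu_max}).
#' @param rho beta-binomial overdispersion of the background.
#' @param n_snps_per_patient,snp_maf private germline heterozygous SNPs.
#' @param baseline_shedders named counts of patients per group with
#'   detectable ctDNA at baseline.
#' @param driver_maf_meanlog,driver_maf_sdlog lognormal baseline driver MAF
#'   of shedding patients.
#' @param high_load_maf_multiplier baseline MAF multiplier for patients with
#'   high metastatic load (at least 3 metastatic sites).
#' @param drivers_per_shedder_mean mean extra driver variants per shedding
#'   patient (1 + Poisson, capped at 3).
#' @param n_decoy_annotations driver-style annotation records at positions
#'   with no injected variant (gives the filter cascade realistic false
#'   positive opportunities under the null).
#' @param survival_median_days named per-group exponential survival medians.
#' @param censor_day administrative censoring day.
#' @param seed master seed; identical seeds give identical cohorts.
#' @return list of class \code{cohort_config}.
#' @export
cohort_config <- function(
    n_patients = 24,
    group_sizes = c(response = 11, resistance = 9, acquired_resistance = 4),
    timepoints_range = c(4, 6),
    visit_interval_days = 21,
    n_positions = 1500,
    n_genes = 40,
    depth_mean = 15000,
    depth_sdlog = 0.15,
    mu_meanlog = log(2e-4),
    mu_sdlog = 0.5,
    mu_max = 5e-3,
    rho = 1e-3,
    n_snps_per_patient = 3,
    snp_maf = 0.5,
    baseline_shedders = c(response = 4, resistance = 7,
                          acquired_resistance = 4),
    driver_maf_meanlog = log(0.08),
    driver_maf_sdlog = 0.4,
    high_load_maf_multiplier = 2,
    drivers_per_shedder_mean = 0.7,
    n_decoy_annotations = 3,
    survival_median_days = c(response = 639, resistance = 121,
                             acquired_resistance = 200),
    censor_day = 1460,
    seed = 1) {
  cfg <- as.list(environment())
  if (sum(group_sizes) != n_patients)
    stop("group sizes must sum to n_patients", call. = FALSE)
  if (!identical(sort(names(group_sizes)), sort(RESPONSE_CATEGORIES)))
    stop("group_sizes must be named by the three response categories",
         call. = FALSE)
  if (any(baseline_shedders > group_sizes[names(baseline_shedders)]))
    stop("more baseline shedders than patients in a group", call. = FALSE)
  stopifnot(timepoints_range[1] >= 2, timepoints_range[2] >=
              timepoints_range[1], n_positions >= n_genes)
  structure(cfg, class = "cohort_config")
}

# deterministic per-group true-MAF trajectory shapes over n_tp timepoints,
# scaled by the patient's baseline MAF maf0
driver_trajectory <- function(group, maf0, n_tp, late = FALSE) {
  t <- seq_len(n_tp) - 1
  m <- switch(group,
    response = {
      v <- maf0 * 0.25^t          # clearance under therapy
      v[v < 5e-4] <- 0
      v[n_tp] <- 0
      v
    },
    resistance = {
      if (late) {                 # not shedding at baseline, positive later
        v <- maf0 * 0.5 * 1.3^t
        v[1] <- 0
        v
      } else pmin(maf0 * 1.3^t, 0.35)
    },
    acquired_resistance = {       # respond, then relapse
      v <- numeric(n_tp)
      v[1] <- maf0 * 0.5
      rise <- max(2, n_tp - 1)
      v[rise:n_tp] <- maf0 * 1.5 * 1.2^(seq_len(n_tp - rise + 1) - 1)
      pmin(v, 0.35)
    })
  m
}

#' Inject a variant into one count row
#'
#' Draws variant counts as binomial(strand coverage, true MAF) per strand
#' and moves them from the reference channel, preserving the row sum.
#'
#' @param row named integer vector of the 10 channel counts.
#' @param true_maf true variant allele fraction.
#' @param ref,var reference and variant nucleotide.
#' @return modified row (same total).
#' @export
inject_variant <- function(row, true_maf, ref, var) {
  stopifnot(true_maf >= 0, true_maf <= 1)
  if (true_maf == 0) return(row)
  for (strand in c("_fwd", "_rev")) {
    rc <- paste0(ref, strand); vc <- paste0(var, strand)
    n_strand <- row[rc] + row[vc]
    k <- rbinom(1, n_strand, true_maf)
    row[vc] <- k
    row[rc] <- n_strand - k
  }
  row
}

#' Germline SNP truth records for one patient
#'
#' Heterozygous private SNPs: true MAF \code{snp_maf} (about 0.5), constant
#' over all timepoints -- the profile the high-and-constant-MAF SNP filter
#' is designed to catch.
#'
#' @param patient_id patient identifier.
#' @param pos_idx panel position indices hosting the SNPs.
#' @param timepoint_days the patient's sampling days.
#' @param snp_maf true heterozygous allele fraction.
#' @return data.frame of truth records (one row per SNP and timepoint).
#' @export
germline_profile <- function(patient_id, pos_idx, timepoint_days,
                             snp_maf = 0.5) {
  if (length(pos_idx) == 0L)
    return(NULL)
  expand <- expand.grid(p_idx = pos_idx, timepoint_day = timepoint_days)
  data.frame(patient_id = patient_id, p_idx = expand$p_idx,
             timepoint_day = expand$timepoint_day, true_maf = snp_maf,
             kind = "germline_snp", rule = "none",
             stringsAsFactors = FALSE)
}

#' Generate a synthetic ctDNA cohort
#'
#' Produces every input the pipeline consumes -- stranded count matrix,
#' clinical table, annotation table, driver-gene role list -- plus the truth
#' table of injected variants. Background counts are beta-binomial per
#' (sample, position, strand, alternative nucleotide); injected somatic
#' drivers follow deterministic group-specific MAF trajectories (response:
#' clearance to 0; resistance: persistent/rising; acquired resistance: dip
#' then rise); germline SNPs are private per patient with constant MAF.
#' All randomness flows from \code{config$seed} through fixed substreams.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list of class \code{ctdna_cohort} with elements \code{counts},
#'   \code{clinical}, \code{sample_info}, \code{annotation}, \code{drivers},
#'   \code{truth}, \code{config}.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config

  clin <- with_seed(derive_seed(cfg$seed, 1), simulate_clinical(cfg))
  plan <- with_seed(derive_seed(cfg$seed, 2), simulate_truth(cfg, clin))
  counts <- with_seed(derive_seed(cfg$seed, 3),
                      simulate_counts(cfg, clin, plan))
  ann <- with_seed(derive_seed(cfg$seed, 4),
                   simulate_annotation(cfg, plan))

  truth <- plan$truth
  truth$chromosome <- plan$positions$chromosome[truth$p_idx]
  truth$coordinate <- plan$positions$coordinate[truth$p_idx]
  truth$gene <- plan$positions$gene[truth$p_idx]
  truth$ref <- plan$ref[truth$p_idx]
  truth$key <- variant_key(truth$chromosome, truth$coordinate, truth$ref,
                           truth$alt)
  truth <- truth[c("patient_id", "key", "chromosome", "coordinate", "ref",
                   "alt", "gene", "kind", "rule", "timepoint_day",
                   "true_maf")]
  structure(list(counts = counts, clinical = clin,
                 sample_info = sample_map(clin), annotation = ann,
                 drivers = plan$drivers, truth = truth, config = cfg),
            class = "ctdna_cohort")
}

simulate_clinical <- function(cfg) {
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  n <- cfg$n_patients
  pid <- sprintf("P%02d", seq_len(n))
  n_tp <- sample_from(seq(cfg$timepoints_range[1], cfg$timepoints_range[2]),
                 n, replace = TRUE)
  sites <- sample(rep(c(1:2, 3:6), length.out = n))  # half low, half high
  med <- cfg$survival_median_days[groups]
  t_death <- rexp(n, rate = log(2) / med)
  surv <- pmin(t_death, cfg$censor_day)
  clin <- data.frame(patient_id = pid, response_category = groups,
                     n_metastatic_sites = as.integer(sites),
                     survival_days = round(surv, 1),
                     death_observed = t_death <= cfg$censor_day,
                     stringsAsFactors = FALSE)
  clin$metastatic_load <- ifelse(clin$n_metastatic_sites >= 3, "high", "low")
  clin$sample_days <- lapply(n_tp, function(k)
    cfg$visit_interval_days * (seq_len(k) - 1))
  class(clin) <- c("clinical_table", "data.frame")
  clin
}

# panel layout, reference alleles, driver/SNP placement, true trajectories
simulate_truth <- function(cfg, clin) {
  genes <- c("TERT", paste0("GENE", sprintf("%02d", seq_len(cfg$n_genes - 1))))
  gene_of <- sort(rep_len(seq_len(cfg$n_genes), cfg$n_positions))
  positions <- data.frame(
    chromosome = paste0("chr", 1 + (gene_of - 1) %% 22),
    coordinate = 1e6 + seq_len(cfg$n_positions) * 150,
    gene = genes[gene_of],
    region_class = ifelse(genes[gene_of] == "TERT", "promoter", "exonic"),
    stringsAsFactors = FALSE)
  ref <- sample(NUCLEOTIDES, cfg$n_positions, replace = TRUE)
  # role mix modelled on the cancer gene census: ~3/8 TSG, ~3/8 oncogene,
  # 1/8 both, 1/8 unlisted
  role_pool <- rep(c("tumor_suppressor", "oncogene", "both", "other"),
                   times = pmax(round(cfg$n_genes * c(3, 3, 1, 1) / 8), 1))
  roles <- data.frame(
    gene = genes,
    role = sample(rep_len(role_pool, cfg$n_genes)),
    stringsAsFactors = FALSE)
  roles$role[roles$gene == "TERT"] <- "oncogene"
  class(roles) <- c("driver_genes", "data.frame")

  used <- integer(0)
  truth <- NULL
  driver_genes <- roles$gene[roles$role != "other"]
  driver_pos <- which(positions$gene %in% driver_genes)

  for (g in names(cfg$group_sizes)) {
    idx <- which(clin$response_category == g)
    shed <- sample_from(idx, cfg$baseline_shedders[g])
    # one resistant patient may turn ctDNA-positive only under therapy;
    # a zero-shedding (null) configuration injects nothing at all
    late <- if (g == "resistance" && cfg$baseline_shedders[g] > 0 &&
                length(setdiff(idx, shed)) > 0)
      sample_from(setdiff(idx, shed), 1) else integer(0)
    for (i in c(shed, late)) {
      pid <- clin$patient_id[i]
      days <- clin$sample_days[[i]]
      n_drv <- min(1 + rpois(1, cfg$drivers_per_shedder_mean), 3)
      maf0 <- rlnorm(1, cfg$driver_maf_meanlog, cfg$driver_maf_sdlog)
      if (clin$metastatic_load[i] == "high")
        maf0 <- maf0 * cfg$high_load_maf_multiplier
      maf0 <- min(maf0, 0.3)
      traj <- driver_trajectory(g, maf0, length(days), late = i %in% late)
      for (d in seq_len(n_drv)) {
        avail <- setdiff(driver_pos, used)
        if (!length(avail)) stop("more injections than driver positions")
        p_idx <- sample_from(avail, 1)
        used <- c(used, p_idx)
        alt <- sample(setdiff(NUCLEOTIDES, ref[p_idx]), 1)
        scale <- runif(1, 0.6, 1.4)
        truth <- rbind(truth, data.frame(
          patient_id = pid, p_idx = p_idx, alt = alt,
          timepoint_day = days, true_maf = pmin(traj * scale, 0.39),
          kind = "somatic_driver",
          rule = if (roles$role[match(positions$gene[p_idx], roles$gene)]
                     %in% c("tumor_suppressor", "both"))
            "tsg_2of3" else "oncogene_cosmic3",
          stringsAsFactors = FALSE))
      }
    }
  }

  truth_cols <- c("patient_id", "p_idx", "alt", "timepoint_day", "true_maf",
                  "kind", "rule")
  if (cfg$n_snps_per_patient > 0) {
    for (i in seq_len(nrow(clin))) {
      avail <- setdiff(seq_len(cfg$n_positions), used)
      p_idx <- sample_from(avail, cfg$n_snps_per_patient)
      used <- c(used, p_idx)
      gp <- germline_profile(clin$patient_id[i], p_idx,
                             clin$sample_days[[i]], cfg$snp_maf)
      gp$alt <- rep(vapply(p_idx, function(p)
        sample(setdiff(NUCLEOTIDES, ref[p]), 1), ""),
        times = length(clin$sample_days[[i]]))
      truth <- rbind(truth, gp[truth_cols])
    }
  }
  if (is.null(truth))
    truth <- data.frame(patient_id = character(0), p_idx = integer(0),
                        alt = character(0), timepoint_day = numeric(0),
                        true_maf = numeric(0), kind = character(0),
                        rule = character(0), stringsAsFactors = FALSE)
  list(positions = positions, ref = ref, drivers = roles, truth = truth)
}

simulate_counts <- function(cfg, clin, plan) {
  info <- sample_map(clin)
  s_n <- nrow(info)
  p_n <- cfg$n_positions
  depth <- matrix(round(rlnorm(s_n * p_n,
                               log(cfg$depth_mean) - cfg$depth_sdlog^2 / 2,
                               cfg$depth_sdlog)), s_n, p_n)
  n_f <- matrix(rbinom(s_n * p_n, depth, 0.5), s_n, p_n)
  n_r <- depth - n_f
  counts <- array(0L, c(s_n, p_n, 10))
  mu <- pmin(rlnorm(p_n, cfg$mu_meanlog, cfg$mu_sdlog), cfg$mu_max)
  sh1 <- mu * (1 - cfg$rho) / cfg$rho
  sh2 <- (1 - mu) * (1 - cfg$rho) / cfg$rho

  for (nt in NUCLEOTIDES) {
    sel <- which(plan$ref != nt)             # error channels only
    if (!length(sel)) next
    p_f <- matrix(rbeta(s_n * length(sel), rep(sh1[sel], each = s_n),
                        rep(sh2[sel], each = s_n)), s_n)
    p_r <- matrix(rbeta(s_n * length(sel), rep(sh1[sel], each = s_n),
                        rep(sh2[sel], each = s_n)), s_n)
    kf <- matrix(rbinom(s_n * length(sel), n_f[, sel], p_f), s_n)
    kr <- matrix(rbinom(s_n * length(sel), n_r[, sel], p_r), s_n)
    counts[, sel, match(paste0(nt, "_fwd"), CHANNELS)] <- kf
    counts[, sel, match(paste0(nt, "_rev"), CHANNELS)] <- kr
  }
  # reference channel takes the remaining strand coverage
  alt_f <- matrix(0L, s_n, p_n); alt_r <- matrix(0L, s_n, p_n)
  for (ch in 1:4) {
    alt_f <- alt_f + matrix(counts[, , ch], s_n, p_n)
    alt_r <- alt_r + matrix(counts[, , ch + 5], s_n, p_n)
  }
  for (nt in NUCLEOTIDES) {
    sel <- which(plan$ref == nt)
    if (!length(sel)) next
    counts[, sel, match(paste0(nt, "_fwd"), CHANNELS)] <-
      pmax(n_f[, sel, drop = FALSE] - alt_f[, sel, drop = FALSE], 0L)
    counts[, sel, match(paste0(nt, "_rev"), CHANNELS)] <-
      pmax(n_r[, sel, drop = FALSE] - alt_r[, sel, drop = FALSE], 0L)
  }

  # injected variants override the error draw at their (sample, position)
  truth <- plan$truth
  if (nrow(truth)) {
    skey <- paste(info$patient_id, info$timepoint_day)
    tkey <- paste(truth$patient_id, truth$timepoint_day)
    s_idx <- match(tkey, skey)
    for (j in which(truth$true_maf > 0 & !is.na(s_idx))) {
      si <- s_idx[j]; pj <- truth$p_idx[j]
      row <- setNames(counts[si, pj, ], CHANNELS)
      row <- inject_variant(row, truth$true_maf[j], plan$ref[pj],
                            truth$alt[j])
      counts[si, pj, ] <- as.integer(row)
    }
  }
  count_matrix(counts, info$sample_id, plan$positions)
}

simulate_annotation <- function(cfg, plan) {
  truth <- plan$truth
  positions <- plan$positions
  recs <- NULL
  if (nrow(truth)) {
    u <- truth[!duplicated(paste(truth$p_idx, truth$alt)), ]
    recs <- do.call(rbind, lapply(seq_len(nrow(u)), function(j) {
      p <- u$p_idx[j]
      if (u$kind[j] == "somatic_driver" && u$rule[j] == "tsg_2of3") {
        cons <- sample(c("stopgain", "missense"), 1)
        verd <- if (cons == "stopgain") c(NA, NA, TRUE) else
          sample(c(TRUE, TRUE, sample(c(TRUE, FALSE), 1)))
        cosmic <- sample(0:2, 1)
        af <- NA_real_
      } else if (u$kind[j] == "somatic_driver") {
        cons <- "missense"
        verd <- sample(c(TRUE, FALSE, NA), 3, replace = TRUE)
        cosmic <- sample(3:25, 1)
        af <- NA_real_
      } else {   # germline SNP
        cons <- sample(c("missense", "synonymous"), 1)
        verd <- sample(c(TRUE, FALSE, NA), 3, replace = TRUE)
        cosmic <- 0L
        af <- round(runif(1, 0.05, 0.4), 3)
      }
      data.frame(chromosome = positions$chromosome[p],
                 coordinate = positions$coordinate[p],
                 ref = plan$ref[p], alt = u$alt[j],
                 gene = positions$gene[p], consequence = cons,
                 sift_deleterious = verd[1], polyphen_damaging = verd[2],
                 mutationtaster_deleterious = verd[3],
                 exac_af = af, gnomad_af = af,
                 cosmic_exact_match_count = as.integer(cosmic),
                 stringsAsFactors = FALSE)
    }))
  }
  # decoy driver-style annotations at uninjected positions: false-positive
  # opportunities for the cascade under the null
  taken <- if (nrow(truth)) unique(truth$p_idx) else integer(0)
  droles <- plan$drivers
  dpos <- setdiff(which(positions$gene %in%
                          droles$gene[droles$role != "other"]), taken)
  n_dec <- min(cfg$n_decoy_annotations, length(dpos))
  if (n_dec > 0) {
    dp <- sample_from(dpos, n_dec)
    dec <- do.call(rbind, lapply(dp, function(p) {
      role <- droles$role[match(positions$gene[p], droles$gene)]
      tsg <- role %in% c("tumor_suppressor", "both")
      data.frame(chromosome = positions$chromosome[p],
                 coordinate = positions$coordinate[p],
                 ref = plan$ref[p],
                 alt = sample(setdiff(NUCLEOTIDES, plan$ref[p]), 1),
                 gene = positions$gene[p],
                 consequence = if (tsg) "stopgain" else "missense",
                 sift_deleterious = TRUE, polyphen_damaging = TRUE,
                 mutationtaster_deleterious = NA,
                 exac_af = NA_real_, gnomad_af = NA_real_,
                 cosmic_exact_match_count = if (tsg) 0L else 5L,
                 stringsAsFactors = FALSE)
    }))
    recs <- rbind(recs, dec)
  }
  if (is.null(recs))
    recs <- data.frame(chromosome = character(0), coordinate = numeric(0),
                       ref = character(0), alt = character(0),
                       gene = character(0), consequence = character(0),
                       sift_deleterious = logical(0),
                       polyphen_damaging = logical(0),
                       mutationtaster_deleterious = logical(0),
                       exac_af = numeric(0), gnomad_af = numeric(0),
                       cosmic_exact_match_count = integer(0),
                       stringsAsFactors = FALSE)
  recs$key <- variant_key(recs$chromosome, recs$coordinate, recs$ref,
                          recs$alt)
  recs <- recs[!duplicated(recs$key), ]
  rownames(recs) <- NULL
  class(recs) <- c("annotation_table", "data.frame")
  recs
}

#' Truth table of a synthetic cohort
#'
#' @param cohort a \code{\link{simulate_cohort}} result.
#' @return data.frame keyed by (patient_id, key) with kind
#'   (\code{somatic_driver} / \code{germline_snp}), the driver rule each
#'   injected driver should satisfy, and the true MAF per timepoint.
#' @export
truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "ctdna_cohort"))
  cohort$truth
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  cat(sprintf(
    "<ctdna_cohort> %d patients, %d samples, %d positions (seed %s)\n",
    nrow(x$clinical), n_samples(x$counts), n_positions(x$counts),
    format(x$config$seed)))
  tt <- x$truth[!duplicated(paste(x$truth$patient_id, x$truth$key)), ]
  cat(sprintf("  injected: %d somatic driver(s), %d germline SNP(s)\n",
              sum(tt$kind == "somatic_driver"),
              sum(tt$kind == "germline_snp")))
  invisible(x)
}
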