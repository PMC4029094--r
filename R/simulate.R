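#' Simulation configuration for the synthetic KIR cohort
#'
#' Bundles every knob of the generator with defaults emulating the study
#' conditions the pipeline is built for: a 1474-sample qPCR cohort spread
#' over 17 x 384-well plates (four replicate wells per sample, four
#' calibrator samples of known groups 1-2 and 2-1 plus one water well per
#' plate), per-plate affine distortion of the delta-Ct scale, total dropout
#' of non-amplifying zero-copy genes, and per-copy-number-group SNP
#' `(R, theta)` clusters with a case/control batch shift.  Copy-number group
#' frequencies default to the published SNP-cohort totals
#' (7316, 3678, 454, 222, 172, 193, 46, 25 out of 12106).
#'
#' @param n_cases,n_controls cohort sizes (defaults 747 / 727).
#' @param group_freqs named probability vector over [kir_groups()].
#' @param or_model named per-group odds ratios versus the reference group
#'   `0-2` used to tilt case frequencies (all 1 = null model).
#' @param bw4_freq carrier probability of HLA-Bw4.
#' @param bw4_80i_given_bw4 carrier probability of HLA-Bw4-80I given Bw4
#'   (80I carriers are a subset of Bw4 carriers by construction).
#' @param plate_size wells-per-plate sample capacity (default 96, of which
#'   4 calibrators and one water well, leaving 91 study samples).
#' @param replicates replicate wells per sample (default 4).
#' @param dct_noise_sd per-well delta-Ct noise SD in cycles (default 0.08).
#' @param plate_effect_a,plate_effect_b ranges of the per-plate affine
#'   distortion `dct -> a * dct + b` (defaults `[0.8, 1.2]`, `[-0.5, 0.5]`).
#' @param ref_ct_range range of the per-plate STAT6 baseline Ct.
#' @param ref_ct_sd per-well reference Ct noise SD.
#' @param dropout_zero probability a zero-copy gene yields no crossing in a
#'   well (default 1: absent genes never amplify).
#' @param dropout_low per-well stochastic dropout probability for one-copy
#'   genes (default 0.01).
#' @param ref_dropout_sample probability a sample's reference channel fails
#'   in all wells (default 0; raise to exercise QC).
#' @param snp_r_base,snp_r_per_copy,snp_r_sd SNP total-intensity model:
#'   `R ~ N(base + per_copy * total copies, sd)`.
#' @param snp_theta_base,snp_theta_span,snp_theta_sd SNP angle model:
#'   `theta ~ N(base + span * l/(s+l), sd)`, truncated to `[0, 1]`.
#' @param case_shift_r,case_shift_theta additive mean shift of case clusters
#'   (emulating the two cohorts having been processed in different centres).
#' @param m number of imputed datasets (default 10).
#' @param seed integer seed; sub-generators use fixed offsets from it.
#' @return list of class `kir_sim_config`.
#' @export
kir_sim_config <- function(n_cases = 747, n_controls = 727,
                           group_freqs = NULL, or_model = NULL,
                           bw4_freq = 0.60, bw4_80i_given_bw4 = 0.62,
                           plate_size = 96, replicates = 4,
                           dct_noise_sd = 0.08,
                           plate_effect_a = c(0.8, 1.2),
                           plate_effect_b = c(-0.5, 0.5),
                           ref_ct_range = c(24, 26), ref_ct_sd = 0.15,
                           dropout_zero = 1.0, dropout_low = 0.01,
                           ref_dropout_sample = 0,
                           snp_r_base = 0.30, snp_r_per_copy = 0.45,
                           snp_r_sd = 0.15,
                           snp_theta_base = 0.10, snp_theta_span = 0.80,
                           snp_theta_sd = 0.05,
                           case_shift_r = 0.05, case_shift_theta = 0.02,
                           m = 10, seed = 1) {
  if (is.null(group_freqs)) {
    group_freqs <- c(`0-2` = 7316, `1-1` = 3678, `2-0` = 454, `2-1` = 222,
                     `1-2` = 172, `0-1` = 193, `1-0` = 46, `3-0` = 25) / 12106
  }
  if (is.null(or_model)) {
    or_model <- stats::setNames(rep(1, 8), kir_groups())
  }
  if (!setequal(names(group_freqs), kir_groups())) {
    stop("group_freqs must be named by the eight copy-number groups")
  }
  if (!all(names(or_model) %in% kir_groups())) {
    stop("or_model names must be copy-number groups")
  }
  if (abs(sum(group_freqs) - 1) > 1e-8) stop("group_freqs must sum to 1")
  stopifnot(dct_noise_sd > 0, snp_r_sd > 0, snp_theta_sd > 0,
            all(plate_effect_a > 0), m >= 1)
  structure(as.list(environment()), class = "kir_sim_config")
}

#' Simulate a case-control cohort with true copy-number groups
#'
#' Control group frequencies follow `group_freqs`; case frequencies are
#' tilted by the per-group odds ratios of `or_model`
#' (`p_case(g) proportional to freq(g) * OR(g)`), so `or_model = 1`
#' everywhere gives a null cohort.  HLA epitope carriage is drawn with the
#' constraint that every Bw4-80I carrier is a Bw4 carrier.
#'
#' @param config a [kir_sim_config()].
#' @return list with `truth` (`sample_id`, `cohort`, `group`, `s`, `l`) and
#'   `phenotype` (`sample_id`, `status`, `bw4`, `bw4_80i`).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  groups <- kir_groups()
  freqs <- config$group_freqs[groups]
  or <- config$or_model[groups]
  or[is.na(or)] <- 1
  p_case <- freqs * or
  p_case <- p_case / sum(p_case)
  n <- config$n_cases + config$n_controls
  cohort <- c(rep("case", config$n_cases), rep("control", config$n_controls))
  grp <- character(n)
  grp[cohort == "case"] <- sample(groups, config$n_cases, TRUE, p_case)
  grp[cohort == "control"] <- sample(groups, config$n_controls, TRUE, freqs)
  bw4 <- ifelse(stats::runif(n) < config$bw4_freq, "carrier", "non-carrier")
  bw4_80i <- ifelse(bw4 == "carrier" &
                      stats::runif(n) < config$bw4_80i_given_bw4,
                    "carrier", "non-carrier")
  id <- sprintf("S%05d", seq_len(n))
  list(
    truth = data.frame(sample_id = id, cohort = cohort, group = grp,
                       s = group_s(grp), l = group_l(grp),
                       stringsAsFactors = FALSE),
    phenotype = data.frame(sample_id = id, status = cohort, bw4 = bw4,
                           bw4_80i = bw4_80i, stringsAsFactors = FALSE)
  )
}

# 384-well position labels A01..P24, consumed four at a time.
well_labels <- function() {
  paste0(rep(LETTERS[1:16], each = 24), sprintf("%02d", 1:24))
}

#' Simulate a multiplexed qPCR well table from true copy numbers
#'
#' Samples are shuffled onto plates (91 study samples per 384-well plate,
#' leaving room for the four calibrator samples — two of group 1-2 and two
#' of 2-1 — and one water well).  Per well, the latent delta-Ct of each gene
#' is `N(copy count, dct_noise_sd)`, distorted by the plate's affine effect
#' `a * dct + b`; the reference Ct is drawn around the plate baseline and
#' the gene Ct back-computed as `ct_ref - distorted delta-Ct`.  Zero-copy
#' genes fail to cross with probability `dropout_zero` per well and one-copy
#' genes with probability `dropout_low`; crossing points outside `(0, 40]`
#' are censored to missing.
#'
#' @param truth truth table from [simulate_cohort()].
#' @param config a [kir_sim_config()].
#' @return list with `wells` (the Ct export table), `plate_effects`, and
#'   `calibrators` (the truth rows of the per-plate calibrator samples).
#' @export
simulate_qpcr <- function(truth, config) {
  set.seed(config$seed + 1L)
  capacity <- config$plate_size - 4L - 1L
  ord <- sample.int(nrow(truth))
  n_plates <- ceiling(nrow(truth) / capacity)
  # samples are arrayed evenly across plates (no small trailing plate)
  sizes <- diff(floor(seq(0, nrow(truth), length.out = n_plates + 1L)))
  plate_of <- rep(seq_len(n_plates), times = sizes)
  plate_ids <- sprintf("P%02d", seq_len(n_plates))

  effects <- data.frame(
    plate_id = plate_ids,
    a = stats::runif(n_plates, config$plate_effect_a[1], config$plate_effect_a[2]),
    b = stats::runif(n_plates, config$plate_effect_b[1], config$plate_effect_b[2]),
    baseline = stats::runif(n_plates, config$ref_ct_range[1], config$ref_ct_range[2]),
    stringsAsFactors = FALSE)

  cal_groups <- c("1-2", "1-2", "2-1", "2-1")
  wells_all <- list()
  cal_truth <- list()
  for (p in seq_len(n_plates)) {
    rows <- truth[ord[plate_of == p], , drop = FALSE]
    cal_id <- sprintf("CAL_%s_%d", plate_ids[p], 1:4)
    cal_truth[[p]] <- data.frame(sample_id = cal_id, cohort = "calibrator",
                                 group = cal_groups, s = group_s(cal_groups),
                                 l = group_l(cal_groups), stringsAsFactors = FALSE)
    plate_samples <- data.frame(
      sample_id = c(rows$sample_id, cal_id),
      role = c(rep("sample", nrow(rows)), rep("calibrator", 4L)),
      s = c(rows$s, group_s(cal_groups)),
      l = c(rows$l, group_l(cal_groups)),
      stringsAsFactors = FALSE)
    ns <- nrow(plate_samples)
    rep_n <- config$replicates
    labels <- well_labels()
    eff <- effects[p, ]

    sid <- rep(plate_samples$sample_id, each = rep_n)
    role <- rep(plate_samples$role, each = rep_n)
    s_cp <- rep(plate_samples$s, each = rep_n)
    l_cp <- rep(plate_samples$l, each = rep_n)
    nw <- length(sid)
    ct_ref <- eff$baseline + stats::rnorm(nw, 0, config$ref_ct_sd)
    ref_fail <- rep(stats::runif(ns) < config$ref_dropout_sample, each = rep_n)
    ct_ref[ref_fail] <- NA_real_

    gene_ct <- function(copies) {
      latent <- copies + stats::rnorm(nw, 0, config$dct_noise_sd)
      ct <- ct_ref - (eff$a * latent + eff$b)
      drop_p <- ifelse(copies == 0, config$dropout_zero,
                       ifelse(copies == 1, config$dropout_low, 0))
      ct[stats::runif(nw) < drop_p] <- NA_real_
      ct[!is.na(ct) & (ct <= 0 | ct > 40)] <- NA_real_
      ct
    }
    ct_3ds1 <- gene_ct(s_cp)
    ct_3dl1 <- gene_ct(l_cp)

    wells_all[[p]] <- data.frame(
      plate_id = plate_ids[p],
      well = labels[seq_len(nw + 1L)],
      sample_id = c(sid, NA_character_),
      role = c(role, "water"),
      ct_fam = c(ct_3ds1, NA_real_),
      ct_cy5 = c(ct_3dl1, NA_real_),
      ct_dfo = c(ct_ref, NA_real_),
      stringsAsFactors = FALSE)
  }
  list(wells = do.call(rbind, wells_all), plate_effects = effects,
       calibrators = do.call(rbind, cal_truth))
}

#' Simulate SNP-array (R, theta) signals from true copy numbers
#'
#' Per sample and SNP, the total intensity follows
#' `R ~ N(r_base + r_per_copy * (s + l), r_sd)` — so R tracks total copy
#' number — and the angle `theta ~ N(theta_base + theta_span * l/(s+l),
#' theta_sd)` truncated to `[0, 1]` — so theta tracks the KIR3DL1:KIR3DS1
#' ratio.  Case clusters are shifted by `(case_shift_r, case_shift_theta)`
#' to emulate the batch difference between cohorts processed in different
#' centres.  Raw intensities X, Y are back-computed so that `x + y = R` and
#' `(2/pi) atan2(y, x) = theta` exactly.
#'
#' @param truth truth table from [simulate_cohort()] (optionally including
#'   calibrator rows).
#' @param config a [kir_sim_config()].
#' @param snps character vector of informative SNP ids
#'   (default `"rs592645"`).
#' @param noise_snps number of additional pure-noise SNPs (signals
#'   independent of copy number; default 0).
#' @return long `data.frame`: `sample_id`, `snp_id`, `x`, `y`, `r`, `theta`,
#'   `cohort`.
#' @export
simulate_snp_signals <- function(truth, config, snps = "rs592645",
                                 noise_snps = 0) {
  set.seed(config$seed + 2L)
  n <- nrow(truth)
  total <- truth$s + truth$l
  rho <- ifelse(total > 0, truth$l / total, 0.5)
  is_case <- truth$cohort == "case"
  out <- list()
  rtrunc01 <- function(mu, sd) pmin(pmax(stats::rnorm(n, mu, sd), 0), 1)
  for (snp in snps) {
    mu_r <- config$snp_r_base + config$snp_r_per_copy * total +
      ifelse(is_case, config$case_shift_r, 0)
    mu_t <- config$snp_theta_base + config$snp_theta_span * rho +
      ifelse(is_case, config$case_shift_theta, 0)
    r <- pmax(stats::rnorm(n, mu_r, config$snp_r_sd), 0.01)
    theta <- rtrunc01(mu_t, config$snp_theta_sd)
    out[[snp]] <- data.frame(sample_id = truth$sample_id, snp_id = snp,
                             r = r, theta = theta, cohort = truth$cohort,
                             stringsAsFactors = FALSE)
  }
  if (noise_snps > 0) {
    for (j in seq_len(noise_snps)) {
      r <- pmax(stats::rnorm(n, 1, config$snp_r_sd), 0.01)
      theta <- rtrunc01(0.5, 4 * config$snp_theta_sd)
      out[[paste0("noise", j)]] <- data.frame(
        sample_id = truth$sample_id, snp_id = sprintf("rsNOISE%03d", j),
        r = r, theta = theta, cohort = truth$cohort, stringsAsFactors = FALSE)
    }
  }
  sig <- do.call(rbind, out)
  rownames(sig) <- NULL
  phi <- sig$theta * pi / 2
  sig$y <- sig$r * sin(phi) / (sin(phi) + cos(phi))
  sig$x <- sig$r - sig$y
  sig[, c("sample_id", "snp_id", "x", "y", "r", "theta", "cohort")]
}
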