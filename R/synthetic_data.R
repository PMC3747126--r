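#' Sibship size structure of the study cohort
#'
#' A fixed vector of 492 sibship sizes totalling 966 individuals: 198
#' singletons and 294 sibships of two or more siblings (sizes up to 10),
#' matching the reported cohort structure (mean sibship size 966/492 = 1.96,
#' about one fifth of participants singletons).  The size composition within
#' the multi-member sibships is not published, so a fixed composition
#' consistent with the printed totals is used.
#'
#' @return Integer vector of length 492 summing to 966.
#' @export
study_sibship_sizes <- function() {
  c(rep(1L, 198L), rep(2L, 194L), rep(3L, 60L), rep(4L, 20L), rep(5L, 11L),
    rep(6L, 4L), rep(7L, 2L), 8L, 9L, 10L)
}

#' Default sibship size distribution
#'
#' Probability of each sibship size 1..10, taken as the empirical frequency
#' of [study_sibship_sizes()]; its mean is 966/492 = 1.96 members.
#'
#' @return Numeric vector of length 10 summing to 1.
#' @export
study_sibship_size_probs <- function() {
  tabulate(study_sibship_sizes(), nbins = 10L) / 492
}

#' Default planted methylation-CRP effects
#'
#' Thirty negative coefficients on the ln-CRP scale per unit beta-value,
#' matching the magnitude range of the strongest reported associations
#' (roughly -2.2 to -4.4).  Used as the default `planted_effects`
#' coefficients of [sim_config()].
#'
#' @return Numeric vector of length 30.
#' @export
default_planted_coefficients <- function() {
  c(-4.12, -3.60, -4.42, -2.79, -3.38, -3.80, -3.32, -2.94, -2.62, -3.08,
    -3.35, -3.58, -2.68, -2.80, -2.62, -3.96, -2.70, -2.62, -3.34, -3.25,
    -3.89, -2.84, -2.93, -3.64, -3.68, -2.24, -4.22, -3.65, -2.55, -2.90)
}

default_pheno_params <- function() {
  list(
    female_fraction = 0.709,
    age_mean_f = 66.10, age_sd_f = 7.56,
    age_mean_m = 66.70, age_sd_m = 7.64,
    bmi_mean_f = 32.06, bmi_sd_f = 6.58,
    bmi_mean_m = 28.98, bmi_sd_m = 4.81,
    smoker_fraction = 0.15,
    hypertension_fraction_f = 0.835,
    hypertension_fraction_m = 0.801
  )
}

default_crp_model <- function() {
  list(
    intercept_f = log(0.38),   # female median CRP 0.38 mg/L
    intercept_m = log(0.27),   # male median CRP 0.27 mg/L
    b_age = 0.005,             # per year, centred at 66.3
    b_bmi = 0.03,              # per kg/m^2, centred at 31.2
    b_smoker = 0.30,
    b_hypertension = 0,
    sibship_sd = 0.40,         # random-intercept SD on the ln scale
    resid_sd = 0.90            # residual SD on the ln scale
  )
}

default_intensity_params <- function() {
  list(
    baseline_log_mean = log(4000),  # typical total array intensity
    baseline_log_sd = 0.40,         # between-probe spread of baselines
    sample_log_sd = 0.25,           # within-probe between-sample spread
    beta_shape1 = 1.2,              # probe mean methylation ~ Beta(1.2, 1.8)
    beta_shape2 = 1.8,
    beta_precision = 50,            # concentration of per-sample beta values
    multimodal_low = 0.15,          # mixture component centres for planted
    multimodal_high = 0.85,         #   multimodal probes (~6 SD apart on
                                    #   the log-intensity scale)
    multimodal_precision = 200,
    control_log_mean = log(3000),
    control_log_sd = 0.5,           # between-feature spread of control levels
    control_noise_sd = 0.15,        # residual noise of control intensities
    control_loading_min = 0.5,      # chip-effect loading range on controls
    control_loading_max = 1.5
  )
}

default_confounder <- function() {
  # A latent per-sample factor loading on a fraction of probes and (optionally)
  # on lnCRP; crp_effect = 0 disables it.  Switching crp_effect on inflates the
  # EWAS p-value distribution the way an unmeasured batch/confounder would.
  list(sd = 1, prop_probes = 0.3, loading_sd = 0.02, crp_effect = 0)
}

#' Configuration for the synthetic cohort generator
#'
#' Collects every parameter of the generative model behind
#' [simulate_cohort()].  The defaults reproduce the structure of the study
#' cohort: 492 sibships of 1 to 10 siblings averaging 1.96 members,
#' phenotype distributions matching the published summary table, log-normal
#' CRP with sex-specific medians (0.38 / 0.27 mg/L), 56 control probes per
#' chip carrying shared chip effects, and 30 planted negative methylation
#' effects on lnCRP.
#'
#' @param n_sibships Number of sibships to draw.
#' @param sibship_size_probs Probabilities of sibship sizes 1..10; must sum
#'   to 1.  Ignored when `sibship_sizes` is given.
#' @param sibship_sizes Optional explicit integer vector of sibship sizes,
#'   overriding random size draws (e.g. `study_sibship_sizes()`).
#' @param n_probes Number of methylation probes.
#' @param n_control_probes Number of control-probe features per chip.
#' @param n_chips Number of chips; defaults to `ceiling(n_samples / 12)`
#'   (12 samples per chip).
#' @param chip_effect_sd SD of the additive per-chip effect on log intensity,
#'   shared between target and control probes.
#' @param pheno_params List of phenotype distribution parameters; see
#'   `crpewas:::default_pheno_params()` for the fields.
#' @param crp_model List of coefficients of the ln-CRP generating model; see
#'   `crpewas:::default_crp_model()`.
#' @param intensity_params List of intensity-model parameters; see
#'   `crpewas:::default_intensity_params()`.
#' @param planted_effects Data frame with columns `probe` (1-based probe
#'   index) and `coefficient` (effect on lnCRP per unit beta-value), or NULL
#'   for the default 30 sites.  Use a zero-row data frame for a null cohort.
#' @param n_multimodal_probes Number of probes drawn from a two-component
#'   beta mixture; defaults to the array proportion 100/27578 of
#'   `n_probes`.
#' @param n_bad_samples Number of samples with displaced control values.
#' @param bad_sample_shift Displacement of bad-sample control values, in
#'   units of the control feature's model SD on the log scale.
#' @param n_bad_control_features How many control features each bad sample
#'   displaces.
#' @param n_xy_probes,n_crossreactive,n_snp_overlap Numbers of probes
#'   assigned to the X/Y chromosomes, flagged cross-reactive, and flagged as
#'   overlapping known SNPs; the defaults keep the array's proportions
#'   (1118, 2984 and 875 of 27578) at the requested `n_probes`.
#' @param confounder List describing a latent per-sample confounder; see
#'   `crpewas:::default_confounder()`.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration including this seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_sibships = 492,
                       sibship_size_probs = study_sibship_size_probs(),
                       sibship_sizes = NULL,
                       n_probes = 27578,
                       n_control_probes = 56,
                       n_chips = NULL,
                       chip_effect_sd = 0.15,
                       pheno_params = list(),
                       crp_model = list(),
                       intensity_params = list(),
                       planted_effects = NULL,
                       n_multimodal_probes = NULL,
                       n_bad_samples = 49,
                       bad_sample_shift = 6,
                       n_bad_control_features = 8,
                       n_xy_probes = NULL,
                       n_crossreactive = NULL,
                       n_snp_overlap = NULL,
                       confounder = list(),
                       seed = 1L) {
  n_sibships <- check_count(n_sibships, "n_sibships", min = 1L)
  n_probes <- check_count(n_probes, "n_probes", min = 1L)
  n_control_probes <- check_count(n_control_probes, "n_control_probes",
                                  min = 1L)
  array_scale <- function(count_27k) as.integer(round(count_27k / 27578 *
                                                        n_probes))
  if (is.null(n_multimodal_probes)) n_multimodal_probes <- array_scale(100)
  if (is.null(n_xy_probes)) n_xy_probes <- array_scale(1118)
  if (is.null(n_crossreactive)) n_crossreactive <- array_scale(2984)
  if (is.null(n_snp_overlap)) n_snp_overlap <- array_scale(875)
  n_multimodal_probes <- check_count(n_multimodal_probes,
                                     "n_multimodal_probes")
  n_bad_samples <- check_count(n_bad_samples, "n_bad_samples")
  n_xy_probes <- check_count(n_xy_probes, "n_xy_probes")
  n_crossreactive <- check_count(n_crossreactive, "n_crossreactive")
  n_snp_overlap <- check_count(n_snp_overlap, "n_snp_overlap")

  if (!is.null(sibship_sizes)) {
    sibship_sizes <- as.integer(sibship_sizes)
    if (any(sibship_sizes < 1L)) {
      stop_fmt("all 'sibship_sizes' must be >= 1")
    }
    n_sibships <- length(sibship_sizes)
  } else {
    if (length(sibship_size_probs) != 10L || any(sibship_size_probs < 0) ||
        abs(sum(sibship_size_probs) - 1) > 1e-8) {
      stop_fmt("'sibship_size_probs' must be 10 non-negative values summing to 1")
    }
  }

  if (is.null(planted_effects)) {
    coefs <- default_planted_coefficients()
    idx <- unique(round(seq(1L, n_probes, length.out = length(coefs))))
    planted_effects <- data.frame(probe = idx,
                                  coefficient = coefs[seq_along(idx)])
  }
  stopifnot(is.data.frame(planted_effects),
            all(c("probe", "coefficient") %in% names(planted_effects)))
  if (nrow(planted_effects)) {
    if (anyDuplicated(planted_effects$probe)) {
      stop_fmt("'planted_effects' probe indices must be distinct")
    }
    if (any(planted_effects$probe < 1L | planted_effects$probe > n_probes)) {
      stop_fmt("'planted_effects' probe indices must lie in [1, n_probes]")
    }
  }

  if (n_xy_probes + n_crossreactive + n_snp_overlap + n_multimodal_probes +
      nrow(planted_effects) > n_probes) {
    stop_fmt("probe annotation counts exceed n_probes")
  }

  cfg <- list(
    n_sibships = n_sibships,
    sibship_size_probs = sibship_size_probs,
    sibship_sizes = sibship_sizes,
    n_probes = n_probes,
    n_control_probes = n_control_probes,
    n_chips = if (is.null(n_chips)) NULL else check_count(n_chips, "n_chips", 1L),
    chip_effect_sd = chip_effect_sd,
    pheno_params = utils::modifyList(default_pheno_params(), pheno_params),
    crp_model = utils::modifyList(default_crp_model(), crp_model),
    intensity_params = utils::modifyList(default_intensity_params(),
                                         intensity_params),
    planted_effects = planted_effects,
    n_multimodal_probes = n_multimodal_probes,
    n_bad_samples = n_bad_samples,
    bad_sample_shift = bad_sample_shift,
    n_bad_control_features = check_count(n_bad_control_features,
                                         "n_bad_control_features", 1L),
    n_xy_probes = n_xy_probes,
    n_crossreactive = n_crossreactive,
    n_snp_overlap = n_snp_overlap,
    confounder = utils::modifyList(default_confounder(), confounder),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  sibships: %d, probes: %d, control probes: %d\n",
              x$n_sibships, x$n_probes, x$n_control_probes))
  cat(sprintf("  planted effects: %d, multimodal: %d, bad samples: %d\n",
              nrow(x$planted_effects), x$n_multimodal_probes,
              x$n_bad_samples))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Simulate a sibship-based methylation cohort
#'
#' Generates a complete synthetic dataset with the statistical structure the
#' analysis pipeline assumes: a phenotype table over sibships, beta-valued
#' methylation converted to methylated/unmethylated intensities with shared
#' per-chip effects, a control-probe matrix carrying the same chip effects,
#' planted ln-CRP effects at known probes, planted multimodal probes,
#' planted low-quality samples, and a probe manifest with chromosome,
#' position, gene, and exclusion flags.
#'
#' The ln-CRP outcome is a linear model in age, sex, BMI, current smoking,
#' (optionally hypertension and a latent confounder) plus the planted
#' mean-centred methylation effects, a per-sibship random intercept, and
#' residual noise; CRP is its exponential.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `synthetic_dataset`: a list with elements
#'   `intensities` (list of matrices `methylated`, `unmethylated`),
#'   `controls` (features x samples matrix), `manifest`, `cohort`, `truth`
#'   (planted sites/coefficients, multimodal probe ids, bad sample ids,
#'   sibship intercepts, chip assignment and effects, confounder scores),
#'   and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  pp <- config$pheno_params
  cm <- config$crp_model
  ip <- config$intensity_params

  ## ---- sibships and samples ------------------------------------------------
  sizes <- config$sibship_sizes
  if (is.null(sizes)) {
    sizes <- sample(1:10, config$n_sibships, replace = TRUE,
                    prob = config$sibship_size_probs)
  }
  n_samples <- sum(sizes)
  sibship_id <- rep(sprintf("F%04d", seq_along(sizes)), times = sizes)
  sample_id <- sprintf("S%05d", seq_len(n_samples))

  ## ---- phenotypes ----------------------------------------------------------
  female <- runif(n_samples) < pp$female_fraction
  sex <- ifelse(female, "F", "M")
  age <- ifelse(female,
                rnorm(n_samples, pp$age_mean_f, pp$age_sd_f),
                rnorm(n_samples, pp$age_mean_m, pp$age_sd_m))
  bmi <- ifelse(female,
                rnorm(n_samples, pp$bmi_mean_f, pp$bmi_sd_f),
                rnorm(n_samples, pp$bmi_mean_m, pp$bmi_sd_m))
  bmi <- pmax(bmi, 15)
  current_smoker <- runif(n_samples) < pp$smoker_fraction
  hypertension <- runif(n_samples) <
    ifelse(female, pp$hypertension_fraction_f, pp$hypertension_fraction_m)

  ## ---- probe-level methylation model --------------------------------------
  n_probes <- config$n_probes
  probe_id <- sprintf("cg%08d", seq_len(n_probes))
  planted <- config$planted_effects
  special <- planted$probe

  pool <- setdiff(seq_len(n_probes), special)
  multimodal_idx <- sort(sample(pool, config$n_multimodal_probes))
  pool <- setdiff(pool, multimodal_idx)
  xy_idx <- sort(sample(pool, config$n_xy_probes))
  pool2 <- setdiff(seq_len(n_probes), c(special, xy_idx))
  crossreactive_idx <- sort(sample(pool2, config$n_crossreactive))
  snp_idx <- sort(sample(pool2, config$n_snp_overlap))

  mu <- rbeta(n_probes, ip$beta_shape1, ip$beta_shape2)
  phi <- ip$beta_precision
  beta_true <- matrix(rbeta(n_probes * n_samples,
                            shape1 = rep(mu * phi, n_samples),
                            shape2 = rep((1 - mu) * phi, n_samples)),
                      nrow = n_probes, ncol = n_samples)

  if (length(multimodal_idx)) {
    phi_mm <- ip$multimodal_precision
    for (i in multimodal_idx) {
      comp <- runif(n_samples) < 0.5
      centre <- ifelse(comp, ip$multimodal_high, ip$multimodal_low)
      beta_true[i, ] <- rbeta(n_samples, centre * phi_mm,
                              (1 - centre) * phi_mm)
    }
  }

  ## ---- latent confounder ---------------------------------------------------
  cf <- config$confounder
  confounder_score <- rnorm(n_samples, 0, cf$sd)
  n_affected <- round(cf$prop_probes * n_probes)
  affected_idx <- sort(sample(seq_len(n_probes), n_affected))
  if (n_affected > 0) {
    loadings <- rnorm(n_affected, 0, cf$loading_sd)
    beta_true[affected_idx, ] <- beta_true[affected_idx, ] +
      outer(loadings, confounder_score)
  } else {
    loadings <- numeric(0)
  }
  beta_true <- pmin(pmax(beta_true, 1e-4), 1 - 1e-4)

  ## ---- ln-CRP --------------------------------------------------------------
  u_sib <- rnorm(length(sizes), 0, cm$sibship_sd)
  eta <- ifelse(female, cm$intercept_f, cm$intercept_m) +
    cm$b_age * (age - 66.3) +
    cm$b_bmi * (bmi - 31.2) +
    cm$b_smoker * current_smoker +
    cm$b_hypertension * hypertension +
    cf$crp_effect * confounder_score +
    rep(u_sib, times = sizes) +
    rnorm(n_samples, 0, cm$resid_sd)
  if (nrow(planted)) {
    for (r in seq_len(nrow(planted))) {
      i <- planted$probe[r]
      eta <- eta + planted$coefficient[r] * (beta_true[i, ] - mu[i])
    }
  }
  crp <- exp(eta)

  ## ---- chips and intensities ----------------------------------------------
  n_chips <- config$n_chips %||% max(1L, ceiling(n_samples / 12))
  chip <- rep(seq_len(n_chips), each = ceiling(n_samples / n_chips),
              length.out = n_samples)
  chip_effect <- rnorm(n_chips, 0, config$chip_effect_sd)

  probe_log_mean <- rnorm(n_probes, ip$baseline_log_mean, ip$baseline_log_sd)
  log_total <- matrix(rnorm(n_probes * n_samples, 0, ip$sample_log_sd),
                      nrow = n_probes, ncol = n_samples)
  log_total <- log_total + probe_log_mean +
    matrix(chip_effect[chip], nrow = n_probes, ncol = n_samples, byrow = TRUE)
  total <- exp(log_total)
  methylated <- total * beta_true
  unmethylated <- total * (1 - beta_true)
  dimnames(methylated) <- dimnames(unmethylated) <-
    list(probe_id, sample_id)

  ## ---- control probes ------------------------------------------------------
  n_ctrl <- config$n_control_probes
  ctrl_base <- rnorm(n_ctrl, ip$control_log_mean, ip$control_log_sd)
  gamma <- runif(n_ctrl, ip$control_loading_min, ip$control_loading_max)
  log_ctrl <- outer(ctrl_base, rep(1, n_samples)) +
    outer(gamma, chip_effect[chip]) +
    matrix(rnorm(n_ctrl * n_samples, 0, ip$control_noise_sd),
           nrow = n_ctrl, ncol = n_samples)

  bad_idx <- sort(sample(seq_len(n_samples),
                         min(config$n_bad_samples, n_samples)))
  feature_sd <- sqrt(gamma^2 * config$chip_effect_sd^2 +
                     ip$control_noise_sd^2)
  for (s in bad_idx) {
    feats <- sample(seq_len(n_ctrl),
                    min(config$n_bad_control_features, n_ctrl))
    signs <- sample(c(-1, 1), length(feats), replace = TRUE)
    log_ctrl[feats, s] <- log_ctrl[feats, s] +
      signs * config$bad_sample_shift * feature_sd[feats]
  }
  controls <- exp(log_ctrl)
  dimnames(controls) <- list(sprintf("ctrl%02d", seq_len(n_ctrl)), sample_id)

  ## ---- manifest ------------------------------------------------------------
  chromosome <- as.character(sample(1:22, n_probes, replace = TRUE))
  if (length(xy_idx)) {
    is_y <- runif(length(xy_idx)) < 0.03
    chromosome[xy_idx] <- ifelse(is_y, "Y", "X")
  }
  n_genes <- max(1L, ceiling(n_probes / 1.95))
  gene_pool <- sprintf("GENE%05d", seq_len(n_genes))
  gene <- sample(gene_pool, n_probes, replace = TRUE)
  gene[runif(n_probes) < 0.02] <- ""   # a few unannotated probes
  manifest <- data.frame(
    probe_id = probe_id,
    chromosome = chromosome,
    position = sample.int(2.4e8, n_probes, replace = TRUE),
    strand = sample(c("+", "-"), n_probes, replace = TRUE),
    gene = gene,
    crossreactive_flag = seq_len(n_probes) %in% crossreactive_idx,
    snp_overlap_flag = seq_len(n_probes) %in% snp_idx,
    stringsAsFactors = FALSE
  )

  cohort <- data.frame(
    sample_id = sample_id,
    sibship_id = sibship_id,
    age = age,
    sex = sex,
    bmi = bmi,
    current_smoker = current_smoker,
    hypertension = hypertension,
    crp = crp,
    stringsAsFactors = FALSE
  )

  truth <- list(
    planted = data.frame(probe_id = probe_id[planted$probe],
                         coefficient = planted$coefficient,
                         stringsAsFactors = FALSE),
    multimodal_probes = probe_id[multimodal_idx],
    bad_samples = sample_id[bad_idx],
    sibship_intercepts = setNames(u_sib,
                                  sprintf("F%04d", seq_along(sizes))),
    chip = setNames(chip, sample_id),
    chip_effects = chip_effect,
    confounder = setNames(confounder_score, sample_id),
    confounder_probes = probe_id[affected_idx],
    probe_mean = setNames(mu, probe_id)
  )

  structure(
    list(intensities = intensity_pair(methylated, unmethylated),
         controls = controls,
         manifest = manifest,
         cohort = cohort,
         truth = truth,
         config = config),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  cat(sprintf("  %d probes x %d samples in %d sibships\n",
              nrow(x$intensities$methylated),
              ncol(x$intensities$methylated),
              length(unique(x$cohort$sibship_id))))
  cat(sprintf("  planted effects: %d, multimodal: %d, bad samples: %d\n",
              nrow(x$truth$planted), length(x$truth$multimodal_probes),
              length(x$truth$bad_samples)))
  invisible(x)
}

#' Report the planted effect sites of a synthetic dataset
#'
#' @param ds A `synthetic_dataset` from [simulate_cohort()].
#' @return Data frame with one row per planted effect: `probe_id`,
#'   `coefficient`.
#' @export
truth_report <- function(ds) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  ds$truth$planted
}

#' Mean sibship size of a cohort
#'
#' @param cohort A cohort table with a `sibship_id` column.
#' @return Number of samples divided by number of sibships.
#' @export
mean_sibship_size <- function(cohort) {
  stopifnot(is.data.frame(cohort), "sibship_id" %in% names(cohort))
  nrow(cohort) / length(unique(cohort$sibship_id))
}
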