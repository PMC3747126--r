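# Control-probe PCA and intensity normalization.

test_that("control components are orthogonal and capped at the rank", {
  ds <- tiny_dataset()
  pca <- orthogonalize_controls(ds$controls, k = 5)
  expect_equal(pca$k, 5L)
  cors <- cor(pca$scores)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-8)
  expect_identical(rownames(pca$scores), colnames(ds$controls))
  expect_error(orthogonalize_controls(ds$controls, k = 1000), "rank")
})

test_that("a dominant chip-effect direction loads on the first component", {
  cfg <- sim_config(n_sibships = 150, n_probes = 5, n_multimodal_probes = 0,
                    n_bad_samples = 0, n_xy_probes = 0, n_crossreactive = 0,
                    n_snp_overlap = 0, chip_effect_sd = 0.6, seed = 88,
                    planted_effects = data.frame(probe = integer(),
                                                 coefficient = numeric()))
  ds <- simulate_cohort(cfg)
  pca <- orthogonalize_controls(ds$controls)
  chip_per_sample <- ds$truth$chip_effects[ds$truth$chip]
  expect_gt(abs(cor(pca$scores[, 1], chip_per_sample)), 0.99)
})

test_that("constant controls degrade gracefully and leave data untouched", {
  ctrl <- matrix(1000, 10, 20, dimnames = list(NULL, sprintf("S%02d", 1:20)))
  pca <- orthogonalize_controls(ctrl)
  expect_equal(pca$k, 0L)
  expect_error(orthogonalize_controls(ctrl, k = 2), "constant")
  set.seed(2)
  m <- matrix(rlnorm(5 * 20, log(2000), 0.3), 5, 20,
              dimnames = list(sprintf("cg%02d", 1:5), colnames(ctrl)))
  ints <- intensity_pair(m, m * 0.7)
  out <- regress_out_controls(ints, pca)
  expect_identical(out$methylated, ints$methylated)
})

test_that("normalization residuals are uncorrelated with the scores and idempotent", {
  # methylation bounded away from 0/1 keeps every intensity far from the
  # non-negativity floor, where the log-scale identities hold exactly
  cfg <- null_config(n_sibships = 100, n_probes = 120, seed = 63,
                     chip_effect_sd = 0.15,
                     intensity_params = list(beta_shape1 = 3,
                                             beta_shape2 = 3))
  ds <- simulate_cohort(cfg)
  pca <- orthogonalize_controls(ds$controls, k = 3)
  norm1 <- regress_out_controls(ds$intensities, pca)
  expect_true(all(norm1$methylated > 0))
  logm <- log(norm1$methylated + 1)
  cors <- abs(cor(t(logm), pca$scores))
  expect_lt(max(cors), 1e-6)
  norm2 <- regress_out_controls(norm1, pca)
  rel <- abs(norm2$methylated - norm1$methylated) /
    (1 + abs(norm1$methylated))
  expect_lt(max(rel), 1e-6)
})

test_that("normalization removes most of the planted between-chip variance", {
  cfg <- sim_config(n_sibships = 220, n_probes = 300, n_multimodal_probes = 0,
                    n_bad_samples = 0, n_xy_probes = 0, n_crossreactive = 0,
                    n_snp_overlap = 0, seed = 19,
                    planted_effects = data.frame(probe = integer(),
                                                 coefficient = numeric()))
  ds <- simulate_cohort(cfg)
  pca <- orthogonalize_controls(ds$controls)
  norm <- regress_out_controls(ds$intensities, pca)
  chip <- factor(ds$truth$chip)
  # per-probe chip variance component from the one-way ANOVA decomposition
  chip_var <- function(mat) {
    v <- log(mat + 1)
    n_per <- as.numeric(table(chip))
    sum(apply(v, 1, function(row) {
      gm <- tapply(row, chip, mean)
      msb <- sum(n_per * (gm - mean(row))^2) / (nlevels(chip) - 1)
      msw <- sum((row - gm[chip])^2) / (length(row) - nlevels(chip))
      max((msb - msw) / mean(n_per), 0)
    }))
  }
  raw <- chip_var(ds$intensities$methylated)
  cleaned <- chip_var(norm$methylated)
  expect_lt(cleaned / raw, 0.1)
})

test_that("planted association signal survives normalization", {
  cfg <- sim_config(n_sibships = 350, sibship_sizes = rep(1L, 350),
                    n_probes = 60, n_multimodal_probes = 0,
                    n_bad_samples = 0, n_xy_probes = 0, n_crossreactive = 0,
                    n_snp_overlap = 0, chip_effect_sd = 0.25, seed = 47,
                    intensity_params = list(beta_shape1 = 3, beta_shape2 = 3),
                    planted_effects = data.frame(probe = 1:5,
                                                 coefficient = rep(-4, 5)))
  ds <- simulate_cohort(cfg)
  pca <- orthogonalize_controls(ds$controls)
  norm <- regress_out_controls(ds$intensities, pca)
  spec <- model_spec(random_effect = FALSE)
  z_of <- function(ints) {
    ew <- run_ewas(compute_beta(ints), ds$cohort, spec = spec,
                   probes = ds$truth$planted$probe_id, verbose = FALSE)
    mean(abs(ew$coefficient / ew$se))
  }
  # chip-effect removal must not erode the planted signal
  expect_gte(z_of(norm), 0.95 * z_of(ds$intensities))
})

test_that("beta-values follow the offset formula and its monotonicity", {
  m <- matrix(c(0, 900, 500, 250), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  u <- matrix(c(0, 0, 500, 250), 2, 2, dimnames = dimnames(m))
  b100 <- compute_beta(intensity_pair(m, u), alpha = 100)
  expect_equal(b100["a", "s1"], 0)          # M = U = 0
  expect_equal(b100["b", "s1"], 0.9)        # 900 / (900 + 0 + 100)
  b0 <- compute_beta(intensity_pair(m, u), alpha = 0)
  expect_equal(b0["a", "s2"], 0.5)          # M = U = 500, no offset
  expect_equal(b0["a", "s1"], 0)            # 0/0 guarded
  expect_error(compute_beta(intensity_pair(m, u), alpha = -1),
               "non-negative")
  # monotone: beta increases with M, decreases with U
  ds <- tiny_dataset()
  base <- compute_beta(ds$intensities)
  up <- compute_beta(intensity_pair(ds$intensities$methylated * 1.3,
                                    ds$intensities$unmethylated))
  down <- compute_beta(intensity_pair(ds$intensities$methylated,
                                      ds$intensities$unmethylated * 1.3))
  expect_true(all(up >= base - 1e-12))
  expect_true(all(down <= base + 1e-12))
  expect_true(all(base >= 0 & base <= 1))
})
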