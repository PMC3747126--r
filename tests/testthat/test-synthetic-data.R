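# The generator is first-class code: structure, determinism, and the
# fidelity of the planted statistical features are all contracted.

test_that("study sibship structure gives a mean size of 1.96", {
  sizes <- study_sibship_sizes()
  expect_length(sizes, 492)
  expect_equal(sum(sizes), 966)
  expect_equal(sum(sizes == 1), 198)
  expect_equal(sum(sizes >= 2), 294)
  expect_lte(max(sizes), 10)
  expect_equal(round(sum(sizes) / length(sizes), 2), 1.96)
  probs <- study_sibship_size_probs()
  expect_equal(sum(probs), 1)
  expect_equal(round(sum(probs * 1:10), 2), 1.96)
})

test_that("the same configuration reproduces an identical dataset", {
  cfg <- sim_config(n_sibships = 25, n_probes = 60, n_multimodal_probes = 2,
                    n_bad_samples = 2, n_xy_probes = 4, n_crossreactive = 3,
                    n_snp_overlap = 2, seed = 7)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  # and a different seed differs
  cfg2 <- sim_config(n_sibships = 25, n_probes = 60, n_multimodal_probes = 2,
                     n_bad_samples = 2, n_xy_probes = 4, n_crossreactive = 3,
                     n_snp_overlap = 2, seed = 8)
  expect_false(identical(simulate_cohort(cfg)$cohort,
                         simulate_cohort(cfg2)$cohort))
})

test_that("dataset components are mutually consistent", {
  ds <- tiny_dataset()
  m <- ds$intensities$methylated
  expect_identical(dim(m), dim(ds$intensities$unmethylated))
  expect_identical(colnames(m), ds$cohort$sample_id)
  expect_identical(colnames(ds$controls), ds$cohort$sample_id)
  expect_identical(rownames(m), ds$manifest$probe_id)
  expect_false(anyDuplicated(ds$cohort$sample_id) > 0)
  expect_true(all(m >= 0) && all(ds$intensities$unmethylated >= 0))
  # truth lists are subsets of the manifest / cohort
  expect_true(all(ds$truth$planted$probe_id %in% ds$manifest$probe_id))
  expect_true(all(ds$truth$multimodal_probes %in% ds$manifest$probe_id))
  expect_true(all(ds$truth$bad_samples %in% ds$cohort$sample_id))
  # planted and multimodal probes stay autosomal and unflagged
  planted_rows <- ds$manifest[ds$manifest$probe_id %in%
                                ds$truth$planted$probe_id, ]
  expect_false(any(planted_rows$chromosome %in% c("X", "Y")))
  expect_true(all(ds$cohort$crp > 0))
})

test_that("truth_report mirrors the planted configuration", {
  cfg <- sim_config(n_sibships = 15, n_probes = 30, n_multimodal_probes = 0,
                    n_bad_samples = 0, n_xy_probes = 0, n_crossreactive = 0,
                    n_snp_overlap = 0, seed = 3,
                    planted_effects = data.frame(probe = c(4L, 9L, 20L),
                                                 coefficient = c(-3, -2.5, -4)))
  tr <- truth_report(simulate_cohort(cfg))
  expect_equal(nrow(tr), 3)
  expect_identical(tr$probe_id, sprintf("cg%08d", c(4L, 9L, 20L)))
  expect_equal(tr$coefficient, c(-3, -2.5, -4))
  # no planted sites -> empty report
  cfg0 <- null_config(n_sibships = 10, n_probes = 20, seed = 4)
  expect_equal(nrow(truth_report(simulate_cohort(cfg0))), 0)
})

test_that("phenotype distributions converge to their parameters", {
  cfg <- sim_config(n_sibships = 2500, n_probes = 2,
                    n_multimodal_probes = 0, n_bad_samples = 0,
                    n_xy_probes = 0, n_crossreactive = 0, n_snp_overlap = 0,
                    planted_effects = data.frame(probe = integer(),
                                                 coefficient = numeric()),
                    seed = 31)
  coh <- simulate_cohort(cfg)$cohort
  n <- nrow(coh)
  tol <- 4 / sqrt(n)
  expect_equal(mean(coh$sex == "F"), 0.709, tolerance = tol / 0.709)
  f <- coh$sex == "F"
  expect_equal(mean(coh$age[f]), 66.10, tolerance = 8 * tol / 66.1)
  expect_equal(sd(coh$age[f]), 7.56, tolerance = 0.05)
  expect_equal(mean(coh$bmi[!f]), 28.98, tolerance = 8 * tol / 29)
  # sex-specific CRP medians on the mg/L scale
  expect_equal(median(coh$crp[f]), 0.38, tolerance = 0.12)
  expect_equal(median(coh$crp[!f]), 0.27, tolerance = 0.12)
  expect_gt(median(coh$crp[f]), median(coh$crp[!f]))
})

test_that("chip_effect_sd = 0 leaves no between-chip control variance", {
  cfg <- null_config(n_sibships = 260, n_probes = 5, seed = 17)
  ds <- simulate_cohort(cfg)
  chip <- factor(ds$truth$chip)
  expect_gt(nlevels(chip), 10)
  fstats <- apply(log(ds$controls), 1, function(v) {
    summary(stats::aov(v ~ chip))[[1]][["F value"]][1]
  })
  # mean F near 1: no excess between-chip variance
  expect_equal(mean(fstats), 1, tolerance = 0.15)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(sibship_size_probs = rep(0.2, 10)), "summing to 1")
  expect_error(sim_config(n_probes = -5), "n_probes")
  expect_error(sim_config(n_probes = 100,
                          planted_effects = data.frame(probe = c(2L, 2L),
                                                       coefficient = c(-1, -2))),
               "distinct")
  expect_error(sim_config(n_probes = 100,
                          planted_effects = data.frame(probe = 200L,
                                                       coefficient = -1)),
               "probe indices")
  expect_error(sim_config(n_probes = 50, n_xy_probes = 60,
                          planted_effects = data.frame(probe = integer(),
                                                       coefficient = numeric())),
               "exceed")
})

test_that("a null generator yields CRP independent of methylation", {
  cfg <- null_config(n_sibships = 400, n_probes = 60, seed = 57,
                     crp_model = list(b_age = 0, b_bmi = 0, b_smoker = 0))
  ds <- simulate_cohort(cfg)
  y <- log(ds$cohort$crp)
  beta <- unclass(compute_beta(ds$intensities))
  cors <- apply(beta, 1, cor, y = y)
  # correlations scatter around zero at the 1/sqrt(n) scale
  expect_lt(max(abs(cors)), 6 / sqrt(nrow(ds$cohort)))
  expect_lt(abs(mean(cors)), 1.5 / sqrt(length(cors) * nrow(ds$cohort)) * 4)
})
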