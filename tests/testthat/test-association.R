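# Per-site mixed models, the interaction variant, and the direction summary.

test_that("ln-CRP transform follows the natural logarithm", {
  expect_equal(ln_transform_crp(1), 0)
  expect_equal(ln_transform_crp(exp(1)), 1)
  expect_equal(ln_transform_crp(0.38), -0.9676, tolerance = 1e-4)
  expect_error(ln_transform_crp(c(1, 0), sample_id = c("a", "b")), "b")
  expect_error(ln_transform_crp(c(1, NA)), "missing")
})

test_that("singleton-only cohorts reduce exactly to ordinary least squares", {
  cfg <- null_config(n_sibships = 200, n_probes = 20, seed = 44,
                     sibship_sizes = rep(1L, 200))
  ds <- simulate_cohort(cfg)
  beta <- compute_beta(ds$intensities)
  y <- ln_transform_crp(ds$cohort$crp)
  for (i in c(1, 7, 20)) {
    fit <- fit_site_lmm(y, beta[i, ],
                        crpewas:::covariate_frame(ds$cohort, model_spec()),
                        ds$cohort$sibship_id)
    expect_identical(fit$method, "ols")
    oracle <- lm(y ~ x + age + sex + bmi + smoke,
                 data = data.frame(y = y, x = beta[i, ], age = ds$cohort$age,
                                   sex = factor(ds$cohort$sex),
                                   bmi = ds$cohort$bmi,
                                   smoke = ds$cohort$current_smoker))
    sm <- summary(oracle)$coefficients["x", ]
    expect_equal(fit$coefficient, unname(sm["Estimate"]), tolerance = 1e-8)
    expect_equal(fit$se, unname(sm["Std. Error"]), tolerance = 1e-8)
    expect_equal(fit$p_value, unname(sm["Pr(>|t|)"]), tolerance = 1e-8)
  }
})

test_that("the coefficient sign equals the sign of the partial correlation", {
  set.seed(66)
  for (i in 1:15) {
    n <- 40
    covs <- data.frame(a = rnorm(n), b = rnorm(n))
    x <- runif(n)
    y <- rnorm(n) + covs$a - covs$b + sample(c(-2, 2), 1) * x
    fit <- fit_site_lmm(y, x, covs, sibship = NULL)
    rx <- resid(lm(x ~ a + b, data = covs))
    ry <- resid(lm(y ~ a + b, data = covs))
    expect_identical(sign(fit$coefficient), sign(cor(rx, ry)))
  }
})

test_that("mixed model recovers a planted coefficient with sibship structure", {
  cfg <- sim_config(n_sibships = 300, n_probes = 5, n_multimodal_probes = 0,
                    n_bad_samples = 0, n_xy_probes = 0, n_crossreactive = 0,
                    n_snp_overlap = 0, chip_effect_sd = 0, seed = 91,
                    intensity_params = list(beta_shape1 = 3, beta_shape2 = 3),
                    planted_effects = data.frame(probe = 2L,
                                                 coefficient = -3))
  ds <- simulate_cohort(cfg)
  beta <- compute_beta(ds$intensities)
  fit <- fit_site_lmm(ln_transform_crp(ds$cohort$crp), beta[2, ],
                      crpewas:::covariate_frame(ds$cohort, model_spec()),
                      ds$cohort$sibship_id)
  expect_identical(fit$method, "lmm")
  expect_true(fit$converged)
  expect_gt(fit$sigma_sibship, 0)
  expect_lt(abs(fit$coefficient - (-3)), 3 * fit$se)
  expect_lt(fit$p_value, 0.01)
})

test_that("degenerate probes are skipped, not fatal, in the scan", {
  ds <- tiny_dataset()
  beta <- unclass(compute_beta(ds$intensities))[1:10, ]
  beta[4, ] <- 0.5  # constant exposure
  ew <- run_ewas(beta, ds$cohort, verbose = FALSE)
  expect_equal(nrow(ew), 9)
  skipped <- attr(ew, "skipped")
  expect_equal(skipped$probe_id, rownames(beta)[4])
  expect_match(skipped$reason, "constant")
})

test_that("the scan is invariant to sample order and duplicates are identical", {
  ds <- tiny_dataset()
  beta <- compute_beta(ds$intensities)[1:8, ]
  ew1 <- run_ewas(beta, ds$cohort, verbose = FALSE)
  perm <- sample(ncol(beta))
  ew2 <- run_ewas(beta[, perm], ds$cohort, verbose = FALSE)
  expect_equal(ew1, ew2)
  dup <- rbind(beta[3, , drop = FALSE], beta[3, , drop = FALSE])
  rownames(dup) <- c("d1", "d2")
  ewd <- run_ewas(dup, ds$cohort, verbose = FALSE)
  expect_equal(ewd$coefficient[1], ewd$coefficient[2])
  expect_equal(ewd$p_value[1], ewd$p_value[2])
})

test_that("a sex-symmetric effect yields a near-zero interaction", {
  cfg <- sim_config(n_sibships = 350, n_probes = 4, n_multimodal_probes = 0,
                    n_bad_samples = 0, n_xy_probes = 0, n_crossreactive = 0,
                    n_snp_overlap = 0, chip_effect_sd = 0, seed = 71,
                    planted_effects = data.frame(probe = 1L,
                                                 coefficient = -3))
  ds <- simulate_cohort(cfg)
  beta <- compute_beta(ds$intensities)
  it <- fit_interaction(beta, ds$cohort, probes = rownames(beta)[1])
  expect_equal(it$model_tag, "interaction")
  expect_lt(abs(it$coefficient), 3 * it$se)
  # single-sex cohorts cannot estimate a sex interaction
  males <- ds$cohort[ds$cohort$sex == "M", ]
  expect_error(fit_interaction(beta, males, probes = rownames(beta)[1]),
               "both sexes")
})

test_that("a planted sex-specific effect is detected by the interaction test", {
  cfg <- null_config(n_sibships = 480, n_probes = 4, seed = 83)
  ds <- simulate_cohort(cfg)
  beta <- compute_beta(ds$intensities)
  coh <- ds$cohort
  x <- beta[2, coh$sample_id]
  # effect differs by 4 units between the sexes
  coh$crp <- exp(log(coh$crp) + ifelse(coh$sex == "F", -4, 0) * (x - mean(x)))
  it <- fit_interaction(beta, coh, probes = rownames(beta)[2])
  expect_lt(it$p_value, 0.05 / 257)
})

test_that("direction summaries reproduce the percentage arithmetic", {
  tab <- data.frame(probe_id = sprintf("p%03d", 1:257),
                    coefficient = c(rep(-1, 207), rep(1, 50)))
  d <- count_direction(tab, tab$probe_id)
  expect_equal(d$n_negative, 207)
  expect_equal(d$n_total, 257)
  expect_equal(d$percent_negative, 80.5)
  expect_equal(count_direction(tab, tab$probe_id[1:207])$percent_negative,
               100.0)
  tab3 <- data.frame(probe_id = c("a", "b", "c"),
                     coefficient = c(-1, 2, 3))
  expect_equal(count_direction(tab3, tab3$probe_id)$percent_negative, 33.3)
  expect_error(count_direction(tab, character(0)), "empty")
  expect_error(count_direction(tab3, "zzz"), "absent")
})
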