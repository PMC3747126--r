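# Sibship splitting into unrelated subsets and top-hit re-testing.

make_cohort <- function(sizes, seed = 1) {
  cfg <- null_config(n_sibships = length(sizes), n_probes = 2, seed = seed,
                     sibship_sizes = sizes)
  simulate_cohort(cfg)$cohort
}

test_that("294 multi-member sibships plus 198 singletons give 393 + 393", {
  coh <- make_cohort(c(rep(2L, 294), rep(1L, 198)), seed = 14)
  sp <- split_sibships(coh, seed = 20)
  expect_length(sp$subset1, 393)
  expect_length(sp$subset2, 393)
  expect_length(intersect(sp$subset1, sp$subset2), 0)
})

test_that("subsets are always disjoint and internally unrelated", {
  for (s in 1:12) {
    sizes <- sample(1:6, 30, replace = TRUE)
    coh <- make_cohort(sizes, seed = s)
    sp <- suppressMessages(split_sibships(coh, seed = s * 3))
    expect_length(intersect(sp$subset1, sp$subset2), 0)
    for (sub in list(sp$subset1, sp$subset2)) {
      sibs <- coh$sibship_id[match(sub, coh$sample_id)]
      expect_false(anyDuplicated(sibs) > 0)
      # every multi-member sibship contributes exactly one member
      expect_true(all(table(coh$sibship_id)[unique(sibs)] >= 1))
    }
    # both subsets the same size (singletons are balanced, odd one dropped)
    expect_length(sp$subset1, length(sp$subset2))
  }
})

test_that("a singleton-only cohort is partitioned in half at random", {
  coh <- make_cohort(rep(1L, 40), seed = 5)
  sp <- split_sibships(coh, seed = 9)
  expect_length(sp$subset1, 20)
  expect_length(sp$subset2, 20)
  expect_setequal(c(sp$subset1, sp$subset2), coh$sample_id)
})

test_that("an odd singleton count drops one sample with a message", {
  coh <- make_cohort(c(2L, 2L, 1L, 1L, 1L), seed = 6)
  expect_message(sp <- split_sibships(coh, seed = 2), "odd singleton")
  expect_length(sp$subset1, 3)
  expect_length(sp$subset2, 3)
  expect_false(is.null(sp$dropped_singleton))
})

test_that("the split is deterministic for a fixed seed", {
  coh <- make_cohort(sample(1:4, 25, replace = TRUE), seed = 8)
  s1 <- suppressMessages(split_sibships(coh, seed = 123))
  s2 <- suppressMessages(split_sibships(coh, seed = 123))
  expect_identical(s1$subset1, s2$subset1)
  expect_identical(s1$subset2, s2$subset2)
  expect_error(split_sibships(coh[coh$sibship_id == coh$sibship_id[1], ]),
               "2 sibships")
})

test_that("top hits with strong planted effects replicate in both subsets", {
  cfg <- sim_config(n_sibships = 450, sibship_sizes = c(rep(2L, 330),
                                                        rep(1L, 120)),
                    n_probes = 40, n_multimodal_probes = 0,
                    n_bad_samples = 0, n_xy_probes = 0, n_crossreactive = 0,
                    n_snp_overlap = 0, chip_effect_sd = 0, seed = 33,
                    intensity_params = list(beta_shape1 = 3, beta_shape2 = 3),
                    planted_effects = data.frame(probe = 1:3,
                                                 coefficient = rep(-5, 3)))
  ds <- simulate_cohort(cfg)
  beta <- compute_beta(ds$intensities)
  sp <- split_sibships(ds$cohort, seed = 77)
  hits <- ds$truth$planted$probe_id
  rep <- replicate_top_hits(beta, ds$cohort, sp, hits)
  expect_equal(rep$threshold, 0.05 / 3)
  expect_gte(mean(rep$verdicts$verdict == "both"), 0.8)
  expect_true(all(rep$verdicts$sign_concordant[
    rep$verdicts$verdict == "both"]))
  expect_identical(rep$subset1$model_tag[1], "subset1")
})

test_that("re-testing 30 hits uses the 1.67e-3 per-test threshold", {
  ds <- tiny_dataset()
  beta <- compute_beta(ds$intensities)
  sp <- suppressMessages(split_sibships(ds$cohort, seed = 4))
  hits <- rownames(beta)[1:30]
  rep <- replicate_top_hits(beta, ds$cohort, sp, hits)
  expect_equal(round(rep$threshold, 5), round(0.05 / 30, 5))
  expect_setequal(rep$verdicts$probe_id, hits)
  expect_error(replicate_top_hits(beta, ds$cohort, sp, "cg99999999"),
               "cg99999999")
})

test_that("null coefficients in the two subsets are uncorrelated", {
  cfg <- null_config(n_sibships = 260, n_probes = 120, seed = 21,
                     sibship_sizes = c(rep(2L, 200), rep(1L, 60)))
  ds <- simulate_cohort(cfg)
  beta <- compute_beta(ds$intensities)
  sp <- split_sibships(ds$cohort, seed = 31)
  rep <- replicate_top_hits(beta, ds$cohort, sp, rownames(beta))
  r <- cor(rep$verdicts$coefficient1, rep$verdicts$coefficient2)
  expect_lt(abs(r), 3 / sqrt(nrow(rep$verdicts)))
})
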