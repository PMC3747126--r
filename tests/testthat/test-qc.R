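# Sample exclusion on control-probe outliers and site-level filtering.

make_controls <- function(n_feat = 8, n_samp = 20, seed = 3) {
  set.seed(seed)
  m <- matrix(rnorm(n_feat * n_samp, mean = 1000, sd = 30),
              n_feat, n_samp,
              dimnames = list(sprintf("ctrl%02d", 1:n_feat),
                              sprintf("S%03d", 1:n_samp)))
  m
}

test_that("a constructed control outlier is the only excluded sample", {
  # all other samples sit exactly at the feature mean, so the displaced
  # sample carries the entire feature variance: its z-score is
  # (1 - 1/n) / sqrt(((1 - 1/n)^2 + (n - 1)/n^2) / (n - 1)) ~ 4.25 at n = 20
  ctrl <- make_controls()
  ctrl[3, ] <- 1000
  ctrl[3, 7] <- 1250
  out <- flag_samples_by_controls(ctrl, k_sd = 4)
  expect_identical(as.character(out), "S007")
  expect_identical(attr(out, "reason"), "ctrl03")
})

test_that("identical control values exclude nobody (zero-variance guard)", {
  ctrl <- matrix(500, 6, 10,
                 dimnames = list(NULL, sprintf("S%02d", 1:10)))
  expect_length(flag_samples_by_controls(ctrl), 0)
})

test_that("sample exclusion is invariant to sample order", {
  ctrl <- make_controls(seed = 9)
  ctrl[2, 4] <- ctrl[2, 4] + 10 * sd(ctrl[2, ])
  perm <- sample(ncol(ctrl))
  a <- sort(as.character(flag_samples_by_controls(ctrl)))
  b <- sort(as.character(flag_samples_by_controls(ctrl[, perm])))
  expect_identical(a, b)
})

test_that("control QC requires at least 3 samples and a positive threshold", {
  ctrl <- make_controls(n_samp = 2)
  expect_error(flag_samples_by_controls(ctrl), "3 samples")
  expect_error(flag_samples_by_controls(make_controls(), k_sd = 0),
               "positive")
})

test_that("planted bad samples are recovered by the 4-SD rule", {
  ds <- tiny_dataset()
  excluded <- flag_samples_by_controls(ds$controls)
  expect_true(all(ds$truth$bad_samples %in% excluded))
})

test_that("planted bimodal probes are flagged, unimodal ones spared", {
  ds <- tiny_dataset()
  keep <- setdiff(colnames(ds$intensities$methylated),
                  ds$truth$bad_samples)
  ints <- intensity_pair(ds$intensities$methylated[, keep],
                         ds$intensities$unmethylated[, keep])
  flagged <- flag_multimodal_sites(ints, n_boot = 1000, seed = 55)
  expect_true(all(ds$truth$multimodal_probes %in% flagged))
  # false positives bounded well above the binomial expectation at alpha
  null_probes <- setdiff(rownames(ds$intensities$methylated),
                         ds$truth$multimodal_probes)
  expect_lte(sum(flagged %in% null_probes), 3)
})

test_that("a probe bimodal in only the unmethylated channel is flagged", {
  set.seed(77)
  n <- 300
  m <- matrix(rnorm(5 * n, 2000, 60), 5, n,
              dimnames = list(sprintf("cg%02d", 1:5), sprintf("S%03d", 1:n)))
  u <- matrix(rnorm(5 * n, 2000, 60), 5, n, dimnames = dimnames(m))
  u[4, ] <- ifelse(runif(n) < 0.5, rnorm(n, 500, 40), rnorm(n, 3500, 40))
  flagged <- flag_multimodal_sites(intensity_pair(m, u),
                                   n_boot = 1000, seed = 6)
  expect_identical(as.character(flagged), "cg04")
})

test_that("site filters count and separate flag reasons correctly", {
  manifest <- data.frame(
    probe_id = sprintf("p%02d", 1:10),
    chromosome = c("X", "X", rep("7", 8)),
    position = 1:10 * 100L,
    strand = "+",
    gene = "G1",
    crossreactive_flag = c(rep(FALSE, 9), TRUE),
    snp_overlap_flag = c(rep(FALSE, 9), TRUE),
    stringsAsFactors = FALSE
  )
  rep1 <- apply_site_filters(manifest, multimodal = "p03")
  expect_equal(rep1$n_sites_tested, 7)          # 10 - 2 on X - 1 multimodal
  expect_setequal(rep1$kept, sprintf("p%02d", c(4:10)))
  # doubly flagged probe appears once per reason
  p10 <- rep1$flagged_sites[rep1$flagged_sites$probe_id == "p10", ]
  expect_setequal(p10$reason, c("crossreactive", "snp_overlap"))
  # strict mode removes the union of all flags
  rep2 <- apply_site_filters(manifest, multimodal = "p03",
                             drop_flagged = TRUE)
  expect_equal(rep2$n_sites_tested,
               10 - length(unique(rep2$flagged_sites$probe_id)))
  # no flags at all: everything kept
  clean <- manifest
  clean$chromosome <- "7"
  clean$crossreactive_flag <- FALSE
  clean$snp_overlap_flag <- FALSE
  expect_setequal(apply_site_filters(clean)$kept, manifest$probe_id)
  expect_error(apply_site_filters(manifest, multimodal = "nope"),
               "not in manifest")
})

test_that("run_qc chains sample exclusion, dip filtering and site filters", {
  ds <- tiny_dataset()
  qc <- run_qc(ds$intensities, ds$controls, ds$manifest,
               n_boot = 1500, seed = 12)
  expect_true(all(ds$truth$bad_samples %in%
                    qc$report$excluded_samples$sample_id))
  mm <- qc$report$flagged_sites$probe_id[
    qc$report$flagged_sites$reason == "multimodal"]
  expect_true(all(ds$truth$multimodal_probes %in% mm))
  expect_equal(qc$report$n_sites_tested, nrow(qc$intensities$methylated))
  expect_false(any(qc$report$excluded_samples$sample_id %in%
                     colnames(qc$intensities$methylated)))
})
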