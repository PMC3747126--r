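## Sample-level QC on control probes and site-level filtering
## (multimodality by the dip test, cross-reactive / SNP-overlap flags,
## sex-chromosome exclusion).

#' Flag samples with outlying control-probe values
#'
#' A sample is excluded when any control feature deviates from that
#' feature's cross-sample mean by more than `k_sd` times its cross-sample
#' standard deviation.  Features with zero variance never trigger
#' exclusions.
#'
#' @param controls Numeric matrix, control features x samples.
#' @param k_sd Exclusion threshold in SD units (default 4).
#' @return Character vector of excluded sample ids, with a `reason`
#'   attribute naming the first offending control feature per sample.
#' @export
flag_samples_by_controls <- function(controls, k_sd = 4) {
  stopifnot(is.matrix(controls), is.numeric(controls))
  if (ncol(controls) < 3L) {
    stop_fmt("control-probe QC needs at least 3 samples, got %d",
             ncol(controls))
  }
  if (!is.numeric(k_sd) || length(k_sd) != 1L || k_sd <= 0) {
    stop_fmt("'k_sd' must be a single positive number")
  }
  mu <- rowMeans(controls)
  sdev <- apply(controls, 1L, sd)
  z <- abs(controls - mu) / ifelse(sdev > 0, sdev, Inf)
  offending <- z > k_sd
  excluded <- which(colSums(offending) > 0)
  ids <- colnames(controls)[excluded] %||% as.character(excluded)
  reason <- vapply(excluded, function(j) {
    f <- which(offending[, j])[1]
    rownames(controls)[f] %||% as.character(f)
  }, character(1), USE.NAMES = FALSE)
  structure(ids, reason = reason)
}

#' Hartigan-Hartigan dip statistic
#'
#' The maximum sup-norm distance between the empirical CDF of `values` and
#' the closest unimodal CDF.  Lies in (0, 0.25]; its minimum for n distinct
#' values is 1/(2n) and it attains 0.25 for two equal point masses.  The
#' statistic is invariant to affine transformations of the data.
#'
#' @param values Numeric vector, at least 4 finite values.
#' @return The dip statistic.
#' @export
dip_statistic <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop_fmt("dip_statistic requires finite values")
  }
  if (length(values) < 4L) {
    stop_fmt("dip_statistic needs at least 4 values, got %d", length(values))
  }
  .dip_sorted(sort(values))
}

#' Null distribution of the dip statistic under uniformity
#'
#' Simulates `n_boot` uniform(0, 1) samples of size `n` and returns their
#' dip statistics.  The uniform is the conservative unimodal null
#' recommended for calibrating the dip test.
#'
#' @param n Sample size of each draw.
#' @param n_boot Number of bootstrap draws (at least 100).
#' @param seed Optional seed for reproducibility.
#' @return Numeric vector of `n_boot` dip statistics.
#' @export
dip_null_distribution <- function(n, n_boot = 2000, seed = NULL) {
  n <- check_count(n, "n", min = 4L)
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  with_seed(seed, {
    m <- matrix(runif(n * n_boot), nrow = n_boot, ncol = n)
    .dip_rows(m)
  })
}

#' Bootstrap p-value for an observed dip statistic
#'
#' The p-value is the add-one-smoothed fraction of uniform null samples of
#' size `n` whose dip is at least the observed dip:
#' `(b + 1) / (n_boot + 1)`.
#'
#' @param dip Observed dip statistic (non-negative).
#' @param n Sample size the dip was computed from.
#' @param n_boot Number of uniform bootstrap draws (at least 100).
#' @param seed Optional seed.
#' @param null_dips Optional precomputed [dip_null_distribution()] to reuse
#'   across many tests at the same `n`.
#' @return P-value in (0, 1].
#' @export
dip_test_pvalue <- function(dip, n, n_boot = 2000, seed = NULL,
                            null_dips = NULL) {
  if (!is.numeric(dip) || length(dip) != 1L || is.na(dip) || dip < 0) {
    stop_fmt("'dip' must be a single non-negative number")
  }
  if (is.null(null_dips)) {
    null_dips <- dip_null_distribution(n, n_boot = n_boot, seed = seed)
  }
  (sum(null_dips >= dip) + 1) / (length(null_dips) + 1)
}

#' Flag probes with multimodal intensity distributions
#'
#' Computes the dip statistic of each probe's methylated and unmethylated
#' cross-sample intensities and flags the probe when the dip-test p-value
#' is below `alpha` in either channel.  One uniform null distribution is
#' simulated per sample size and shared across probes.
#'
#' @param intensities An [intensity_pair()].
#' @param alpha Flagging threshold on the dip p-value (default 0.001).
#' @param n_boot Bootstrap draws for the null distribution.
#' @param seed Optional seed for the null simulation.
#' @return Character vector of flagged probe ids; a data frame of per-probe
#'   dips and p-values in both channels is attached as attribute
#'   `"details"`.
#' @export
flag_multimodal_sites <- function(intensities, alpha = 0.001,
                                  n_boot = 2000, seed = NULL) {
  stopifnot(inherits(intensities, "intensity_pair"))
  if (alpha <= 0 || alpha >= 1) stop_fmt("'alpha' must be in (0, 1)")
  if (1 / (n_boot + 1) >= alpha) {
    warning(sprintf(paste("the smallest attainable p-value 1/(n_boot + 1)",
                          "= %.3g is not below alpha = %g; no probe can",
                          "be flagged"), 1 / (n_boot + 1), alpha))
  }
  n <- ncol(intensities$methylated)
  null_dips <- sort(dip_null_distribution(n, n_boot = n_boot, seed = seed))
  dip_m <- .dip_rows(intensities$methylated)
  dip_u <- .dip_rows(intensities$unmethylated)
  # p = (#null >= dip + 1) / (n_boot + 1), vectorized over probes
  p_of <- function(d) {
    (length(null_dips) - findInterval(d, null_dips, left.open = TRUE) + 1) /
      (length(null_dips) + 1)
  }
  p_m <- p_of(dip_m)
  p_u <- p_of(dip_u)
  flagged <- p_m < alpha | p_u < alpha
  details <- data.frame(
    probe_id = rownames(intensities$methylated),
    dip_methylated = dip_m, p_methylated = p_m,
    dip_unmethylated = dip_u, p_unmethylated = p_u,
    flagged = flagged,
    stringsAsFactors = FALSE
  )
  structure(details$probe_id[flagged], details = details)
}

#' Apply site-level filters to a probe manifest
#'
#' The tested probe set excludes X/Y-chromosome probes and probes flagged
#' multimodal.  Cross-reactive and SNP-overlap probes are flagged and
#' reported separately but kept in the tested set unless
#' `drop_flagged = TRUE`, so their results can be set apart after the
#' analysis rather than silently discarded.
#'
#' @param manifest Probe manifest (see [read_manifest()]).
#' @param multimodal Character vector of multimodal probe ids.
#' @param drop_flagged Also exclude cross-reactive and SNP-overlap probes
#'   from the tested set.
#' @return List of class `qc_report`: `kept` (tested probe ids),
#'   `flagged_sites` (data frame probe_id/reason, one row per reason),
#'   `n_sites_tested`, and `excluded_samples` (empty here; filled by
#'   [run_qc()]).
#' @export
apply_site_filters <- function(manifest, multimodal = character(),
                               drop_flagged = FALSE) {
  manifest <- validate_manifest(manifest)
  unknown <- setdiff(multimodal, manifest$probe_id)
  if (length(unknown)) {
    stop_fmt("multimodal probe(s) not in manifest: %s",
             paste(head(unknown, 3), collapse = ", "))
  }
  sexchrom <- manifest$probe_id[manifest$chromosome %in% c("X", "Y")]
  crossreactive <- manifest$probe_id[manifest$crossreactive_flag]
  snp <- manifest$probe_id[manifest$snp_overlap_flag]

  flag_df <- function(ids, reason) {
    data.frame(probe_id = as.character(ids),
               reason = rep(reason, length(ids)), stringsAsFactors = FALSE)
  }
  flagged_sites <- rbind(
    flag_df(sexchrom, "sex_chromosome"),
    flag_df(multimodal, "multimodal"),
    flag_df(crossreactive, "crossreactive"),
    flag_df(snp, "snp_overlap")
  )

  drop <- union(sexchrom, multimodal)
  if (drop_flagged) drop <- union(drop, union(crossreactive, snp))
  kept <- setdiff(manifest$probe_id, drop)

  structure(
    list(kept = kept,
         flagged_sites = flagged_sites,
         n_sites_tested = length(kept),
         excluded_samples = data.frame(sample_id = character(),
                                       reason = character(),
                                       stringsAsFactors = FALSE)),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  samples excluded: %d\n", nrow(x$excluded_samples)))
  if (nrow(x$flagged_sites)) {
    tab <- table(x$flagged_sites$reason)
    cat(sprintf("  flagged sites: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  cat(sprintf("  sites tested: %d\n", x$n_sites_tested))
  invisible(x)
}

#' Run the full QC stage of the pipeline
#'
#' Excludes samples on control-probe outliers, runs the dip test on the
#' remaining samples' intensities, and applies the site filters.
#'
#' @param intensities An [intensity_pair()].
#' @param controls Control-probe matrix (features x samples).
#' @param manifest Probe manifest.
#' @param k_sd Sample-exclusion threshold in SD units.
#' @param dip_alpha Dip-test flagging threshold.
#' @param n_boot Dip-test bootstrap draws.
#' @param seed Seed for the dip null simulation.
#' @param drop_flagged Passed to [apply_site_filters()].
#' @return List: `report` (a `qc_report` including excluded samples),
#'   `intensities` (filtered intensity pair), `kept_samples`.
#' @export
run_qc <- function(intensities, controls, manifest, k_sd = 4,
                   dip_alpha = 0.001, n_boot = 2000, seed = NULL,
                   drop_flagged = FALSE) {
  stopifnot(inherits(intensities, "intensity_pair"))
  bad <- flag_samples_by_controls(controls, k_sd = k_sd)
  keep_samples <- setdiff(colnames(intensities$methylated), bad)
  filtered <- intensity_pair(
    intensities$methylated[, keep_samples, drop = FALSE],
    intensities$unmethylated[, keep_samples, drop = FALSE]
  )
  multimodal <- flag_multimodal_sites(filtered, alpha = dip_alpha,
                                      n_boot = n_boot, seed = seed)
  report <- apply_site_filters(manifest, multimodal,
                               drop_flagged = drop_flagged)
  report$excluded_samples <- data.frame(
    sample_id = as.character(bad),
    reason = sprintf("control_probe_outlier:%s", attr(bad, "reason")),
    stringsAsFactors = FALSE
  )
  filtered <- intensity_pair(
    filtered$methylated[report$kept, , drop = FALSE],
    filtered$unmethylated[report$kept, , drop = FALSE]
  )
  list(report = report, intensities = filtered, kept_samples = keep_samples)
}
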