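## Control-probe principal-component normalization: standardize the control
## features, extract orthogonal per-sample scores, and regress them out of
## the log methylated/unmethylated signals probe by probe.

#' Orthogonal control-probe predictors
#'
#' Standardizes each control feature across samples (mean 0, SD 1) and
#' decomposes the samples x features matrix into principal components.  The
#' component scores are mutually orthogonal summaries of the control-probe
#' distributions, suitable as batch/chip-effect predictors.
#'
#' @param controls Control matrix, features x samples.
#' @param k Number of components; default keeps components with eigenvalue
#'   above 1 on the standardized features (Kaiser rule), at least 1.
#' @param log_scale Standardize `log(controls + 1)` rather than the raw
#'   values (default): chip and batch artefacts act multiplicatively on
#'   intensities, so they are linear on the log scale.
#' @return Object of class `control_pca`: `scores` (samples x k),
#'   `loadings` (features x k), `eigenvalues`, `explained_variance`
#'   (proportions), `k`.  Constant control matrices yield `k = 0` with
#'   empty scores when `k` is not requested explicitly.
#' @export
orthogonalize_controls <- function(controls, k = NULL, log_scale = TRUE) {
  stopifnot(is.matrix(controls), is.numeric(controls))
  if (log_scale) {
    if (min(controls) < 0) stop_fmt("negative control values on log scale")
    controls <- log(controls + 1)
  }
  n <- ncol(controls)
  sdev <- apply(controls, 1L, sd)
  variable <- sdev > 0
  if (!any(variable)) {
    if (!is.null(k)) stop_fmt("control probes are constant across samples")
    return(structure(list(scores = matrix(0, n, 0,
                                          dimnames = list(colnames(controls),
                                                          NULL)),
                          loadings = matrix(0, nrow(controls), 0),
                          eigenvalues = numeric(0),
                          explained_variance = numeric(0), k = 0L),
                     class = "control_pca"))
  }
  x <- t((controls[variable, , drop = FALSE] - rowMeans(controls[variable, ,
                                                               drop = FALSE])) /
           sdev[variable])
  p <- prcomp(x, center = FALSE, scale. = FALSE)
  ev <- p$sdev^2
  rank <- sum(p$sdev > max(p$sdev) * 1e-8)
  if (is.null(k)) {
    k <- max(1L, sum(ev > 1))
    k <- min(k, rank)
  } else {
    k <- check_count(k, "k", min = 1L)
    if (k > rank) {
      stop_fmt("k = %d exceeds the rank (%d) of the control matrix", k, rank)
    }
  }
  scores <- p$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- colnames(controls)
  loadings <- matrix(0, nrow(controls), k,
                     dimnames = list(rownames(controls), colnames(scores)))
  loadings[variable, ] <- p$rotation[, seq_len(k), drop = FALSE]
  structure(list(scores = scores, loadings = loadings,
                 eigenvalues = ev[seq_len(k)],
                 explained_variance = ev[seq_len(k)] / sum(ev), k = k),
            class = "control_pca")
}

#' @export
print.control_pca <- function(x, ...) {
  cat(sprintf("<control_pca> k = %d component(s), explained variance: %s\n",
              x$k, paste(sprintf("%.1f%%", 100 * x$explained_variance),
                         collapse = ", ")))
  invisible(x)
}

#' Regress control-probe components out of the intensity signals
#'
#' For every probe and each channel independently, the log intensities
#' `log(y + 1)` are regressed across samples on the control-PCA scores; the
#' normalized signal is `exp(residual + fitted intercept) - 1`, floored at
#' zero, which removes the chip/batch component while keeping each probe on
#' its original intensity scale.
#'
#' @param intensities An [intensity_pair()].
#' @param pca A [orthogonalize_controls()] result whose scores cover the
#'   same samples.
#' @param log_scale Regress on the log scale (default) or on raw
#'   intensities.
#' @return A normalized [intensity_pair()].
#' @export
regress_out_controls <- function(intensities, pca, log_scale = TRUE) {
  stopifnot(inherits(intensities, "intensity_pair"),
            inherits(pca, "control_pca"))
  samples <- colnames(intensities$methylated)
  if (!setequal(samples, rownames(pca$scores))) {
    stop_fmt("control PCA scores and intensities cover different samples")
  }
  scores <- pca$scores[samples, , drop = FALSE]
  k <- ncol(scores)
  if (k == 0L) return(intensities)
  n <- length(samples)
  if (n <= k + 1L) {
    stop_fmt("need more than k + 1 = %d samples to regress out %d components",
             k + 1L, k)
  }
  design <- cbind(intercept = 1, scores)
  # per-probe OLS for all probes at once: B = Y X (X'X)^-1
  proj <- design %*% solve(crossprod(design))
  normalize_channel <- function(y) {
    v <- if (log_scale) log(y + 1) else y
    beta <- v %*% proj                      # probes x (k+1) coefficients
    fitted_batch <- beta[, -1, drop = FALSE] %*% t(scores)
    out <- v - fitted_batch
    out <- if (log_scale) exp(out) - 1 else out
    pmax(out, 0)
  }
  intensity_pair(normalize_channel(intensities$methylated),
                 normalize_channel(intensities$unmethylated))
}

#' Compute beta-values from an intensity pair
#'
#' The beta-value is `M / (M + U + alpha)`, the standard methylation
#' fraction estimate with a stabilizing offset in the denominator.
#'
#' @param intensities An [intensity_pair()].
#' @param alpha Non-negative offset (platform convention 100).
#' @return A `beta_matrix`: probes x samples matrix of values in `[0, 1]`
#'   with the offset stored in attribute `offset_alpha`.
#' @export
compute_beta <- function(intensities, alpha = 100) {
  stopifnot(inherits(intensities, "intensity_pair"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    stop_fmt("'alpha' must be a single non-negative number")
  }
  m <- intensities$methylated
  u <- intensities$unmethylated
  denom <- m + u + alpha
  beta <- ifelse(denom > 0, m / denom, 0)
  structure(beta, offset_alpha = alpha, class = c("beta_matrix", "matrix",
                                                  "array"))
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples, offset alpha = %g\n",
              nrow(x), ncol(x), attr(x, "offset_alpha")))
  cat(sprintf("  mean beta-value: %.3f\n", mean(x)))
  invisible(x)
}

as_beta_values <- function(beta) {
  if (inherits(beta, "beta_matrix")) {
    attributes(beta)[setdiff(names(attributes(beta)),
                             c("dim", "dimnames"))] <- NULL
  }
  stopifnot(is.matrix(beta), is.numeric(beta))
  beta
}
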