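## Multiple-testing corrections and inflation diagnostics: Bonferroni
## thresholds, Benjamini-Hochberg q-values, the genomic inflation factor
## with QQ-plot coordinates, and methylome principal components used to
## adjust for unmeasured confounding.

#' Bonferroni-corrected nominal p-value threshold
#'
#' @param alpha Family-wise error level, in (0, 1).
#' @param m Number of tests (at least 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_fmt("'alpha' must be a single number in (0, 1)")
  }
  m <- check_count(m, "m", min = 1L)
  alpha / m
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up adjusted p-values: on sorted p-values,
#' `q(i) = min_{j >= i} p(j) * m / j`, mapped back to the input order.
#'
#' @param pvals P-values in (0, 1].
#' @return Q-values in (0, 1], same order as the input.
#' @export
bh_qvalues <- function(pvals) {
  if (!is.numeric(pvals) || length(pvals) == 0L) {
    stop_fmt("'pvals' must be a non-empty numeric vector")
  }
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1)) {
    stop_fmt("all p-values must lie in (0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Annotate an association table with q-values
#'
#' @param table Association table from [run_ewas()].
#' @return The table with its `q_value` column filled by [bh_qvalues()].
#' @export
annotate_qvalues <- function(table) {
  table$q_value <- bh_qvalues(table$p_value)
  table
}

#' Genomic inflation factor and QQ-plot coordinates
#'
#' Converts each p-value to a 1-df chi-square quantile; lambda is the
#' median of those quantiles divided by the null median 0.4549.  The
#' QQ coordinates compare observed `-log10(p)` against uniform order
#' statistics `i / (m + 1)`.
#'
#' @param pvals At least 100 p-values (a stable median needs a reasonable
#'   number of tests); zeros are clipped to the smallest positive double
#'   with a warning.
#' @return Object of class `inflation_summary`: `lambda`, `n_tests`,
#'   `qq_points` (data frame `expected`, `observed`, both `-log10` scale,
#'   sorted by expected).
#' @export
genomic_inflation <- function(pvals) {
  if (!is.numeric(pvals) || length(pvals) < 100L) {
    stop_fmt("genomic inflation needs at least 100 p-values")
  }
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop_fmt("p-values must lie in [0, 1]")
  }
  if (any(pvals == 0)) {
    warning("p-values of 0 clipped to the smallest positive double")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  chisq <- qchisq(pvals, df = 1, lower.tail = FALSE)
  lambda <- median(chisq) / qchisq(0.5, df = 1, lower.tail = FALSE)
  m <- length(pvals)
  qq <- data.frame(expected = -log10(seq_len(m) / (m + 1)),
                   observed = -log10(sort(pvals)))
  qq <- qq[order(qq$expected), ]
  rownames(qq) <- NULL
  structure(list(lambda = lambda, n_tests = m, qq_points = qq),
            class = "inflation_summary")
}

#' @export
print.inflation_summary <- function(x, ...) {
  cat(sprintf("<inflation_summary> lambda = %.3f over %d tests\n",
              x$lambda, x$n_tests))
  invisible(x)
}

#' Write the inflation summary as a TSV of QQ coordinates
#'
#' The first line is a comment carrying lambda and the number of tests.
#'
#' @param summary An [genomic_inflation()] result.
#' @param path Output path.
#' @export
write_inflation <- function(summary, path) {
  stopifnot(inherits(summary, "inflation_summary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lambda=%.6f n_tests=%d", summary$lambda,
                     summary$n_tests), con)
  write.table(summary$qq_points, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Principal components of the methylome
#'
#' Standardizes each probe's beta-values across samples and returns the
#' top `k` per-sample principal component scores, used as covariates to
#' absorb unmeasured global structure (batch effects, cell-type shifts).
#'
#' @param beta Beta matrix (probes x samples).
#' @param k Number of components (default 3).
#' @return Samples x k score matrix (rownames are sample ids).
#' @export
methylome_pca <- function(beta, k = 3) {
  beta <- as_beta_values(beta)
  k <- check_count(k, "k", min = 1L)
  sdev <- apply(beta, 1L, sd)
  variable <- sdev > 0
  if (!any(variable)) stop_fmt("all probes are constant")
  x <- t((beta[variable, , drop = FALSE] -
            rowMeans(beta[variable, , drop = FALSE])) / sdev[variable])
  n <- nrow(x)
  rank_bound <- min(n - 1L, ncol(x))
  if (k > rank_bound) {
    stop_fmt("k = %d exceeds the maximum rank %d", k, rank_bound)
  }
  if (ncol(x) > n) {
    # wide matrix: eigen-decompose the samples x samples Gram matrix
    g <- tcrossprod(x)
    e <- eigen(g, symmetric = TRUE)
    if (e$values[k] <= max(e$values) * 1e-12) {
      stop_fmt("k = %d exceeds the numerical rank of the beta matrix", k)
    }
    scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  } else {
    p <- prcomp(x, center = FALSE, scale. = FALSE)
    if (p$sdev[k] <= max(p$sdev) * 1e-8) {
      stop_fmt("k = %d exceeds the numerical rank of the beta matrix", k)
    }
    scores <- p$x[, seq_len(k), drop = FALSE]
  }
  dimnames(scores) <- list(colnames(beta), sprintf("PC%d", seq_len(k)))
  scores
}
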