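## Per-site association models: ln-CRP regressed on each probe's
## beta-values with covariate adjustment and a sibship random intercept,
## Wald inference on the methylation coefficient, sex-interaction and
## sensitivity variants, and the direction summary.

#' Natural-log transform of serum CRP
#'
#' CRP is analyzed on the natural-log scale because of its skewed
#' distribution.
#'
#' @param crp Positive CRP concentrations (mg/L).
#' @param sample_id Optional ids used in error messages.
#' @return `log(crp)`.
#' @export
ln_transform_crp <- function(crp, sample_id = NULL) {
  if (!is.numeric(crp)) stop_fmt("'crp' must be numeric")
  bad <- which(is.na(crp) | crp <= 0)
  if (length(bad)) {
    ids <- if (is.null(sample_id)) as.character(bad) else sample_id[bad]
    stop_fmt("non-positive or missing CRP for sample(s): %s",
             paste(head(ids, 5), collapse = ", "))
  }
  log(crp)
}

#' Specification of the per-site association model
#'
#' @param covariates Cohort columns adjusted for; the primary model uses
#'   age, sex, BMI and current smoking, the sensitivity model adds
#'   hypertension.
#' @param interaction Optional covariate whose interaction with the
#'   methylation exposure is tested (e.g. `"sex"`); must be among
#'   `covariates`.
#' @param random_effect Model the sibship as a random intercept (default);
#'   `FALSE` fits ordinary least squares.
#' @param pc_scores Optional samples x k matrix of methylome principal
#'   components (see [methylome_pca()]) appended to the covariates.
#' @param model_tag Label stored in the result table.
#' @return A `model_spec` list.
#' @export
model_spec <- function(covariates = c("age", "sex", "bmi", "current_smoker"),
                       interaction = NULL,
                       random_effect = TRUE,
                       pc_scores = NULL,
                       model_tag = "primary") {
  if (!is.null(interaction) && !interaction %in% covariates) {
    stop_fmt("interaction covariate '%s' must be among the covariates",
             interaction)
  }
  if (!is.null(pc_scores)) {
    stopifnot(is.matrix(pc_scores), !is.null(rownames(pc_scores)))
  }
  structure(list(covariates = covariates, interaction = interaction,
                 random_effect = isTRUE(random_effect),
                 pc_scores = pc_scores, model_tag = model_tag),
            class = "model_spec")
}

covariate_frame <- function(cohort, spec) {
  missing <- setdiff(spec$covariates, names(cohort))
  if (length(missing)) {
    stop_fmt("cohort lacks covariate column(s): %s",
             paste(missing, collapse = ", "))
  }
  covs <- cohort[spec$covariates]
  if ("sex" %in% names(covs)) covs$sex <- factor(covs$sex, levels = c("F", "M"))
  for (nm in names(covs)) {
    if (is.logical(covs[[nm]])) {
      covs[[nm]] <- as.numeric(covs[[nm]])
    } else if (is.numeric(covs[[nm]])) {
      # centre/scale continuous covariates: leaves the exposure coefficient
      # untouched and keeps the mixed-model optimizer well conditioned
      if (sd(covs[[nm]]) > 0) covs[[nm]] <- as.numeric(scale(covs[[nm]]))
    }
  }
  if (!is.null(spec$pc_scores)) {
    sc <- spec$pc_scores
    if (!all(cohort$sample_id %in% rownames(sc))) {
      stop_fmt("pc_scores do not cover all cohort samples")
    }
    sc <- sc[cohort$sample_id, , drop = FALSE]
    sc <- scale(sc)  # unit variance, same fit, better optimizer scaling
    colnames(sc) <- sprintf("mPC%d", seq_len(ncol(sc)))
    covs <- cbind(covs, as.data.frame(sc))
  }
  covs
}

degenerate_error <- function(msg) {
  structure(class = c("crpewas_degenerate", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Fit the association model for one methylation site
#'
#' Restricted-maximum-likelihood linear mixed model of `y` (ln-CRP) on the
#' site's beta-values `x` with covariates and a sibship random intercept,
#' with a Wald z-test on the methylation coefficient.  When the sibship
#' variance is estimated at the boundary (zero) or the mixed model cannot
#' be fitted (e.g. every sibship is a singleton), the site is refitted by
#' ordinary least squares, reported with `converged = FALSE` and
#' `method = "ols"` (inference then uses the usual t-test).
#'
#' @param y Outcome vector (ln-CRP).
#' @param x Exposure vector (beta-values).
#' @param covariates Data frame of covariates, or NULL.
#' @param sibship Sibship identifiers, same length as `y`.
#' @return One-row data frame: `coefficient`, `se`, `p_value`, `converged`,
#'   `method`, `sigma_sibship`, `sigma_resid`, `n_used`.
#' @export
fit_site_lmm <- function(y, x, covariates = NULL, sibship = NULL) {
  n <- length(y)
  stopifnot(length(x) == n)
  if (anyNA(y) || anyNA(x)) stop_fmt("missing values in y or x")
  if (sd(x) == 0) {
    stop(degenerate_error("constant exposure (zero variance beta-values)"))
  }
  df <- data.frame(.y = y, .x = x)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == n)
    df <- cbind(df, covariates)
  }
  rhs <- paste(c(".x", names(covariates)), collapse = " + ")

  use_lmm <- !is.null(sibship) && length(unique(sibship)) >= 2L &&
    length(unique(sibship)) < n
  if (use_lmm) {
    df$.sibship <- factor(sibship)
    fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .sibship)"))
    fit <- tryCatch(
      suppressMessages(lme4::lmer(fml, data = df, REML = TRUE,
                                  control = lme4::lmerControl(
                                    calc.derivs = FALSE,
                                    check.conv.singular = "ignore"))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      vc <- as.data.frame(lme4::VarCorr(fit))
      sigma_sib <- vc$sdcor[vc$grp == ".sibship"][1]
      if (is.finite(sigma_sib) && sigma_sib > 0) {
        est <- lme4::fixef(fit)[".x"]
        se <- sqrt(diag(as.matrix(vcov(fit)))[".x"])
        return(data.frame(
          coefficient = unname(est), se = unname(se),
          p_value = 2 * pnorm(-abs(est / se)),
          converged = TRUE, method = "lmm",
          sigma_sibship = sigma_sib,
          sigma_resid = vc$sdcor[vc$grp == "Residual"][1],
          n_used = n, row.names = NULL, stringsAsFactors = FALSE))
      }
    }
  }

  fml <- stats::as.formula(paste(".y ~", rhs))
  fit <- lm(fml, data = df)
  sm <- summary(fit)$coefficients
  if (!".x" %in% rownames(sm)) {
    stop(degenerate_error("exposure dropped from the OLS fit (collinear)"))
  }
  data.frame(
    coefficient = sm[".x", "Estimate"], se = sm[".x", "Std. Error"],
    p_value = sm[".x", "Pr(>|t|)"],
    converged = FALSE, method = "ols",
    sigma_sibship = 0, sigma_resid = summary(fit)$sigma,
    n_used = n, row.names = NULL, stringsAsFactors = FALSE)
}

align_beta_cohort <- function(beta, cohort) {
  beta <- as_beta_values(beta)
  if (!all(cohort$sample_id %in% colnames(beta))) {
    stop_fmt("beta matrix lacks %d cohort sample(s)",
             sum(!cohort$sample_id %in% colnames(beta)))
  }
  beta[, cohort$sample_id, drop = FALSE]
}

#' Epigenome-wide association scan
#'
#' Fits [fit_site_lmm()] for every probe of the beta matrix.  Per-site
#' failures (constant exposure, collinearity) are collected and reported,
#' never aborting the scan.
#'
#' @param beta Beta-value matrix (probes x samples) or [compute_beta()]
#'   result; columns must cover the cohort's samples.
#' @param cohort Cohort table with `crp`, `sibship_id` and the covariates.
#' @param spec A [model_spec()].
#' @param probes Optional probe subset to scan.
#' @param verbose Log progress every 1000 probes.
#' @return Association data frame, one row per scanned probe: `probe_id`,
#'   `coefficient`, `se`, `p_value`, `q_value` (NA until
#'   [annotate_qvalues()]), `n_used`, `model_tag`, `converged`,
#'   `sigma_sibship`, `sigma_resid`, `method`.  Skipped probes are in
#'   attribute `"skipped"` (probe_id, reason).
#' @export
run_ewas <- function(beta, cohort, spec = model_spec(), probes = NULL,
                     verbose = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  cohort <- validate_cohort(cohort)
  beta <- align_beta_cohort(beta, cohort)
  if (!is.null(probes)) {
    missing <- setdiff(probes, rownames(beta))
    if (length(missing)) {
      stop_fmt("probe(s) absent from beta matrix: %s",
               paste(head(missing, 3), collapse = ", "))
    }
    beta <- beta[probes, , drop = FALSE]
  }
  y <- ln_transform_crp(cohort$crp, cohort$sample_id)
  covs <- covariate_frame(cohort, spec)
  sib <- if (spec$random_effect) cohort$sibship_id else NULL

  ids <- rownames(beta)
  rows <- vector("list", length(ids))
  skipped <- list()
  for (i in seq_along(ids)) {
    res <- tryCatch(fit_site_lmm(y, beta[i, ], covs, sib),
                    crpewas_degenerate = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(probe_id = ids[i], reason = res, stringsAsFactors = FALSE)
    } else {
      res$probe_id <- ids[i]
      rows[[i]] <- res
    }
    if (verbose && i %% 1000 == 0) {
      message(sprintf("ewas: %d / %d probes", i, length(ids)))
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(probe_id = character(), coefficient = numeric(),
                      se = numeric(), p_value = numeric(),
                      converged = logical(), method = character(),
                      sigma_sibship = numeric(), sigma_resid = numeric(),
                      n_used = integer(), stringsAsFactors = FALSE)
  }
  out$q_value <- NA_real_
  out$model_tag <- spec$model_tag
  out <- out[c("probe_id", "coefficient", "se", "p_value", "q_value",
               "n_used", "model_tag", "converged", "sigma_sibship",
               "sigma_resid", "method")]
  rownames(out) <- NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(probe_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  if (verbose && nrow(skipped)) {
    message(sprintf("ewas: skipped %d degenerate probe(s)", nrow(skipped)))
  }
  structure(out, skipped = skipped)
}

#' Sex-methylation interaction test
#'
#' Adds an interaction between the methylation exposure and one covariate
#' (by default sex) to the adjusted model and reports the Wald p-value of
#' the interaction coefficient per probe.  Intended for the subset of
#' probes that reached significance in the main scan.
#'
#' @param beta Beta matrix.
#' @param cohort Cohort table; both sexes must be present when the
#'   interaction covariate is sex.
#' @param probes Probe subset to test (typically the significant sites).
#' @param spec A [model_spec()] with `interaction` set (default sex, kept
#'   random effect).
#' @return Association data frame where `coefficient`, `se` and `p_value`
#'   describe the interaction term; `model_tag` is `"interaction"`.
#' @export
fit_interaction <- function(beta, cohort, probes,
                            spec = model_spec(interaction = "sex",
                                              model_tag = "interaction")) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(spec$interaction)) {
    stop_fmt("the model spec must name an interaction covariate")
  }
  cohort <- validate_cohort(cohort)
  if (spec$interaction == "sex" && length(unique(cohort$sex)) < 2L) {
    stop_fmt("sex interaction needs both sexes in the cohort")
  }
  beta <- align_beta_cohort(beta, cohort)
  missing <- setdiff(probes, rownames(beta))
  if (length(missing)) {
    stop_fmt("probe(s) absent from beta matrix: %s",
             paste(head(missing, 3), collapse = ", "))
  }
  y <- ln_transform_crp(cohort$crp, cohort$sample_id)
  covs <- covariate_frame(cohort, spec)
  sib <- if (spec$random_effect) factor(cohort$sibship_id) else NULL
  int_col <- spec$interaction

  rows <- lapply(probes, function(pid) {
    df <- cbind(data.frame(.y = y, .x = beta[pid, ]), covs)
    rhs <- paste(c(".x", names(covs),
                   sprintf(".x:%s", int_col)), collapse = " + ")
    use_lmm <- !is.null(sib) && nlevels(sib) >= 2L && nlevels(sib) < nrow(df)
    est <- se <- NA_real_
    method <- "ols"
    if (use_lmm) {
      df$.sibship <- sib
      fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .sibship)"))
      fit <- tryCatch(
        suppressMessages(lme4::lmer(fml, data = df, REML = TRUE,
                                    control = lme4::lmerControl(
                                      calc.derivs = FALSE,
                                      check.conv.singular = "ignore"))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        fe <- lme4::fixef(fit)
        nm <- grep("^\\.x:", names(fe), value = TRUE)[1]
        if (!is.na(nm)) {
          est <- unname(fe[nm])
          se <- sqrt(diag(as.matrix(vcov(fit)))[nm])
          method <- "lmm"
        }
      }
    }
    if (method == "ols") {
      fit <- lm(stats::as.formula(paste(".y ~", rhs)), data = df)
      sm <- summary(fit)$coefficients
      nm <- grep("^\\.x:", rownames(sm), value = TRUE)[1]
      if (is.na(nm)) stop_fmt("interaction term missing for probe %s", pid)
      est <- sm[nm, "Estimate"]
      se <- sm[nm, "Std. Error"]
    }
    data.frame(probe_id = pid, coefficient = est, se = unname(se),
               p_value = 2 * pnorm(-abs(est / se)), q_value = NA_real_,
               n_used = nrow(df), model_tag = spec$model_tag,
               converged = method == "lmm", sigma_sibship = NA_real_,
               sigma_resid = NA_real_, method = method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Direction summary of significant associations
#'
#' Counts how many of the significant sites have a negative methylation
#' coefficient (hypomethylation with higher CRP).
#'
#' @param table Association table.
#' @param significant Probe ids of the significant sites (non-empty subset
#'   of the table's probes).
#' @return List: `n_negative`, `n_total`, `percent_negative` (rounded to
#'   one decimal).
#' @export
count_direction <- function(table, significant) {
  if (length(significant) == 0L) {
    stop_fmt("the significant set is empty")
  }
  missing <- setdiff(significant, table$probe_id)
  if (length(missing)) {
    stop_fmt("significant probe(s) absent from the table: %s",
             paste(head(missing, 3), collapse = ", "))
  }
  coefs <- table$coefficient[match(significant, table$probe_id)]
  n_neg <- sum(coefs < 0)
  list(n_negative = n_neg, n_total = length(significant),
       percent_negative = round(100 * n_neg / length(significant), 1))
}
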