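## Internal replication design: split the sibship cohort into two subsets
## of mutually unrelated individuals and re-test top hits by ordinary
## regression within each subset.

#' Split sibships into two unrelated subsets
#'
#' From every sibship with at least two members, one uniformly sampled
#' sibling goes to subset 1 and a second, distinct sibling to subset 2
#' (members beyond the second stay unassigned).  Singletons are split
#' evenly at random between the subsets; with an odd singleton count the
#' leftover singleton is dropped so the subsets stay the same size.
#' Within each subset no sibship appears twice, so all members are
#' mutually unrelated.
#'
#' @param cohort Cohort table with `sample_id` and `sibship_id`.
#' @param seed Optional seed; the split is deterministic given the seed.
#' @return Object of class `split_assignment`: `subset1`, `subset2`
#'   (sample id vectors), `seed`, `dropped_singleton` (id or NULL).
#' @export
split_sibships <- function(cohort, seed = NULL) {
  stopifnot(is.data.frame(cohort),
            all(c("sample_id", "sibship_id") %in% names(cohort)))
  if (length(unique(cohort$sibship_id)) < 2L) {
    stop_fmt("the cohort must contain at least 2 sibships")
  }
  with_seed(seed, {
    members <- split(cohort$sample_id, cohort$sibship_id)
    multi <- members[lengths(members) >= 2L]
    singles <- unlist(members[lengths(members) == 1L], use.names = FALSE)

    s1 <- s2 <- character(0)
    for (sib in multi) {
      pick <- sample(sib, 2L)
      s1 <- c(s1, pick[1])
      s2 <- c(s2, pick[2])
    }
    dropped <- NULL
    if (length(singles)) {
      singles <- sample(singles)
      if (length(singles) %% 2L == 1L) {
        dropped <- singles[length(singles)]
        singles <- singles[-length(singles)]
        message(sprintf("odd singleton count: dropping '%s' to equalize subsets",
                        dropped))
      }
      half <- length(singles) / 2L
      s1 <- c(s1, singles[seq_len(half)])
      s2 <- c(s2, singles[half + seq_len(half)])
    }
    structure(list(subset1 = s1, subset2 = s2, seed = seed,
                   dropped_singleton = dropped),
              class = "split_assignment")
  })
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> %d + %d unrelated individuals\n",
              length(x$subset1), length(x$subset2)))
  invisible(x)
}

#' Write or read a split assignment as TSV (sample_id, subset)
#'
#' @param split A [split_sibships()] result.
#' @param path File path.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "split_assignment"))
  df <- data.frame(
    sample_id = c(split$subset1, split$subset2),
    subset = rep(c("subset1", "subset2"),
                 c(length(split$subset1), length(split$subset2))),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Re-test top association hits in the two unrelated subsets
#'
#' Within each subset, ln-CRP is regressed on each hit probe's beta-values
#' with the same covariates as the pooled analysis, by ordinary least
#' squares (the subsets contain no relatives, so no random effect is
#' needed).  A hit replicates in a subset when its p-value is below
#' `alpha / k` with `k = length(hits)`.
#'
#' @param beta Beta matrix covering both subsets.
#' @param cohort Cohort table.
#' @param split A [split_sibships()] assignment over this cohort.
#' @param hits Probe ids to re-test (e.g. the top 30 sites by p-value).
#' @param alpha Nominal level before the per-test correction (default
#'   0.05, giving 0.05/30 = 1.67e-3 for 30 hits).
#' @param covariates Covariate set (defaults to the primary model's).
#' @return List: `verdicts` (data frame probe_id, coefficient and p per
#'   subset, `verdict` in both/one/neither, `sign_concordant`),
#'   `subset1`, `subset2` (per-subset association tables),
#'   `threshold` (= alpha / k).
#' @export
replicate_top_hits <- function(beta, cohort, split, hits, alpha = 0.05,
                               covariates = c("age", "sex", "bmi",
                                              "current_smoker")) {
  stopifnot(inherits(split, "split_assignment"))
  beta <- as_beta_values(beta)
  missing <- setdiff(hits, rownames(beta))
  if (length(missing)) {
    stop_fmt("hit probe(s) absent from beta matrix: %s",
             paste(head(missing, 3), collapse = ", "))
  }
  if (length(hits) == 0L) stop_fmt("'hits' must be non-empty")
  threshold <- alpha / length(hits)

  fit_subset <- function(ids, tag) {
    sub <- cohort[cohort$sample_id %in% ids, , drop = FALSE]
    spec <- model_spec(covariates = covariates, random_effect = FALSE,
                       model_tag = tag)
    run_ewas(beta[, sub$sample_id, drop = FALSE], sub, spec = spec,
             probes = hits, verbose = FALSE)
  }
  t1 <- fit_subset(split$subset1, "subset1")
  t2 <- fit_subset(split$subset2, "subset2")

  i1 <- match(hits, t1$probe_id)
  i2 <- match(hits, t2$probe_id)
  p1 <- t1$p_value[i1]
  p2 <- t2$p_value[i2]
  c1 <- t1$coefficient[i1]
  c2 <- t2$coefficient[i2]
  n_sig <- (p1 < threshold) + (p2 < threshold)
  verdicts <- data.frame(
    probe_id = hits,
    coefficient1 = c1, p1 = p1,
    coefficient2 = c2, p2 = p2,
    verdict = c("neither", "one", "both")[n_sig + 1L],
    sign_concordant = sign(c1) == sign(c2),
    stringsAsFactors = FALSE
  )
  list(verdicts = verdicts, subset1 = t1, subset2 = t2,
       threshold = threshold)
}
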