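#!/usr/bin/env Rscript
# Stage 4: the primary sibship-aware EWAS of lnCRP, the Bonferroni
# threshold, the direction summary, a hypertension sensitivity model on
# the top sites, and the sex-interaction screen.

source("analysis/00_config.R")
ensure_dirs()

beta <- crpewas:::read_matrix_tsv(require_stage(file.path(DATA_DIR,
                                                          "beta.tsv"),
                                                "03_normalize.R"))
cohort <- read_cohort(file.path(DATA_DIR, "cohort.tsv"))
cohort <- cohort[cohort$sample_id %in% colnames(beta), ]
truth <- read.delim(file.path(DATA_DIR, "truth_planted.tsv"),
                    stringsAsFactors = FALSE)

message(sprintf("primary model: lnCRP ~ beta + age + sex + bmi + smoking + (1 | sibship), n = %d",
                nrow(cohort)))
ewas <- run_ewas(beta, cohort, spec = model_spec())
ewas <- annotate_qvalues(ewas)
ewas <- ewas[order(ewas$p_value), ]

threshold <- bonferroni_threshold(0.05, nrow(ewas))
sig <- ewas$probe_id[ewas$p_value < threshold]
message(sprintf("Bonferroni nominal threshold for %d tests: %.3g",
                nrow(ewas), threshold))
message(sprintf("%d site(s) reach epigenome-wide significance", length(sig)))
message(sprintf("%d of %d planted sites are among the significant ones",
                sum(truth$probe_id %in% sig), nrow(truth)))

if (length(sig)) {
  dir_sum <- count_direction(ewas, sig)
  message(sprintf("%.1f%% of significant sites (%d of %d) are hypomethylated with higher CRP",
                  dir_sum$percent_negative, dir_sum$n_negative,
                  dir_sum$n_total))
}

infl <- genomic_inflation(ewas$p_value)
message(sprintf("genomic inflation factor of the primary scan: %.3f",
                infl$lambda))

top30 <- head(ewas$probe_id, 30)
message("refitting the top 30 sites with hypertension added (sensitivity model)")
sens <- run_ewas(beta, cohort, probes = top30, verbose = FALSE,
                 spec = model_spec(covariates = c("age", "sex", "bmi",
                                                  "current_smoker",
                                                  "hypertension"),
                                   model_tag = "sensitivity_htn"))
r2 <- cor(ewas$coefficient[match(top30, ewas$probe_id)] /
            ewas$se[match(top30, ewas$probe_id)],
          sens$coefficient / sens$se)^2
message(sprintf("test statistics with vs without hypertension: R^2 = %.3f", r2))

message("screening the significant sites for sex-methylation interactions")
inter <- fit_interaction(beta, cohort,
                         probes = if (length(sig)) sig else top30)
min_p <- min(inter$p_value)
n_int <- nrow(inter)
message(sprintf("smallest interaction p-value: %.3g (threshold %.3g): %s",
                min_p, 0.05 / n_int,
                if (min_p < 0.05 / n_int) "significant" else
                  "no significant sex-specific effects"))

write_association(ewas, file.path(DATA_DIR, "ewas_primary.tsv"))
write_association(sens, file.path(DATA_DIR, "ewas_sensitivity.tsv"))
write_association(inter, file.path(DATA_DIR, "ewas_interaction.tsv"))
top <- head(ewas, 100)
top$planted <- top$probe_id %in% truth$probe_id
write.table(top, file.path(RESULTS_DIR, "04_ewas_top100.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
qq <- infl$qq_points[round(seq(1, nrow(infl$qq_points), length.out = 400)), ]
writeLines(c(sprintf("# lambda=%.4f n_tests=%d n_significant=%d",
                     infl$lambda, infl$n_tests, length(sig))),
           file.path(RESULTS_DIR, "04_qq_primary.tsv"))
suppressWarnings(write.table(qq, file.path(RESULTS_DIR, "04_qq_primary.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE,
                             append = TRUE))
message("wrote EWAS outputs")
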