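#!/usr/bin/env Rscript
# Stage 1: generate the synthetic sibship cohort and write the TSV inputs
# that the rest of the pipeline consumes.

source("analysis/00_config.R")
ensure_dirs()

cfg <- pipeline_config()
message("simulating cohort: ", cfg$n_sibships, " sibships, ",
        cfg$n_probes, " probes")
ds <- simulate_cohort(cfg)

message(sprintf("cohort: %d individuals, %.1f%% female, mean sibship size %.2f",
                nrow(ds$cohort), 100 * mean(ds$cohort$sex == "F"),
                mean_sibship_size(ds$cohort)))
message(sprintf("median CRP: %.2f mg/L (F) / %.2f mg/L (M)",
                median(ds$cohort$crp[ds$cohort$sex == "F"]),
                median(ds$cohort$crp[ds$cohort$sex == "M"])))
message(sprintf("planted: %d CRP-associated sites, %d multimodal probes, %d bad samples",
                nrow(ds$truth$planted), length(ds$truth$multimodal_probes),
                length(ds$truth$bad_samples)))

write_dataset(ds, DATA_DIR)
# chip assignment is part of the truth; kept for the normalization check
write.table(data.frame(sample_id = names(ds$truth$chip),
                       chip = ds$truth$chip),
            file.path(DATA_DIR, "chips.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

pheno <- ds$cohort
summary_tab <- do.call(rbind, lapply(c("F", "M"), function(s) {
  sub <- pheno[pheno$sex == s, ]
  data.frame(sex = s, n = nrow(sub),
             age_mean = round(mean(sub$age), 2),
             age_sd = round(sd(sub$age), 2),
             bmi_mean = round(mean(sub$bmi), 2),
             bmi_sd = round(sd(sub$bmi), 2),
             crp_median = round(median(sub$crp), 2),
             crp_q1 = round(quantile(sub$crp, 0.25), 2),
             crp_q3 = round(quantile(sub$crp, 0.75), 2),
             hypertensive = round(100 * mean(sub$hypertension), 1))
}))
write.table(summary_tab, file.path(RESULTS_DIR, "01_cohort_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", file.path(RESULTS_DIR, "01_cohort_summary.tsv"))
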