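#!/usr/bin/env Rscript
# Stage 6: internal replication: split the sibships into two unrelated
# subsets and re-test the top 30 sites in each by ordinary regression.

source("analysis/00_config.R")
ensure_dirs()

beta <- crpewas:::read_matrix_tsv(require_stage(file.path(DATA_DIR,
                                                          "beta.tsv"),
                                                "03_normalize.R"))
cohort <- read_cohort(file.path(DATA_DIR, "cohort.tsv"))
cohort <- cohort[cohort$sample_id %in% colnames(beta), ]
primary <- read_association(require_stage(
  file.path(DATA_DIR, "ewas_primary.tsv"), "04_ewas.R"))

split <- split_sibships(cohort, seed = PIPELINE_SEED + 6)
message(sprintf("split: %d + %d mutually unrelated individuals",
                length(split$subset1), length(split$subset2)))

top30 <- head(primary$probe_id[order(primary$p_value)], 30)
rep <- replicate_top_hits(beta, cohort, split, top30)
message(sprintf("per-test threshold for 30 hits: %.3g", rep$threshold))
tab <- table(factor(rep$verdicts$verdict,
                    levels = c("both", "one", "neither")))
message(sprintf("replication verdicts: both=%d, one=%d, neither=%d",
                tab["both"], tab["one"], tab["neither"]))
message(sprintf("%d of %d top sites significant in at least one subset; %d in both",
                sum(rep$verdicts$verdict != "neither"), nrow(rep$verdicts),
                tab["both"]))
message(sprintf("coefficient signs concordant between subsets for %d of %d sites",
                sum(rep$verdicts$sign_concordant), nrow(rep$verdicts)))

write_split(split, file.path(DATA_DIR, "split_assignment.tsv"))
write.table(rep$verdicts, file.path(RESULTS_DIR, "06_replication.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", file.path(RESULTS_DIR, "06_replication.tsv"))
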