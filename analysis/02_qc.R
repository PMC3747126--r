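#!/usr/bin/env Rscript
# Stage 2: sample QC on control probes, dip-test filtering, site filters.

source("analysis/00_config.R")
ensure_dirs()

ints <- read_intensities(require_stage(file.path(DATA_DIR, "methylated.tsv"),
                                       "01_simulate.R"),
                         file.path(DATA_DIR, "unmethylated.tsv"))
controls <- read_controls(file.path(DATA_DIR, "controls.tsv"))
manifest <- read_manifest(file.path(DATA_DIR, "manifest.tsv"))

qc <- run_qc(ints, controls, manifest, k_sd = 4, dip_alpha = 0.001,
             n_boot = 2000, seed = PIPELINE_SEED + 1)

message(sprintf("excluded %d sample(s) on control-probe outliers",
                nrow(qc$report$excluded_samples)))
tab <- table(qc$report$flagged_sites$reason)
message("flagged sites: ",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
message(sprintf("%d sites enter the association analysis",
                qc$report$n_sites_tested))

write.table(qc$report$excluded_samples,
            file.path(RESULTS_DIR, "02_excluded_samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(qc$report$flagged_sites,
            file.path(DATA_DIR, "flagged_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(qc$report$kept, file.path(DATA_DIR, "kept_probes.txt"))
writeLines(qc$kept_samples, file.path(DATA_DIR, "kept_samples.txt"))
write.table(as.data.frame(tab),
            file.path(RESULTS_DIR, "02_flagged_site_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote QC outputs")
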