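#!/usr/bin/env Rscript
# Stage 3: control-probe PCA normalization and beta-value computation.

source("analysis/00_config.R")
ensure_dirs()

ints <- read_intensities(require_stage(file.path(DATA_DIR, "methylated.tsv"),
                                       "01_simulate.R"),
                         file.path(DATA_DIR, "unmethylated.tsv"))
controls <- read_controls(file.path(DATA_DIR, "controls.tsv"))
kept_samples <- readLines(require_stage(file.path(DATA_DIR,
                                                  "kept_samples.txt"),
                                        "02_qc.R"))
kept_probes <- readLines(file.path(DATA_DIR, "kept_probes.txt"))

ints <- intensity_pair(ints$methylated[kept_probes, kept_samples],
                       ints$unmethylated[kept_probes, kept_samples])
controls <- controls[, kept_samples]

pca <- orthogonalize_controls(controls)
message(sprintf("control PCA kept %d orthogonal component(s); PC1 explains %.1f%% of control variance",
                pca$k, 100 * pca$explained_variance[1]))

norm <- regress_out_controls(ints, pca)

# how much of the between-chip variance did normalization remove?
chips <- read.delim(file.path(DATA_DIR, "chips.tsv"))
chip <- factor(chips$chip[match(kept_samples, chips$sample_id)])
n_per <- as.numeric(table(chip))
chip_var <- function(mat) {
  v <- log(mat + 1)
  sum(apply(v, 1, function(row) {
    gm <- tapply(row, chip, mean)
    msb <- sum(n_per * (gm - mean(row))^2) / (nlevels(chip) - 1)
    msw <- sum((row - gm[chip])^2) / (length(row) - nlevels(chip))
    max((msb - msw) / mean(n_per), 0)
  }))
}
reduction <- 1 - chip_var(norm$methylated) / chip_var(ints$methylated)
message(sprintf("normalization removed %.1f%% of the between-chip intensity variance",
                100 * reduction))

beta <- compute_beta(norm, alpha = 100)
message(sprintf("beta matrix: %d probes x %d samples, mean beta %.3f",
                nrow(beta), ncol(beta), mean(beta)))

write_intensities(norm, file.path(DATA_DIR, "methylated_norm.tsv"),
                  file.path(DATA_DIR, "unmethylated_norm.tsv"))
crpewas:::write_matrix_tsv(unclass(beta), file.path(DATA_DIR, "beta.tsv"))

pc_summary <- data.frame(component = seq_len(pca$k),
                         eigenvalue = round(pca$eigenvalues, 3),
                         explained = round(pca$explained_variance, 4))
pc_summary$chip_variance_removed <- c(round(reduction, 4),
                                      rep(NA, pca$k - 1))
write.table(pc_summary, file.path(RESULTS_DIR, "03_control_pca.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", file.path(RESULTS_DIR, "03_control_pca.tsv"))
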