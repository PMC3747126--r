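#!/usr/bin/env Rscript
# Stage 5: methylome principal components as covariates: the PC-adjusted
# scan, its FDR q-values, and the inflation comparison with the primary
# analysis.

source("analysis/00_config.R")
ensure_dirs()

beta <- crpewas:::read_matrix_tsv(require_stage(file.path(DATA_DIR,
                                                          "beta.tsv"),
                                                "03_normalize.R"))
cohort <- read_cohort(file.path(DATA_DIR, "cohort.tsv"))
cohort <- cohort[cohort$sample_id %in% colnames(beta), ]
primary <- read_association(require_stage(
  file.path(DATA_DIR, "ewas_primary.tsv"), "04_ewas.R"))

message("computing the top 3 principal components of the methylome")
pcs <- methylome_pca(beta, k = 3)

message("rerunning the scan with the methylome PCs as covariates")
adj <- run_ewas(beta, cohort,
                spec = model_spec(pc_scores = pcs,
                                  model_tag = "pc_adjusted"))
adj <- annotate_qvalues(adj)
adj <- adj[order(adj$p_value), ]

lam0 <- genomic_inflation(primary$p_value)$lambda
infl <- genomic_inflation(adj$p_value)
message(sprintf("inflation factor: %.3f (primary) -> %.3f (PC-adjusted)",
                lam0, infl$lambda))
n_fdr <- sum(adj$q_value < 0.05)
message(sprintf("%d site(s) at FDR q < 0.05 after PC adjustment", n_fdr))
if (n_fdr) {
  show <- head(adj[adj$q_value < 0.05,
                   c("probe_id", "coefficient", "p_value", "q_value")], 5)
  for (i in seq_len(nrow(show))) {
    message(sprintf("  %s: beta = %.2f, p = %.3g, q = %.3f",
                    show$probe_id[i], show$coefficient[i],
                    show$p_value[i], show$q_value[i]))
  }
}

write_association(adj, file.path(DATA_DIR, "ewas_pc_adjusted.tsv"))
top <- head(adj, 100)
write.table(top, file.path(RESULTS_DIR, "05_pc_adjusted_top100.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
qq <- infl$qq_points[round(seq(1, nrow(infl$qq_points), length.out = 400)), ]
writeLines(sprintf("# lambda_primary=%.4f lambda_pc_adjusted=%.4f n_fdr05=%d",
                   lam0, infl$lambda, n_fdr),
           file.path(RESULTS_DIR, "05_qq_pc_adjusted.tsv"))
suppressWarnings(write.table(qq,
                             file.path(RESULTS_DIR, "05_qq_pc_adjusted.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE,
                             append = TRUE))
message("wrote PC-adjusted outputs")
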