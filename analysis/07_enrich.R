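#!/usr/bin/env Rscript
# Stage 7: gene-set over-representation among the genes carrying the
# significant sites.  The annotation is synthetic: one "inflammation"
# term enriched for genes hit by planted sites plus random terms, so the
# expected outcome (the enriched term at the top) is known.

source("analysis/00_config.R")
ensure_dirs()

manifest <- read_manifest(require_stage(file.path(DATA_DIR, "manifest.tsv"),
                                        "01_simulate.R"))
primary <- read_association(require_stage(
  file.path(DATA_DIR, "ewas_primary.tsv"), "04_ewas.R"))
truth <- read.delim(file.path(DATA_DIR, "truth_planted.tsv"),
                    stringsAsFactors = FALSE)

threshold <- bonferroni_threshold(0.05, nrow(primary))
sig <- primary$probe_id[primary$p_value < threshold]
if (length(sig) < 5) sig <- head(primary$probe_id[order(primary$p_value)], 30)
query <- map_sites_to_genes(sig, manifest)
background <- setdiff(unique(manifest$gene), "")
message(sprintf("%d significant site(s) map to %d unique gene(s) (background %d)",
                length(sig), length(query), length(background)))

# synthetic annotation: an inflammation-like term seeded with planted genes
set.seed(PIPELINE_SEED + 7)
planted_genes <- map_sites_to_genes(truth$probe_id, manifest)
terms <- c(
  list(list(term_id = "TERM:0001", term_name = "inflammatory response (planted)",
            genes = unique(c(planted_genes,
                             sample(background, 40))))),
  lapply(2:25, function(i) {
    list(term_id = sprintf("TERM:%04d", i),
         term_name = sprintf("random process %d", i),
         genes = sample(background, sample(20:80, 1)))
  })
)
ann_path <- file.path(DATA_DIR, "annotations.tsv")
ann_df <- do.call(rbind, lapply(terms, function(t) {
  data.frame(term_id = t$term_id, gene = t$genes, term_name = t$term_name)
}))
write.table(ann_df, ann_path, sep = "\t", quote = FALSE, row.names = FALSE)
terms <- read_annotations(ann_path)

res <- hypergeometric_enrichment(query, background, terms)
message("top over-represented terms:")
for (i in seq_len(min(5, nrow(res)))) {
  message(sprintf("  %s (%s): overlap %d of %d, p = %.3g",
                  res$term_id[i], res$term_name[i], res$overlap[i],
                  res$n_genes[i], res$p_value[i]))
}

write.table(res, file.path(RESULTS_DIR, "07_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", file.path(RESULTS_DIR, "07_enrichment.tsv"))
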