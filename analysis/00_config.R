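# Shared settings for the analysis workflow.
#
# The synthetic cohort mirrors the study design at full sample size
# (492 sibships, 966 individuals) with the probe dimension scaled to 3,000
# sites so that a complete run of scripts 01-07 finishes in minutes; the
# per-category probe counts keep the array's proportions.  Large
# intermediate matrices are kept under scratch/ and only summary tables are
# written to results/.

suppressPackageStartupMessages(library(crpewas))

PIPELINE_SEED <- 20130819
N_PROBES <- 3000L

DATA_DIR <- "scratch/pipeline"
RESULTS_DIR <- "results"

pipeline_config <- function() {
  sim_config(
    sibship_sizes = study_sibship_sizes(),
    n_probes = N_PROBES,
    n_xy_probes = round(1118 / 27578 * N_PROBES),        # 122
    n_crossreactive = round(2984 / 27578 * N_PROBES),    # 325
    n_snp_overlap = round(875 / 27578 * N_PROBES),       # 95
    n_multimodal_probes = 30,
    n_bad_samples = 49,
    confounder = list(crp_effect = 0.25),  # mild unmeasured confounding
    seed = PIPELINE_SEED
  )
}

require_stage <- function(path, script) {
  if (!file.exists(path)) {
    stop(sprintf("missing '%s': run analysis/%s first", path, script),
         call. = FALSE)
  }
  path
}

ensure_dirs <- function() {
  dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)
  dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
}
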