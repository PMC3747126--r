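## Readers and writers for the tab-delimited formats the pipeline consumes:
## intensity matrices, control-probe matrices, probe manifests, cohort
## phenotype tables, association results, and YAML analysis configurations.
## All writers are lossless for their readers.

read_matrix_tsv <- function(path, what = "matrix") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "probe_id") {
    stop_fmt("%s file '%s' must have 'probe_id' as its first column",
             what, path)
  }
  if (anyDuplicated(df$probe_id)) {
    stop_fmt("duplicate probe_id in '%s'", path)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_fmt("non-numeric values in '%s'", path)
  rownames(m) <- df$probe_id
  m
}

write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated methylated/unmethylated intensity pair
#'
#' @param methylated,unmethylated Non-negative numeric matrices (probes x
#'   samples) with identical dimnames.
#' @return A list of the two aligned matrices, class `intensity_pair`.
#' @export
intensity_pair <- function(methylated, unmethylated) {
  stopifnot(is.matrix(methylated), is.matrix(unmethylated))
  if (!identical(dim(methylated), dim(unmethylated))) {
    stop_fmt("methylated and unmethylated matrices differ in shape")
  }
  if (is.null(rownames(methylated)) || is.null(colnames(methylated))) {
    stop_fmt("intensity matrices need probe rownames and sample colnames")
  }
  if (!setequal(rownames(methylated), rownames(unmethylated)) ||
      !setequal(colnames(methylated), colnames(unmethylated))) {
    stop_fmt("methylated and unmethylated matrices cover different probes or samples")
  }
  unmethylated <- unmethylated[rownames(methylated), colnames(methylated),
                               drop = FALSE]
  if (min(methylated) < 0 || min(unmethylated) < 0) {
    stop_fmt("negative intensity values are not allowed")
  }
  structure(list(methylated = methylated, unmethylated = unmethylated),
            class = "intensity_pair")
}

#' Read a methylated/unmethylated intensity pair from TSV files
#'
#' Both files are tab-delimited with a `probe_id` first column and one
#' column per sample.  The two files must cover identical probe and sample
#' sets; sample column order may differ and is aligned.
#'
#' @param path_methylated,path_unmethylated File paths.
#' @return An [intensity_pair()].
#' @export
read_intensities <- function(path_methylated, path_unmethylated) {
  m <- read_matrix_tsv(path_methylated, "methylated intensity")
  u <- read_matrix_tsv(path_unmethylated, "unmethylated intensity")
  if (!setequal(rownames(m), rownames(u))) {
    stop_fmt("probe sets differ between '%s' and '%s'",
             path_methylated, path_unmethylated)
  }
  if (!setequal(colnames(m), colnames(u))) {
    stop_fmt("sample sets differ between '%s' and '%s'",
             path_methylated, path_unmethylated)
  }
  intensity_pair(m, u[rownames(m), colnames(m), drop = FALSE])
}

#' Write an intensity pair to two TSV files
#'
#' @param intensities An [intensity_pair()].
#' @param path_methylated,path_unmethylated Output paths.
#' @export
write_intensities <- function(intensities, path_methylated,
                              path_unmethylated) {
  stopifnot(inherits(intensities, "intensity_pair"))
  write_matrix_tsv(intensities$methylated, path_methylated)
  write_matrix_tsv(intensities$unmethylated, path_unmethylated)
  invisible(NULL)
}

#' Read or write a control-probe matrix (features x samples)
#'
#' @param path File path.
#' @return Numeric matrix with control features as rows.
#' @export
read_controls <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "control_id") {
    stop_fmt("control file '%s' must have 'control_id' as its first column",
             path)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$control_id
  m
}

#' @rdname read_controls
#' @param controls Control matrix to write.
#' @export
write_controls <- function(controls, path) {
  write_matrix_tsv(controls, path, id_col = "control_id")
}

manifest_columns <- c("probe_id", "chromosome", "position", "strand",
                      "gene", "crossreactive_flag", "snp_overlap_flag")
allowed_chromosomes <- c(as.character(1:22), "X", "Y")

#' Read a probe manifest
#'
#' Required columns: `probe_id`, `chromosome` (1-22, X, Y), `position`
#' (1-based bp), `strand` (+/-), `gene` (symbol, may be empty),
#' `crossreactive_flag`, `snp_overlap_flag` (logical/0-1).
#'
#' @param path File path.
#' @return Validated manifest data frame.
#' @export
read_manifest <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(manifest_columns, header)
  if (length(missing)) {
    stop_fmt("manifest '%s' is missing column(s): %s", path,
             paste(missing, collapse = ", "))
  }
  # gene symbols stay literal strings ("T", "NA" are legitimate symbols)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(gene = "character"), na.strings = NULL)
  df <- df[manifest_columns]
  validate_manifest(df, path)
}

validate_manifest <- function(df, label = "manifest") {
  if (anyDuplicated(df$probe_id)) {
    stop_fmt("duplicate probe_id in %s", label)
  }
  df$chromosome <- as.character(df$chromosome)
  if (!all(df$chromosome %in% allowed_chromosomes)) {
    stop_fmt("%s contains chromosomes outside 1-22, X, Y", label)
  }
  if (any(df$position <= 0)) stop_fmt("%s has non-positive positions", label)
  df$strand <- gsub("−", "-", df$strand)  # unicode minus
  if (!all(df$strand %in% c("+", "-"))) {
    stop_fmt("%s strand must be '+' or '-'", label)
  }
  df$gene[is.na(df$gene)] <- ""
  df$crossreactive_flag <- as.logical(df$crossreactive_flag)
  df$snp_overlap_flag <- as.logical(df$snp_overlap_flag)
  df
}

#' @rdname read_manifest
#' @param manifest Manifest data frame to write.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest[manifest_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

cohort_columns <- c("sample_id", "sibship_id", "age", "sex", "bmi",
                    "current_smoker", "hypertension", "crp")

#' Read a cohort phenotype table
#'
#' Required columns: `sample_id`, `sibship_id`, `age` (years), `sex` (M/F),
#' `bmi` (kg/m^2), `current_smoker`, `hypertension` (logical/0-1), `crp`
#' (mg/L, positive).
#'
#' @param path File path.
#' @param drop_incomplete Drop samples with missing modelled covariates or
#'   non-positive CRP instead of failing; the number dropped is reported
#'   with a message.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path, drop_incomplete = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_columns, names(df))
  if (length(missing)) {
    stop_fmt("cohort '%s' is missing column(s): %s", path,
             paste(missing, collapse = ", "))
  }
  df <- df[union(cohort_columns, names(df))]
  validate_cohort(df, path, drop_incomplete = drop_incomplete)
}

validate_cohort <- function(df, label = "cohort", drop_incomplete = FALSE) {
  if (anyDuplicated(df$sample_id)) {
    stop_fmt("duplicate sample_id in %s", label)
  }
  if (!all(df$sex %in% c("M", "F"))) {
    stop_fmt("%s sex must be 'M' or 'F'", label)
  }
  df$current_smoker <- as.logical(df$current_smoker)
  df$hypertension <- as.logical(df$hypertension)
  modelled <- c("age", "sex", "bmi", "current_smoker", "hypertension", "crp")
  complete <- complete.cases(df[modelled]) & df$crp > 0
  if (!all(complete)) {
    if (!drop_incomplete) {
      stop_fmt("%s has %d sample(s) with missing covariates or non-positive CRP",
               label, sum(!complete))
    }
    message(sprintf("dropping %d sample(s) with incomplete phenotypes",
                    sum(!complete)))
    df <- df[complete, , drop = FALSE]
  }
  df
}

#' @rdname read_cohort
#' @param cohort Cohort data frame to write.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

association_columns <- c("probe_id", "coefficient", "se", "p_value",
                         "q_value", "n_used", "model_tag", "converged",
                         "sigma_sibship", "sigma_resid")

#' Read or write an association result table
#'
#' @param path File path.
#' @return Association data frame (one row per probe and model tag).
#' @export
read_association <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("probe_id", "coefficient", "se", "p_value"),
                     names(df))
  if (length(missing)) {
    stop_fmt("association table '%s' is missing column(s): %s", path,
             paste(missing, collapse = ", "))
  }
  if ("converged" %in% names(df)) df$converged <- as.logical(df$converged)
  df
}

#' @rdname read_association
#' @param table Association data frame to write.
#' @export
write_association <- function(table, path) {
  keep <- intersect(association_columns, names(table))
  write.table(table[keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset as the TSV files the pipeline reads
#'
#' Emits `methylated.tsv`, `unmethylated.tsv`, `controls.tsv`,
#' `manifest.tsv`, `cohort.tsv`, and the truth sidecar
#' `truth_planted.tsv` (probe_id, coefficient) into `dir`.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(ds$intensities$methylated, file.path(dir, "methylated.tsv"))
  write_matrix_tsv(ds$intensities$unmethylated,
                   file.path(dir, "unmethylated.tsv"))
  write_controls(ds$controls, file.path(dir, "controls.tsv"))
  write_manifest(ds$manifest, file.path(dir, "manifest.tsv"))
  write_cohort(ds$cohort, file.path(dir, "cohort.tsv"))
  write.table(ds$truth$planted, file.path(dir, "truth_planted.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an analysis configuration from YAML
#'
#' The YAML mirrors the fields of [sim_config()] under a `simulation` key,
#' plus an `analysis` key with covariate list, number of methylome PCs,
#' alpha, and top-k settings.  Unknown fields are rejected.
#'
#' @param path YAML file path.
#' @return List with elements `simulation` (a `sim_config`) and `analysis`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulation %||% list()
  if (!is.null(sim$planted_effects)) {
    sim$planted_effects <- as.data.frame(sim$planted_effects)
  }
  unknown <- setdiff(names(sim), names(formals(sim_config)))
  if (length(unknown)) {
    stop_fmt("unknown simulation config field(s): %s",
             paste(unknown, collapse = ", "))
  }
  analysis_defaults <- list(
    covariates = c("age", "sex", "bmi", "current_smoker"),
    n_pcs = 3L, alpha = 0.05, top_k = 30L, beta_offset = 100,
    dip_alpha = 0.001, dip_n_boot = 2000L, qc_k_sd = 4
  )
  analysis <- utils::modifyList(analysis_defaults, raw$analysis %||% list())
  list(simulation = do.call(sim_config, sim), analysis = analysis)
}
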