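## Gene-set over-representation: map significant probes to genes through
## the manifest and test each annotation term with a one-sided
## hypergeometric test against a background gene universe.

#' Map significant probes to their annotated genes
#'
#' Probes with an empty gene field contribute nothing (the number dropped
#' is reported with a message); genes hit by several probes are counted
#' once.
#'
#' @param probes Probe ids, all present in the manifest.
#' @param manifest Probe manifest with `probe_id` and `gene` columns.
#' @return Character vector of unique, non-empty gene symbols.
#' @export
map_sites_to_genes <- function(probes, manifest) {
  missing <- setdiff(probes, manifest$probe_id)
  if (length(missing)) {
    stop_fmt("probe(s) absent from manifest: %s",
             paste(head(missing, 3), collapse = ", "))
  }
  genes <- manifest$gene[match(probes, manifest$probe_id)]
  empty <- genes == "" | is.na(genes)
  if (any(empty)) {
    message(sprintf("%d probe(s) without gene annotation dropped",
                    sum(empty)))
  }
  unique(genes[!empty])
}

#' Hypergeometric over-representation test
#'
#' For each annotation term, the one-sided upper-tail probability of
#' observing at least the seen overlap between the query gene set and the
#' term's genes, drawing `|query|` genes from the background universe.
#' Term gene sets are intersected with the background first.
#'
#' @param query Gene set of interest (must be a subset of `background`).
#' @param background Background gene universe (e.g. all genes on the
#'   tested manifest).
#' @param annotations List of terms; each element has `term_id`,
#'   `term_name` (optional) and `genes` (see [read_annotations()] /
#'   [read_gmt()]).
#' @return Data frame sorted by p-value: `term_id`, `term_name`,
#'   `n_genes` (term size within background), `overlap`, `p_value`,
#'   `q_value` (Benjamini-Hochberg across terms).
#' @export
hypergeometric_enrichment <- function(query, background, annotations) {
  query <- unique(query)
  background <- unique(background)
  if (length(query) == 0L || length(background) == 0L) {
    stop_fmt("query and background must be non-empty")
  }
  if (!all(query %in% background)) {
    stop_fmt("%d query gene(s) are not in the background",
             sum(!query %in% background))
  }
  if (length(annotations) == 0L) {
    stop_fmt("no annotation terms supplied")
  }
  ids <- vapply(annotations, function(a) a$term_id, character(1))
  if (anyDuplicated(ids)) stop_fmt("duplicate term_id in annotations")

  n_bg <- length(background)
  n_q <- length(query)
  rows <- lapply(annotations, function(a) {
    term_genes <- intersect(unique(a$genes), background)
    k <- length(intersect(term_genes, query))
    m <- length(term_genes)
    # P(X >= k) with m successes among n_bg, n_q draws
    p <- if (m == 0L) 1 else
      phyper(k - 1, m, n_bg - m, n_q, lower.tail = FALSE)
    data.frame(term_id = a$term_id,
               term_name = a$term_name %||% a$term_id,
               n_genes = m, overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_qvalues(out$p_value)
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Read term annotations from a two-column TSV
#'
#' Expects columns `term_id` and `gene` (one pair per line, with header),
#' plus an optional `term_name` column.
#'
#' @param path File path.
#' @return List of terms usable by [hypergeometric_enrichment()].
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("term_id", "gene"), names(df))
  if (length(missing)) {
    stop_fmt("annotation file '%s' is missing column(s): %s", path,
             paste(missing, collapse = ", "))
  }
  terms <- split(df, df$term_id)
  lapply(unname(terms), function(d) {
    list(term_id = d$term_id[1],
         term_name = if ("term_name" %in% names(d)) d$term_name[1] else
           d$term_id[1],
         genes = unique(d$gene))
  })
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: term id, description, then one gene per field.
#'
#' @param path File path.
#' @return List of terms usable by [hypergeometric_enrichment()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop_fmt("malformed GMT line (need id, description, >= 1 gene)")
    }
    list(term_id = parts[1], term_name = parts[2],
         genes = unique(parts[-(1:2)]))
  })
}
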