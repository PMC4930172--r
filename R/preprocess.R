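#' Filter features below a log2 intensity threshold
#'
#' Removes features whose maximum log2 intensity over all samples fails to
#' reach `threshold` (default 7). "Reach" is read as inclusive: a feature
#' whose maximum equals the threshold is retained. Row order is preserved.
#'
#' @param expr Expression tibble: first column feature ids, remaining
#'   columns numeric log2 intensities per sample.
#' @param threshold Log2 intensity cutoff (default 7).
#' @return The filtered expression tibble; empty (with a warning) when no
#'   feature passes.
#' @export
#' @examples
#' m <- tibble::tibble(feature_id = c("a", "b"), s1 = c(6.5, 8), s2 = c(6.9, 5))
#' filter_low_intensity(m)
filter_low_intensity <- function(expr, threshold = 7.0) {
  check_scalar_number(threshold, "threshold")
  x <- expr_matrix(expr)
  keep <- apply(x, 1, max) >= threshold
  if (!any(keep)) {
    warn("no feature reaches the intensity threshold; returning an empty matrix")
  }
  expr[keep, , drop = FALSE]
}

# One row per (probe_id, gene_symbol); gene_symbol NA marks an unannotated
# probe. `protein_coding` is a per-row logical.
validate_probe_map <- function(probe_map) {
  required <- c("probe_id", "gene_symbol")
  if (!all(required %in% names(probe_map))) {
    abort("probe map must have columns `probe_id` and `gene_symbol`",
          class = "ffldyn_input_error")
  }
  probe_map
}

#' Drop probes mapping to several genes or to none
#'
#' A probe annotated to two or more distinct gene symbols is ambiguous and
#' removed; probes without any gene annotation cannot contribute to a gene
#' row and are removed too.
#'
#' @param expr Probe-level expression tibble.
#' @param probe_map Tibble with columns `probe_id`, `gene_symbol` (NA for
#'   unannotated probes) and optionally `protein_coding`.
#' @return Expression tibble restricted to unambiguous, annotated probes.
#' @export
drop_multigene_probes <- function(expr, probe_map) {
  probe_map <- validate_probe_map(probe_map)
  probes <- as.character(expr[[1]])
  missing <- setdiff(probes, probe_map$probe_id)
  if (length(missing) > 0) {
    abort(paste0("probes absent from the probe map: ",
                 paste(head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) ", ..." else ""),
          class = "ffldyn_input_error")
  }
  gene_counts <- probe_map |>
    dplyr::filter(!is.na(.data$gene_symbol)) |>
    dplyr::distinct(.data$probe_id, .data$gene_symbol) |>
    dplyr::count(.data$probe_id, name = "n_genes")
  single <- gene_counts$probe_id[gene_counts$n_genes == 1L]
  expr[probes %in% single, , drop = FALSE]
}

#' Average probes into gene-level rows
#'
#' Collapses a probe-level matrix to one row per gene symbol by taking, per
#' sample, the arithmetic mean of the log2 values of all probes mapped to
#' that gene. Rows are returned sorted by gene symbol. Every probe must map
#' to exactly one gene (run [drop_multigene_probes()] first).
#'
#' @inheritParams drop_multigene_probes
#' @return Gene-level expression tibble with first column `gene`.
#' @export
collapse_to_genes <- function(expr, probe_map) {
  probe_map <- validate_probe_map(probe_map)
  map1 <- probe_map |>
    dplyr::filter(!is.na(.data$gene_symbol)) |>
    dplyr::distinct(.data$probe_id, .data$gene_symbol)
  ambiguous <- map1$probe_id[duplicated(map1$probe_id)]
  probes <- as.character(expr[[1]])
  if (any(probes %in% ambiguous)) {
    abort("multi-gene probes present; call drop_multigene_probes() first",
          class = "ffldyn_input_error")
  }
  idx <- match(probes, map1$probe_id)
  if (anyNA(idx)) {
    abort("unannotated probes present; call drop_multigene_probes() first",
          class = "ffldyn_input_error")
  }
  x <- expr_matrix(expr)
  g <- map1$gene_symbol[idx]
  sums <- rowsum(x, group = g)
  counts <- as.vector(table(g)[rownames(sums)])
  collapsed <- sums / counts
  collapsed <- collapsed[order(rownames(collapsed)), , drop = FALSE]
  expr_tibble(collapsed, id_col = "gene")
}

#' Keep protein-coding genes
#'
#' Restricts a gene-level matrix to genes flagged protein-coding in the
#' probe map. Genes without a biotype flag are treated as non-coding and
#' dropped with a message.
#'
#' @param expr Gene-level expression tibble (first column `gene`).
#' @param probe_map Probe map containing `gene_symbol` and `protein_coding`.
#' @return The restricted expression tibble.
#' @export
keep_protein_coding <- function(expr, probe_map) {
  probe_map <- validate_probe_map(probe_map)
  if (!"protein_coding" %in% names(probe_map)) {
    abort("probe map lacks a `protein_coding` column",
          class = "ffldyn_input_error")
  }
  flags <- probe_map |>
    dplyr::filter(!is.na(.data$gene_symbol)) |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(protein_coding = any(.data$protein_coding %in% TRUE),
                     .groups = "drop")
  genes <- as.character(expr[[1]])
  flag <- flags$protein_coding[match(genes, flags$gene_symbol)]
  flag[is.na(flag)] <- FALSE
  n_unflagged <- sum(!genes %in% flags$gene_symbol)
  if (n_unflagged > 0) {
    inform(sprintf("%d gene(s) without a biotype flag treated as non-coding",
                   n_unflagged))
  }
  if (!any(flag)) {
    warn("no protein-coding genes retained; returning an empty matrix")
  }
  expr[flag, , drop = FALSE]
}

#' Full probe-level preprocessing pipeline
#'
#' Applies, in order: the intensity filter, removal of multi-gene and
#' unannotated probes, probe-to-gene averaging, and restriction to
#' protein-coding genes. Each step is idempotent.
#'
#' @inheritParams drop_multigene_probes
#' @param intensity_threshold Log2 intensity cutoff passed to
#'   [filter_low_intensity()].
#' @return Gene-level expression tibble of protein-coding genes.
#' @export
preprocess_expression <- function(expr, probe_map, intensity_threshold = 7.0) {
  expr |>
    filter_low_intensity(threshold = intensity_threshold) |>
    drop_multigene_probes(probe_map) |>
    collapse_to_genes(probe_map) |>
    keep_protein_coding(probe_map)
}
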