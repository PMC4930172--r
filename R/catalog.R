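catalog_edge_types <- c("mirna_gene", "mirna_tf", "tf_gene", "tf_mirna")

new_catalog <- function(edges, tfs, mirnas) {
  edges <- tibble::as_tibble(edges)
  attr(edges, "tfs") <- tfs
  attr(edges, "mirnas") <- sort(unique(mirnas))
  class(edges) <- c("interaction_catalog", class(edges))
  edges
}

# miRNA identifier normalization: case-fold, then apply the alias map.
normalize_mirna_ids <- function(ids, alias_map = NULL) {
  ids <- tolower(ids)
  if (!is.null(alias_map)) {
    if (!all(c("alias", "canonical") %in% names(alias_map))) {
      abort("alias map must have columns `alias` and `canonical`",
            class = "ffldyn_input_error")
    }
    idx <- match(ids, tolower(alias_map$alias))
    hit <- !is.na(idx)
    ids[hit] <- tolower(alias_map$canonical[idx[hit]])
  }
  ids
}

#' Load and merge typed regulatory interaction catalogs
#'
#' Reads one or more edge-list tables (TSV files or data frames) with
#' columns `source_id`, `target_id`, `edge_type` (one of `mirna_gene`,
#' `mirna_tf`, `tf_gene`, `tf_mirna`) and optional `evidence`. Edges are
#' merged and de-duplicated on `(source, target, type)` with evidence tags
#' concatenated. miRNA identifiers are normalized by case-folding plus an
#' optional alias map (a stand-in for mature-miRNA mapping). Identifier
#' roles are validated: an id may be both a TF and a target gene, but never
#' both a miRNA and a TF/gene.
#'
#' @param paths Character vector of TSV paths, a data frame, or a list of
#'   data frames.
#' @param tf_list Path to a one-symbol-per-line TF registry, or a character
#'   vector of TF symbols.
#' @param alias_map Optional tibble (`alias`, `canonical`) applied to miRNA
#'   ids after case-folding.
#' @return An `interaction_catalog` tibble with attributes `tfs` and
#'   `mirnas`.
#' @export
load_catalog <- function(paths, tf_list, alias_map = NULL) {
  frames <- if (is.data.frame(paths)) list(paths)
  else if (is.character(paths)) {
    purrr::map(paths, function(p) {
      readr::read_tsv(p, col_types = readr::cols(.default = readr::col_character()))
    })
  } else paths
  edges <- dplyr::bind_rows(purrr::map(frames, tibble::as_tibble))
  tfs <- if (length(tf_list) == 1 && file.exists(tf_list)) {
    readLines(tf_list)
  } else as.character(tf_list)
  tfs <- unique(tfs[nzchar(tfs)])

  if (nrow(edges) == 0) {
    return(new_catalog(tibble::tibble(source_id = character(),
                                      target_id = character(),
                                      edge_type = character(),
                                      evidence = character()),
                       tfs = tfs, mirnas = character()))
  }
  required <- c("source_id", "target_id", "edge_type")
  if (!all(required %in% names(edges))) {
    abort("catalog tables need columns source_id, target_id, edge_type",
          class = "ffldyn_input_error")
  }
  if (!"evidence" %in% names(edges)) edges$evidence <- "unspecified"
  bad <- which(!edges$edge_type %in% catalog_edge_types)
  if (length(bad) > 0) {
    abort(paste0("unknown edge_type in rows: ",
                 paste(head(bad, 10), collapse = ", ")),
          class = "ffldyn_input_error")
  }

  mirna_src <- edges$edge_type %in% c("mirna_gene", "mirna_tf")
  mirna_tgt <- edges$edge_type == "tf_mirna"
  edges$source_id[mirna_src] <-
    normalize_mirna_ids(edges$source_id[mirna_src], alias_map)
  edges$target_id[mirna_tgt] <-
    normalize_mirna_ids(edges$target_id[mirna_tgt], alias_map)

  mirnas <- unique(c(edges$source_id[mirna_src], edges$target_id[mirna_tgt]))
  others <- unique(c(edges$source_id[!mirna_src], edges$target_id[!mirna_tgt]))
  conflict <- intersect(mirnas, others)
  if (length(conflict) > 0) {
    rows <- which(edges$source_id %in% conflict | edges$target_id %in% conflict)
    abort(paste0("identifier(s) used both as miRNA and as TF/gene: ",
                 paste(head(conflict, 10), collapse = ", "),
                 " (rows ", paste(head(rows, 10), collapse = ", "), ")"),
          class = "ffldyn_input_error")
  }

  merged <- edges |>
    dplyr::group_by(.data$source_id, .data$target_id, .data$edge_type) |>
    dplyr::summarise(
      evidence = paste(sort(unique(.data$evidence)), collapse = ";"),
      .groups = "drop") |>
    dplyr::arrange(.data$edge_type, .data$source_id, .data$target_id)
  new_catalog(merged, tfs = tfs, mirnas = mirnas)
}

#' Enumerate miRNA-TF co-regulatory motifs (feed-forward loops)
#'
#' A motif is a triple `(miRNA m, TF t, gene g)` whose four regulatory edges
#' are all present in the catalog: mutual regulation `m -> t` (mirna_tf) and
#' `t -> m` (tf_mirna), plus the shared target edges `m -> g` and `t -> g`.
#' The TF and the target gene must belong to the supplied SDE set; miRNAs
#' are not filtered (no miRNA expression is assumed to be available). The
#' target may coincide with the TF (a TF regulating itself) unless
#' `allow_self_target = FALSE`.
#'
#' @param catalog An `interaction_catalog`.
#' @param sde Character vector of stage SDE gene ids.
#' @param allow_self_target Keep motifs with `g == t` (default `TRUE`).
#' @return A tibble (`mirna`, `tf`, `gene`) sorted lexicographically.
#' @export
enumerate_motifs <- function(catalog, sde, allow_self_target = TRUE) {
  empty <- tibble::tibble(mirna = character(), tf = character(),
                          gene = character())
  if (nrow(catalog) == 0) return(empty)
  mt <- catalog |> dplyr::filter(.data$edge_type == "mirna_tf") |>
    dplyr::select(mirna = "source_id", tf = "target_id")
  tm <- catalog |> dplyr::filter(.data$edge_type == "tf_mirna") |>
    dplyr::select(tf = "source_id", mirna = "target_id")
  mutual <- dplyr::inner_join(mt, tm, by = c("mirna", "tf")) |>
    dplyr::filter(.data$tf %in% sde)
  if (nrow(mutual) == 0) return(empty)
  m_targets <- catalog |>
    dplyr::filter(.data$edge_type %in% c("mirna_gene", "mirna_tf")) |>
    dplyr::select(mirna = "source_id", gene = "target_id") |>
    dplyr::distinct()
  t_targets <- catalog |> dplyr::filter(.data$edge_type == "tf_gene") |>
    dplyr::select(tf = "source_id", gene = "target_id") |>
    dplyr::distinct()
  motifs <- mutual |>
    dplyr::inner_join(m_targets, by = "mirna",
                      relationship = "many-to-many") |>
    dplyr::inner_join(t_targets, by = c("tf", "gene")) |>
    dplyr::filter(.data$gene %in% sde)
  if (!allow_self_target) {
    motifs <- dplyr::filter(motifs, .data$gene != .data$tf)
  }
  motifs <- motifs |>
    dplyr::distinct(.data$mirna, .data$tf, .data$gene) |>
    dplyr::arrange(.data$mirna, .data$tf, .data$gene)
  # plain tibble: do not leak catalog attributes/class into the motif list
  tibble::tibble(mirna = motifs$mirna, tf = motifs$tf, gene = motifs$gene)
}
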