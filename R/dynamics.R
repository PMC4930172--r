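region_key <- function(stages_present, all_stages) {
  paste(all_stages[all_stages %in% stages_present], collapse = "+")
}

#' Exact-subset (Venn) decomposition of stage networks
#'
#' Assigns every node and every edge of a set of stage networks to the
#' exact subset of stages containing it. Edge identity is the full triple
#' `(source, target, label)`, so an inhibition and a regulation between the
#' same nodes are distinct edges. Regions are pairwise disjoint and their
#' union is the union of the stage networks.
#'
#' @param nets Named list of `reg_network`s (names are stage labels;
#'   unnamed lists are labelled by the stored stage or position).
#' @return A `stage_comparison`: list with `stages`, `node_regions`
#'   (`id`, `region`), `edge_regions` (`source`, `target`, `label`,
#'   `region`), `region_sizes` (`region`, `n_nodes`, `n_edges`) and the
#'   input networks. `tidy()` returns `region_sizes`.
#' @export
venn_decompose <- function(nets) {
  if (length(nets) < 2) {
    abort("at least two stage networks are required",
          class = "ffldyn_input_error")
  }
  if (is.null(names(nets)) || any(!nzchar(names(nets)))) {
    names(nets) <- purrr::imap_chr(nets, function(n, i) {
      if (!is.na(n$stage)) as.character(n$stage) else as.character(i)
    })
  }
  stages <- names(nets)

  node_member <- purrr::imap_dfr(nets, function(n, s) {
    tibble::tibble(id = n$nodes$id, stage = s)
  })
  node_regions <- node_member |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(region = region_key(.data$stage, stages),
                     .groups = "drop") |>
    dplyr::arrange(.data$id)

  edge_member <- purrr::imap_dfr(nets, function(n, s) {
    dplyr::mutate(n$edges, stage = s)
  })
  edge_regions <- edge_member |>
    dplyr::group_by(.data$source, .data$target, .data$label) |>
    dplyr::summarise(region = region_key(.data$stage, stages),
                     .groups = "drop") |>
    dplyr::arrange(.data$source, .data$target, .data$label)

  all_regions <- unlist(lapply(seq_along(stages), function(k) {
    apply(utils::combn(stages, k), 2, paste, collapse = "+")
  }))
  region_sizes <- tibble::tibble(region = all_regions) |>
    dplyr::mutate(
      n_nodes = purrr::map_int(.data$region,
                               ~ sum(node_regions$region == .x)),
      n_edges = purrr::map_int(.data$region,
                               ~ sum(edge_regions$region == .x)))

  structure(list(stages = stages,
                 node_regions = node_regions,
                 edge_regions = edge_regions,
                 region_sizes = region_sizes,
                 nets = nets),
            class = "stage_comparison")
}

#' @export
tidy.stage_comparison <- function(x, ...) x$region_sizes

#' @export
glance.stage_comparison <- function(x, ...) {
  tibble::tibble(n_stages = length(x$stages),
                 n_nodes_union = nrow(x$node_regions),
                 n_edges_union = nrow(x$edge_regions))
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat(sprintf("<stage_comparison over %s: %d nodes, %d edges in union>\n",
              paste(x$stages, collapse = ", "),
              nrow(x$node_regions), nrow(x$edge_regions)))
  print(x$region_sizes)
  invisible(x)
}

#' Extract the subnetwork specific to a stage subset
#'
#' Returns the subnetwork induced by the edges present in exactly the given
#' stage subset, together with their endpoints. Endpoints whose own node
#' region equals the subset are flagged `specific`; the rest are flagged
#' `shared` (they also occur in other stages).
#'
#' @param sc A `stage_comparison`.
#' @param subset Character vector of stage labels (a subset of
#'   `sc$stages`).
#' @return A `specific_subnetwork`: list with `subset`, `nodes`
#'   (`id`, `role`, `status`) and `edges` (`source`, `target`, `label`).
#' @export
extract_specific <- function(sc, subset) {
  if (length(subset) == 0 || !all(subset %in% sc$stages)) {
    abort("`subset` must be a non-empty subset of the compared stages",
          class = "ffldyn_input_error")
  }
  key <- region_key(subset, sc$stages)
  edges <- sc$edge_regions |>
    dplyr::filter(.data$region == key) |>
    dplyr::select("source", "target", "label")
  if (nrow(edges) == 0) {
    warn(sprintf("no edge is specific to the stage subset {%s}",
                 paste(subset, collapse = ", ")))
  }
  ids <- unique(c(edges$source, edges$target))
  roles <- purrr::map_dfr(sc$nets, ~ .x$nodes) |>
    dplyr::distinct(.data$id, .keep_all = TRUE)
  node_region <- sc$node_regions$region[match(ids, sc$node_regions$id)]
  nodes <- tibble::tibble(
    id = ids,
    role = roles$role[match(ids, roles$id)],
    status = ifelse(node_region == key, "specific", "shared")
  ) |> dplyr::arrange(.data$id)
  structure(list(subset = subset, nodes = nodes, edges = edges),
            class = "specific_subnetwork")
}

#' Pairwise containment report for stage networks
#'
#' For every ordered pair of stages, reports whether the node set and the
#' edge set of the first network are contained in the second; additionally
#' tests each stage against the union of the other stages.
#'
#' @param sc A `stage_comparison` over at least two stages.
#' @return Tibble (`inner`, `outer`, `nodes_contained`, `edges_contained`);
#'   `outer = "union(others)"` rows give the against-the-rest tests.
#' @export
containment_check <- function(sc) {
  node_sets <- purrr::map(sc$nets, ~ unique(.x$nodes$id))
  edge_sets <- purrr::map(sc$nets, ~ edge_key(.x$edges$source,
                                              .x$edges$target,
                                              .x$edges$label))
  stages <- sc$stages
  pairs <- expand.grid(inner = stages, outer = stages,
                       stringsAsFactors = FALSE) |>
    dplyr::filter(.data$inner != .data$outer)
  pairwise <- purrr::pmap_dfr(pairs, function(inner, outer) {
    tibble::tibble(
      inner = inner, outer = outer,
      nodes_contained = all(node_sets[[inner]] %in% node_sets[[outer]]),
      edges_contained = all(edge_sets[[inner]] %in% edge_sets[[outer]]))
  })
  vs_union <- purrr::map_dfr(stages, function(s) {
    others_n <- unique(unlist(node_sets[setdiff(stages, s)]))
    others_e <- unique(unlist(edge_sets[setdiff(stages, s)]))
    tibble::tibble(
      inner = s, outer = "union(others)",
      nodes_contained = all(node_sets[[s]] %in% others_n),
      edges_contained = all(edge_sets[[s]] %in% others_e))
  })
  dplyr::bind_rows(pairwise, vs_union)
}
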