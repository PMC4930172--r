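#' Read and write GMT gene-set files
#'
#' GMT is tab-separated: set id, description, then one gene per field. The
#' description field carries the parent pathway id (or `NA`).
#'
#' @param path File path.
#' @return `read_gmt()` returns a `gene_set_collection` tibble (`set_id`,
#'   `parent_id`, `genes` list-column); set `attr(, "universe")` before use
#'   or pass a universe to [hypergeom_enrich()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- tibble::tibble(
    set_id = purrr::map_chr(parts, 1),
    parent_id = purrr::map_chr(parts, function(p) {
      if (length(p) >= 2 && nzchar(p[2]) && p[2] != "NA") p[2] else NA_character_
    }),
    genes = purrr::map(parts, function(p) unique(p[-(1:2)]))
  )
  class(out) <- c("gene_set_collection", class(out))
  out
}

#' @rdname read_gmt
#' @param sets A `gene_set_collection` tibble.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(
    list(sets$set_id, sets$parent_id, sets$genes),
    function(id, parent, genes) {
      paste(c(id, ifelse(is.na(parent), "NA", parent), genes),
            collapse = "\t")
    })
  writeLines(lines, path)
  invisible(path)
}

#' One-sided hypergeometric gene-set enrichment
#'
#' For each set, tests over-representation of the SDE genes with the exact
#' upper-tail hypergeometric probability
#' `P(X >= x) = sum_{i=x}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`, where `N`
#' is the background universe size, `K` the set size within the universe,
#' `n` the number of SDE genes in the universe and `x` their overlap with
#' the set. P-values are BH-adjusted across all sets of the collection; a
#' set is significant when the adjusted p is below `alpha`.
#'
#' @param sde Character vector of SDE gene ids; genes outside the universe
#'   are dropped with a message.
#' @param sets A `gene_set_collection` tibble.
#' @param universe Background gene universe; defaults to
#'   `attr(sets, "universe")`. Standard practice (followed here) is the set
#'   of genes that survived preprocessing, not the whole genome.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return An `enrichment_table` tibble: `set_id`, `parent_id`, `set_size`,
#'   `overlap`, `n_sde`, `n_universe`, `p_value`, `adj_p`, `significant`.
#' @export
hypergeom_enrich <- function(sde, sets, universe = attr(sets, "universe"),
                             alpha = 0.05) {
  if (is.null(universe) || length(universe) == 0) {
    abort("an enrichment background universe is required",
          class = "ffldyn_input_error")
  }
  if (length(sde) == 0) {
    abort("the SDE gene set is empty", class = "ffldyn_input_error")
  }
  universe <- unique(universe)
  sde_in <- intersect(unique(sde), universe)
  dropped <- length(unique(sde)) - length(sde_in)
  if (dropped > 0) {
    inform(sprintf("%d SDE gene(s) outside the universe dropped", dropped))
  }
  if (length(sde_in) == 0) {
    abort("no SDE gene lies in the universe", class = "ffldyn_input_error")
  }
  n_univ <- length(universe)
  n_sde <- length(sde_in)
  out <- tibble::tibble(
    set_id = sets$set_id,
    parent_id = if ("parent_id" %in% names(sets)) sets$parent_id else NA_character_,
    set_size = purrr::map_int(sets$genes,
                              ~ length(intersect(.x, universe))),
    overlap = purrr::map_int(sets$genes,
                             ~ length(intersect(.x, sde_in)))
  )
  out$n_sde <- n_sde
  out$n_universe <- n_univ
  # upper tail P(X >= x) = phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  out$p_value <- phyper(out$overlap - 1L, out$set_size,
                        n_univ - out$set_size, n_sde, lower.tail = FALSE)
  out$adj_p <- bh_adjust(out$p_value)
  out$significant <- out$adj_p < alpha
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Collapse significant subpathways to one per parent pathway
#'
#' When several significant subpathways share a parent pathway, only the one
#' with the minimum adjusted p is retained (ties broken by the
#' lexicographically smallest set id). Non-significant rows are dropped.
#'
#' @param tbl An `enrichment_table` with `parent_id`.
#' @return The collapsed `enrichment_table` (at most one row per parent).
#' @export
collapse_subpathways <- function(tbl) {
  out <- tbl |>
    dplyr::filter(.data$significant) |>
    dplyr::arrange(.data$adj_p, .data$set_id) |>
    dplyr::group_by(parent = dplyr::coalesce(.data$parent_id, .data$set_id)) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-"parent") |>
    dplyr::arrange(.data$set_id)
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Stage-by-set significance matrix
#'
#' Assembles the per-stage enrichment results into the long form behind the
#' stage-dynamics heatmap: one row per set and stage with the adjusted p and
#' a status marker -- `"sig"` (adjusted p < alpha), `"ns"` (tested, some
#' overlap, not significant) or `"na"` (zero overlap with the SDE genes).
#'
#' @param tables Named list of `enrichment_table`s, one per stage (names are
#'   the stage labels).
#' @param filter Optional regular expression; sets whose id or parent id
#'   matches are removed (e.g. to drop cancer pathways).
#' @param alpha Significance level (default 0.05).
#' @return An `enrich_matrix` tibble (`set_id`, `stage`, `adj_p`, `status`),
#'   restricted to sets significant in at least one stage.
#' @export
significance_matrix <- function(tables, filter = NULL, alpha = 0.05) {
  if (length(tables) < 1) {
    abort("at least one stage table is required", class = "ffldyn_input_error")
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- as.character(seq_along(tables))
  }
  long <- purrr::imap_dfr(tables, function(tbl, stage) {
    tibble::tibble(set_id = tbl$set_id,
                   parent_id = tbl$parent_id,
                   stage = stage,
                   adj_p = tbl$adj_p,
                   status = dplyr::case_when(
                     tbl$overlap == 0 ~ "na",
                     tbl$adj_p < alpha ~ "sig",
                     TRUE ~ "ns"
                   ))
  })
  if (!is.null(filter)) {
    long <- long |>
      dplyr::filter(!grepl(filter, .data$set_id) &
                      !(!is.na(.data$parent_id) & grepl(filter, .data$parent_id)))
  }
  keep <- unique(long$set_id[long$status == "sig"])
  out <- long |>
    dplyr::filter(.data$set_id %in% keep) |>
    dplyr::select(-"parent_id")
  if (nrow(out) == 0) {
    warn("no set is significant in any stage after filtering")
  }
  class(out) <- c("enrich_matrix", class(out))
  out
}

#' @export
autoplot.enrich_matrix <- function(object, ...) {
  dat <- dplyr::mutate(object,
                       shade = ifelse(.data$status == "sig",
                                      -log10(pmax(.data$adj_p, 1e-300)), NA_real_))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stage, y = .data$set_id,
                                    fill = .data$shade)) +
    ggplot2::geom_tile(colour = "grey50") +
    ggplot2::scale_fill_gradient(low = "grey85", high = "black",
                                 na.value = "white",
                                 name = "-log10 adj p") +
    ggplot2::labs(x = "stage", y = NULL) +
    ggplot2::theme_minimal()
}
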