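#' Build standardized stage-profile rows for a gene list
#'
#' For each gene the profile is the control baseline (0) followed by the
#' per-stage log2 fold change versus controls; rows are then standardized to
#' mean 0, standard deviation 1. Constant rows cannot be standardized and
#' are dropped with a warning.
#'
#' @param det Combined `de_table` with a `stage` column.
#' @param genes Genes to profile (must appear in `det` at every stage).
#' @return A `profile_matrix` tibble: `gene`, `baseline`, then one
#'   `stage_<s>` column per stage, standardized row-wise.
#' @export
build_profiles <- function(det, genes) {
  missing <- setdiff(genes, det$gene)
  if (length(missing) > 0) {
    abort(paste0("genes absent from the DE table: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "ffldyn_input_error")
  }
  wide <- det |>
    dplyr::filter(.data$gene %in% genes) |>
    dplyr::select("gene", "stage", "log2fc") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "log2fc",
                       names_prefix = "stage_") |>
    dplyr::arrange(match(.data$gene, genes))
  x <- cbind(baseline = 0, as.matrix(wide[, -1, drop = FALSE]))
  rownames(x) <- wide$gene
  sds <- apply(x, 1, sd)
  constant <- sds < 1e-12
  if (any(constant)) {
    warn(sprintf("%d constant profile(s) dropped before standardization",
                 sum(constant)))
    x <- x[!constant, , drop = FALSE]
    sds <- sds[!constant]
  }
  z <- (x - rowMeans(x)) / sds
  out <- expr_tibble(z, id_col = "gene")
  class(out) <- c("profile_matrix", class(out))
  out
}

#' Hierarchically cluster standardized profiles
#'
#' City-block (Manhattan) distance with complete linkage, cut into `k`
#' clusters (default 2, the two main expression patterns: sharp
#' up-regulation then slow decay, and sharp down-regulation then slow
#' recovery).
#'
#' @param profiles A `profile_matrix` from [build_profiles()].
#' @param k Number of clusters to cut.
#' @return A `profile_clustering` object bundling the `hclust` tree, the
#'   cluster assignments and the profiles. `tidy()` returns the
#'   assignments; `glance()` the cluster sizes.
#' @export
hcluster_profiles <- function(profiles, k = 2) {
  x <- expr_matrix(profiles)
  if (k > nrow(x)) {
    abort(sprintf("cannot cut %d rows into %d clusters", nrow(x), k),
          class = "ffldyn_input_error")
  }
  d <- dist(x, method = "manhattan")
  tree <- hclust(d, method = "complete")
  assignment <- cutree(tree, k = k)
  structure(list(
    tree = tree,
    k = k,
    assignments = tibble::tibble(gene = rownames(x),
                                 cluster = unname(assignment)),
    profiles = profiles
  ), class = "profile_clustering")
}

#' @export
tidy.profile_clustering <- function(x, ...) x$assignments

#' @export
glance.profile_clustering <- function(x, ...) {
  tibble::tibble(k = x$k,
                 n_genes = nrow(x$assignments),
                 max_merge_height = max(x$tree$height))
}

#' Per-cluster mean profiles with a qualitative pattern label
#'
#' Averages the standardized rows of each cluster and labels the pattern by
#' the sign of the stage-1 mean: negative gives `down-then-recover`,
#' positive gives `up-then-decay`.
#'
#' @param clustering A `profile_clustering` from [hcluster_profiles()].
#' @return A tibble with `cluster`, `pattern`, and one row per profile
#'   point (`point`, `mean`).
#' @export
cluster_means <- function(clustering) {
  z <- expr_matrix(clustering$profiles)
  cl <- clustering$assignments$cluster
  means <- rowsum(z, group = cl) / as.vector(table(cl))
  first_stage_col <- 2L  # column 1 is the baseline point
  purrr::map_dfr(seq_len(nrow(means)), function(i) {
    tibble::tibble(
      cluster = as.integer(rownames(means)[i]),
      pattern = if (means[i, first_stage_col] < 0) "down-then-recover"
                else "up-then-decay",
      point = colnames(means),
      mean = unname(means[i, ])
    )
  })
}

#' @export
autoplot.profile_clustering <- function(object, ...) {
  z <- expr_matrix(object$profiles)
  long <- expr_tibble(z, id_col = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "point", values_to = "value") |>
    dplyr::left_join(object$assignments, by = "gene") |>
    dplyr::mutate(point = factor(.data$point, levels = colnames(z)))
  means <- cluster_means(object) |>
    dplyr::mutate(point = factor(.data$point, levels = colnames(z)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$point, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$gene),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = means, ggplot2::aes(y = .data$mean),
                        colour = "black", size = 2) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(y = .data$mean, group = .data$cluster),
                       colour = "black") +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "standardized expression") +
    ggplot2::theme_minimal()
}
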