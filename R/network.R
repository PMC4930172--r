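#' Merge co-regulatory motifs into a stage network
#'
#' Takes the union of the four directed edges of every motif and resolves
#' node roles: `miRNA`, `TF`, `gene`, or `TF+gene` when an id appears both
#' as a TF and as a target gene. Edges from miRNAs are labelled `"inh"`
#' (inhibition); edges from TFs are labelled `"reg"` (regulation).
#'
#' @param motifs Motif tibble (`mirna`, `tf`, `gene`) from
#'   [enumerate_motifs()].
#' @param stage Stage label stored on the network.
#' @return A `reg_network`: list with `nodes` (`id`, `role`), `edges`
#'   (`source`, `target`, `label`), `stage` and `n_motifs`. `tidy()`
#'   returns the edges; `glance()` a Table-1-style count summary.
#' @export
merge_motifs <- function(motifs, stage = NA) {
  edges <- dplyr::bind_rows(
    tibble::tibble(source = motifs$mirna, target = motifs$tf, label = "inh"),
    tibble::tibble(source = motifs$tf, target = motifs$mirna, label = "reg"),
    tibble::tibble(source = motifs$mirna, target = motifs$gene, label = "inh"),
    tibble::tibble(source = motifs$tf, target = motifs$gene, label = "reg")
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$source, .data$target, .data$label)
  mirnas <- unique(motifs$mirna)
  tfs <- unique(motifs$tf)
  targets <- unique(motifs$gene)
  both <- intersect(tfs, targets)
  nodes <- tibble::tibble(
    id = c(mirnas, union(tfs, targets)),
    role = c(rep("miRNA", length(mirnas)),
             ifelse(union(tfs, targets) %in% both, "TF+gene",
                    ifelse(union(tfs, targets) %in% tfs, "TF", "gene")))
  ) |> dplyr::arrange(.data$role, .data$id)
  structure(list(nodes = nodes, edges = edges, stage = stage,
                 n_motifs = nrow(motifs)),
            class = "reg_network")
}

#' @export
print.reg_network <- function(x, ...) {
  cat(sprintf("<reg_network stage=%s: %d nodes, %d edges, %d motifs>\n",
              as.character(x$stage), nrow(x$nodes), nrow(x$edges), x$n_motifs))
  invisible(x)
}

#' @export
tidy.reg_network <- function(x, ...) {
  dplyr::mutate(x$edges, stage = x$stage)
}

#' @export
glance.reg_network <- function(x, ...) {
  role <- setNames(x$nodes$role, x$nodes$id)
  src_role <- role[x$edges$source]
  tgt_role <- role[x$edges$target]
  tibble::tibble(
    stage = x$stage,
    n_motifs = x$n_motifs,
    n_nodes = nrow(x$nodes),
    n_mirnas = sum(x$nodes$role == "miRNA"),
    n_tfs = sum(x$nodes$role %in% c("TF", "TF+gene")),
    n_genes = sum(x$nodes$role %in% c("gene", "TF+gene")),
    n_tf_gene_shared = sum(x$nodes$role == "TF+gene"),
    n_edges = nrow(x$edges),
    n_mirna_gene = sum(src_role == "miRNA" & tgt_role == "gene"),
    n_mirna_tf = sum(src_role == "miRNA" & tgt_role != "gene"),
    n_tf_gene = sum(src_role != "miRNA" & tgt_role != "miRNA"),
    n_tf_mirna = sum(src_role != "miRNA" & tgt_role == "miRNA")
  )
}

# Undirected simple collapse of the edge list: unordered distinct pairs,
# self-loops kept apart.
collapse_edges <- function(net) {
  e <- dplyr::distinct(net$edges, .data$source, .data$target)
  loops <- e[e$source == e$target, , drop = FALSE]
  e <- e[e$source != e$target, , drop = FALSE]
  a <- pmin(e$source, e$target)
  b <- pmax(e$source, e$target)
  pairs <- dplyr::distinct(tibble::tibble(a = a, b = b))
  list(pairs = pairs, loop_ids = unique(loops$source))
}

#' Node degree
#'
#' In `collapsed` mode (default) the degree is the number of distinct
#' neighbours in the undirected collapse of the network, so a mutual
#' miRNA-TF pair contributes one; a self-loop adds one. In `directed` mode
#' it is the number of incident directed edges; a self-loop adds two.
#'
#' @param net A `reg_network`.
#' @param mode `"collapsed"` or `"directed"`.
#' @return Tibble (`id`, `degree`) covering every network node.
#' @export
node_degree <- function(net, mode = c("collapsed", "directed")) {
  mode <- match.arg(mode)
  ids <- net$nodes$id
  deg <- setNames(rep(0L, length(ids)), ids)
  if (mode == "collapsed") {
    ce <- collapse_edges(net)
    tab <- table(c(ce$pairs$a, ce$pairs$b))
    deg[names(tab)] <- as.integer(tab)
    deg[ce$loop_ids] <- deg[ce$loop_ids] + 1L
  } else {
    e <- dplyr::distinct(net$edges, .data$source, .data$target, .data$label)
    tab <- table(c(e$source, e$target))
    deg[names(tab)] <- as.integer(tab)
  }
  tibble::tibble(id = ids, degree = unname(deg[ids]))
}

# Brandes' accumulation for unweighted betweenness over ordered pairs:
# BC(v) = sum over ordered (s, t), s != v != t, of sigma_st(v) / sigma_st.
brandes_bc <- function(adj, ids) {
  n <- length(ids)
  bc <- setNames(rep(0, n), ids)
  for (s in ids) {
    stack <- character(0)
    pred <- setNames(vector("list", n), ids)
    sigma <- setNames(rep(0, n), ids)
    dist_ <- setNames(rep(-1, n), ids)
    sigma[s] <- 1
    dist_[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      stack <- c(stack, v)
      for (w in adj[[v]]) {
        if (dist_[w] < 0) {
          queue <- c(queue, w)
          dist_[w] <- dist_[v] + 1
        }
        if (dist_[w] == dist_[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
    delta <- setNames(rep(0, n), ids)
    for (w in rev(stack)) {
      for (v in pred[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc
}

#' Betweenness centrality
#'
#' Computes `BC_i = sum_{s != i != t} sigma_i(s, t) / sigma(s, t)` over
#' ordered node pairs with unweighted shortest paths, by Brandes'
#' dependency accumulation. The default view is the undirected collapse of
#' the network (mutual edges count once, self-loops ignored); ordered-pair
#' counting means the middle of a three-node path scores 2. Unreachable
#' pairs contribute nothing.
#'
#' @param net A `reg_network`.
#' @param mode `"undirected"` (default) or `"directed"`.
#' @return Tibble (`id`, `betweenness`).
#' @export
node_betweenness <- function(net, mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  ids <- net$nodes$id
  adj <- setNames(vector("list", length(ids)), ids)
  for (i in seq_along(adj)) adj[[i]] <- character(0)
  if (mode == "undirected") {
    ce <- collapse_edges(net)
    for (i in seq_len(nrow(ce$pairs))) {
      a <- ce$pairs$a[i]; b <- ce$pairs$b[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  } else {
    e <- dplyr::distinct(net$edges, .data$source, .data$target)
    e <- e[e$source != e$target, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      adj[[e$source[i]]] <- c(adj[[e$source[i]]], e$target[i])
    }
  }
  bc <- brandes_bc(adj, ids)
  tibble::tibble(id = ids, betweenness = unname(bc[ids]))
}

#' Call hub nodes from a degree table
#'
#' Hubs are the nodes whose degree reaches the `1 - top_fraction` quantile
#' of the degree distribution; every tie at the cutoff is included, so at
#' least the maximum-degree node is always a hub.
#'
#' @param deg Tibble (`id`, `degree`) from [node_degree()].
#' @param top_fraction Fraction of the distribution called hubs
#'   (default 0.20).
#' @return Sorted character vector of hub ids.
#' @export
call_hubs <- function(deg, top_fraction = 0.20) {
  if (nrow(deg) == 0) {
    abort("empty degree table", class = "ffldyn_input_error")
  }
  check_scalar_number(top_fraction, "top_fraction", 0, 1, strict_lower = TRUE)
  cutoff <- quantile(deg$degree, probs = 1 - top_fraction, names = FALSE)
  sort(deg$id[deg$degree >= cutoff])
}

#' Node centrality table for a stage network
#'
#' Convenience wrapper combining [node_degree()], [node_betweenness()] and
#' [call_hubs()].
#'
#' @param net A `reg_network`.
#' @param degree_mode Passed to [node_degree()].
#' @param bc_mode Passed to [node_betweenness()].
#' @param hub_fraction Passed to [call_hubs()].
#' @return Tibble (`id`, `role`, `degree`, `betweenness`, `hub`).
#' @export
centrality_table <- function(net, degree_mode = "collapsed",
                             bc_mode = "undirected", hub_fraction = 0.20) {
  deg <- node_degree(net, mode = degree_mode)
  bc <- node_betweenness(net, mode = bc_mode)
  hubs <- call_hubs(deg, top_fraction = hub_fraction)
  net$nodes |>
    dplyr::left_join(deg, by = "id") |>
    dplyr::left_join(bc, by = "id") |>
    dplyr::mutate(hub = .data$id %in% hubs) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$id)
}

#' @export
autoplot.reg_network <- function(object, ...) {
  nodes <- object$nodes
  n <- nrow(nodes)
  theta <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  layout <- tibble::tibble(id = nodes$id, role = nodes$role,
                           x = cos(theta), y = sin(theta))
  edges <- object$edges |>
    dplyr::left_join(layout, by = c(source = "id")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(layout, by = c(target = "id")) |>
    dplyr::rename(x1 = "x", y1 = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       colour = .data$label),
                          alpha = 0.6) +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$role), size = 3) +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(x = .data$x * 1.08, y = .data$y * 1.08,
                                    label = .data$id), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(inh = "#D55E00", reg = "#0072B2")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("stage %s co-regulatory network",
                                  as.character(object$stage)))
}
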