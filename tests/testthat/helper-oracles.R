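# Independent brute-force oracles used across the suite. These are written
# against the definitions, not against the package implementations.

# Exhaustive O(M*T*G) feed-forward-loop enumeration over a typed edge list.
oracle_enumerate_ffls <- function(catalog, sde, allow_self_target = TRUE) {
  has <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(catalog))) {
    assign(paste(catalog$source_id[i], catalog$target_id[i],
                 catalog$edge_type[i], sep = "\r"), TRUE, envir = has)
  }
  chk <- function(s, t, ty) exists(paste(s, t, ty, sep = "\r"), envir = has)
  mirnas <- unique(catalog$source_id[catalog$edge_type %in%
                                       c("mirna_gene", "mirna_tf")])
  mirnas <- union(mirnas,
                  catalog$target_id[catalog$edge_type == "tf_mirna"])
  tfs <- unique(c(catalog$source_id[catalog$edge_type %in%
                                      c("tf_gene", "tf_mirna")],
                  catalog$target_id[catalog$edge_type == "mirna_tf"]))
  genes <- unique(catalog$target_id[catalog$edge_type %in%
                                      c("mirna_gene", "tf_gene", "mirna_tf")])
  out <- list()
  for (m in mirnas) for (t in tfs) {
    if (!(chk(m, t, "mirna_tf") && chk(t, m, "tf_mirna"))) next
    if (!t %in% sde) next
    for (g in genes) {
      if (!g %in% sde) next
      if (g == t && !allow_self_target) next
      m_to_g <- chk(m, g, "mirna_gene") || chk(m, g, "mirna_tf")
      t_to_g <- chk(t, g, "tf_gene")
      if (m_to_g && t_to_g) out[[length(out) + 1]] <- c(m, t, g)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(mirna = character(), tf = character(),
                          gene = character()))
  }
  mat <- do.call(rbind, out)
  res <- tibble::tibble(mirna = mat[, 1], tf = mat[, 2], gene = mat[, 3])
  res[order(res$mirna, res$tf, res$gene), ]
}

# Shortest-path sigma counting by plain BFS from one source.
bfs_sigma <- function(adj, ids, s) {
  dist_ <- stats::setNames(rep(Inf, length(ids)), ids)
  sigma <- stats::setNames(rep(0, length(ids)), ids)
  dist_[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist_[w])) {
          dist_[w] <- dist_[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist_[w] == dist_[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist_, sigma = sigma)
}

# Betweenness by direct evaluation of the definition: for every ordered
# pair (s, t) and interior node i, add sigma(s,i) * sigma(i,t) / sigma(s,t)
# whenever d(s,i) + d(i,t) = d(s,t).
oracle_betweenness <- function(net, mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  ids <- net$nodes$id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(adj)) adj[[i]] <- character(0)
  e <- unique(net$edges[, c("source", "target")])
  e <- e[e$source != e$target, , drop = FALSE]
  for (i in seq_len(nrow(e))) {
    adj[[e$source[i]]] <- union(adj[[e$source[i]]], e$target[i])
    if (mode == "undirected") {
      adj[[e$target[i]]] <- union(adj[[e$target[i]]], e$source[i])
    }
  }
  sp <- lapply(stats::setNames(ids, ids), function(s) bfs_sigma(adj, ids, s))
  bc <- stats::setNames(rep(0, length(ids)), ids)
  for (s in ids) for (t in ids) {
    if (s == t) next
    d_st <- sp[[s]]$dist[t]
    if (is.infinite(d_st)) next
    sig_st <- sp[[s]]$sigma[t]
    for (i in ids) {
      if (i == s || i == t) next
      if (sp[[s]]$dist[i] + sp[[i]]$dist[t] == d_st) {
        bc[i] <- bc[i] + sp[[s]]$sigma[i] * sp[[i]]$sigma[t] / sig_st
      }
    }
  }
  tibble::tibble(id = ids, betweenness = unname(bc[ids]))
}

# Naive O(n^3) complete-linkage agglomeration; returns sorted merge heights.
oracle_complete_linkage_heights <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  d <- as.matrix(dist(x, method = "manhattan"))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Direct step-up evaluation of the BH definition, quadratic on purpose.
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- m * p[r >= r[i]] / r[r >= r[i]]
    q[i] <- min(1, min(cand))
  }
  q
}

# Random typed catalog for motif-oracle equivalence checks.
random_catalog <- function(n_mirnas, n_tfs, n_genes, n_edges, seed) {
  set.seed(seed)
  mirnas <- sprintf("hsa-mir-r%03d", seq_len(n_mirnas))
  tfs <- sprintf("RTF%03d", seq_len(n_tfs))
  genes <- sprintf("RG%03d", seq_len(n_genes))
  types <- sample(c("mirna_gene", "mirna_tf", "tf_gene", "tf_mirna"),
                  n_edges, replace = TRUE)
  src <- ifelse(types %in% c("mirna_gene", "mirna_tf"),
                sample(mirnas, n_edges, replace = TRUE),
                sample(tfs, n_edges, replace = TRUE))
  tgt <- character(n_edges)
  tgt[types == "mirna_gene"] <- sample(c(genes, tfs),
                                       sum(types == "mirna_gene"),
                                       replace = TRUE)
  tgt[types == "mirna_tf"] <- sample(tfs, sum(types == "mirna_tf"),
                                     replace = TRUE)
  tgt[types == "tf_gene"] <- sample(c(genes, tfs), sum(types == "tf_gene"),
                                    replace = TRUE)
  tgt[types == "tf_mirna"] <- sample(mirnas, sum(types == "tf_mirna"),
                                     replace = TRUE)
  cat_tbl <- tibble::tibble(source_id = src, target_id = tgt,
                            edge_type = types, evidence = "random")
  cat_tbl <- cat_tbl[!duplicated(cat_tbl[, 1:3]), ]
  load_catalog(cat_tbl, tf_list = tfs)
}

# Random reg_network-shaped object (roles are irrelevant to the graph ops).
random_network <- function(n_nodes, n_edges, seed, stage = NA) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  src <- sample(ids, n_edges, replace = TRUE)
  tgt <- sample(ids, n_edges, replace = TRUE)
  keep <- src != tgt
  edges <- unique(tibble::tibble(source = src[keep], target = tgt[keep],
                                 label = sample(c("inh", "reg"),
                                                sum(keep), replace = TRUE)))
  structure(list(
    nodes = tibble::tibble(id = ids,
                           role = sample(c("miRNA", "TF", "gene"),
                                         n_nodes, replace = TRUE)),
    edges = edges, stage = stage, n_motifs = NA_integer_
  ), class = "reg_network")
}

# Small deterministic motif set for dynamics tests.
random_motifs <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    mirna = sprintf("hsa-mir-m%02d", sample(1:8, n, replace = TRUE)),
    tf = sprintf("MTF%02d", sample(1:6, n, replace = TRUE)),
    gene = sprintf("MG%02d", sample(1:10, n, replace = TRUE))
  ) |> dplyr::distinct()
}
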