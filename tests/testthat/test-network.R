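minimal_catalog <- function(extra = NULL, drop = NULL) {
  edges <- tibble::tibble(
    source_id = c("hsa-mir-0001", "TF1", "hsa-mir-0001", "TF1"),
    target_id = c("TF1", "hsa-mir-0001", "G1", "G1"),
    edge_type = c("mirna_tf", "tf_mirna", "mirna_gene", "tf_gene"),
    evidence = "fixture")
  if (!is.null(drop)) edges <- edges[-drop, ]
  if (!is.null(extra)) edges <- dplyr::bind_rows(edges, extra)
  load_catalog(edges, tf_list = c("TF1", "TF2"))
}

test_that("catalog loading merges duplicates, normalizes ids and validates roles", {
  a <- tibble::tibble(source_id = "HSA-MIR-21-5P", target_id = "STAT3",
                      edge_type = "mirna_tf", evidence = "tarbase")
  b <- tibble::tibble(source_id = "hsa-miR-21-5p", target_id = "STAT3",
                      edge_type = "mirna_tf", evidence = "mirtarbase")
  cat_ab <- load_catalog(list(a, b), tf_list = "STAT3")
  expect_equal(nrow(cat_ab), 1)
  expect_equal(cat_ab$evidence, "mirtarbase;tarbase")
  expect_equal(cat_ab$source_id, "hsa-mir-21-5p")

  # alias map closure
  alias <- tibble::tibble(alias = c("hsa-mir-21", "mir-21"),
                          canonical = c("hsa-mir-21-5p", "hsa-mir-21-5p"))
  c3 <- tibble::tibble(source_id = c("hsa-miR-21", "MIR-21", "hsa-mir-21-5p"),
                       target_id = "STAT3", edge_type = "mirna_tf",
                       evidence = c("x", "y", "z"))
  cat_c <- load_catalog(c3, tf_list = "STAT3", alias_map = alias)
  expect_equal(nrow(cat_c), 1)
  expect_equal(cat_c$evidence, "x;y;z")

  expect_equal(nrow(load_catalog(tibble::tibble(), tf_list = "STAT3")), 0)
  bad <- tibble::tibble(source_id = "m1", target_id = "g1",
                        edge_type = "mystery", evidence = "e")
  expect_error(load_catalog(bad, tf_list = "T"), "edge_type",
               class = "ffldyn_input_error")
  conflict <- tibble::tibble(
    source_id = c("hsa-mir-9", "TFX"),
    target_id = c("TFX", "hsa-mir-9"),
    edge_type = c("mirna_tf", "tf_gene"),  # hsa-mir-9 also used as a gene
    evidence = "e")
  expect_error(load_catalog(conflict, tf_list = "TFX"),
               "both as miRNA", class = "ffldyn_input_error")
})

test_that("motif enumeration needs all four edges and the SDE filter", {
  full <- minimal_catalog()
  found <- enumerate_motifs(full, sde = c("TF1", "G1"))
  expect_equal(as.data.frame(found),
               data.frame(mirna = "hsa-mir-0001", tf = "TF1", gene = "G1"))
  # mutual regulation is required
  expect_equal(nrow(enumerate_motifs(minimal_catalog(drop = 2),
                                     sde = c("TF1", "G1"))), 0)
  # TF must be SDE, target must be SDE, miRNA is never filtered
  expect_equal(nrow(enumerate_motifs(full, sde = "G1")), 0)
  expect_equal(nrow(enumerate_motifs(full, sde = "TF1")), 0)
  # self-target motif via a TF self-loop
  self_cat <- minimal_catalog(extra = tibble::tibble(
    source_id = "TF1", target_id = "TF1", edge_type = "tf_gene",
    evidence = "fixture"))
  m_self <- enumerate_motifs(self_cat, sde = c("TF1", "G1"))
  expect_true(any(m_self$gene == m_self$tf))
  m_noself <- enumerate_motifs(self_cat, sde = c("TF1", "G1"),
                               allow_self_target = FALSE)
  expect_false(any(m_noself$gene == m_noself$tf))
})

test_that("enumeration equals the exhaustive triple loop on random catalogs", {
  for (seed in 1:10) {
    cat_r <- random_catalog(n_mirnas = 12, n_tfs = 8, n_genes = 20,
                            n_edges = 250, seed = seed)
    sde <- sample(c(sprintf("RG%03d", 1:20), sprintf("RTF%03d", 1:8)), 15)
    fast <- enumerate_motifs(cat_r, sde)
    slow <- oracle_enumerate_ffls(cat_r, sde)
    expect_equal(as.data.frame(fast), as.data.frame(slow),
                 ignore_attr = TRUE)
  }
})

test_that("motif merging resolves roles, labels and deduplicates edges", {
  one <- tibble::tibble(mirna = "m1", tf = "t1", gene = "g1")
  net1 <- merge_motifs(one, stage = 1)
  expect_equal(nrow(net1$nodes), 3)
  expect_equal(nrow(net1$edges), 4)
  expect_setequal(net1$edges$label[net1$edges$source == "m1"], "inh")
  expect_setequal(net1$edges$label[net1$edges$source == "t1"], "reg")

  two <- tibble::tibble(mirna = c("m1", "m1"), tf = c("t1", "t1"),
                        gene = c("g1", "g2"))
  net2 <- merge_motifs(two)
  expect_equal(nrow(net2$nodes), 4)
  expect_equal(nrow(net2$edges), 6)

  # a TF that is also a target becomes a TF+gene node
  shared <- tibble::tibble(mirna = c("m1", "m2"), tf = c("t1", "t2"),
                           gene = c("t2", "g1"))
  net3 <- merge_motifs(shared)
  expect_equal(net3$nodes$role[net3$nodes$id == "t2"], "TF+gene")
  # node accounting: miRNAs + union of TFs and genes, shared ids once
  g <- glance(net3)
  expect_equal(g$n_nodes, g$n_mirnas + g$n_tfs + g$n_genes -
                 g$n_tf_gene_shared)

  set.seed(33)
  motifs <- random_motifs(20, seed = 33)
  netr <- merge_motifs(motifs)
  edges_brute <- unique(rbind(
    cbind(motifs$mirna, motifs$tf), cbind(motifs$tf, motifs$mirna),
    cbind(motifs$mirna, motifs$gene), cbind(motifs$tf, motifs$gene)))
  expect_equal(nrow(netr$edges), nrow(edges_brute))
  expect_equal(nrow(netr$nodes),
               length(unique(c(motifs$mirna, motifs$tf, motifs$gene))))
})

test_that("degree follows the collapsed and directed conventions", {
  one <- merge_motifs(tibble::tibble(mirna = "m1", tf = "t1", gene = "g1"))
  deg_c <- node_degree(one, "collapsed")
  expect_equal(sort(deg_c$degree), c(2L, 2L, 2L))  # a triangle
  deg_d <- node_degree(one, "directed")
  expect_equal(deg_d$degree[deg_d$id == "m1"], 3L)  # m->t, t->m, m->g
  expect_equal(deg_d$degree[deg_d$id == "g1"], 2L)

  # self-loop: +1 collapsed, +2 directed
  self_net <- merge_motifs(tibble::tibble(mirna = "m1", tf = "t1",
                                          gene = "t1"))
  expect_equal(node_degree(self_net, "collapsed")$degree[
    node_degree(self_net)$id == "t1"], 2L)  # neighbour m1 + self-loop
  expect_equal(node_degree(self_net, "directed")$degree[
    node_degree(self_net)$id == "t1"], 4L)

  # adjacency-matrix oracle on a random network
  net <- random_network(12, 40, seed = 5)
  ids <- net$nodes$id
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(net$edges))) {
    A[net$edges$source[i], net$edges$target[i]] <- 1L
  }
  U <- 1L * ((A + t(A)) > 0)
  deg <- node_degree(net, "collapsed")
  expect_equal(deg$degree, unname(rowSums(U)[deg$id]))
})

test_that("betweenness follows the ordered-pair formula", {
  path3 <- structure(list(
    nodes = tibble::tibble(id = c("a", "b", "c"), role = "gene"),
    edges = tibble::tibble(source = c("a", "b"), target = c("b", "c"),
                           label = "reg"),
    stage = NA, n_motifs = NA_integer_), class = "reg_network")
  bc <- node_betweenness(path3)
  expect_equal(bc$betweenness[bc$id == "b"], 2)  # ordered pairs (a,c),(c,a)
  expect_equal(bc$betweenness[bc$id == "a"], 0)

  k4 <- structure(list(
    nodes = tibble::tibble(id = letters[1:4], role = "gene"),
    edges = tibble::tibble(
      source = c("a", "a", "a", "b", "b", "c"),
      target = c("b", "c", "d", "c", "d", "d"), label = "reg"),
    stage = NA, n_motifs = NA_integer_), class = "reg_network")
  expect_true(all(node_betweenness(k4)$betweenness == 0))
})

test_that("Brandes accumulation matches the exhaustive oracle and igraph", {
  for (seed in 1:8) {
    net <- random_network(n_nodes = 14, n_edges = 30, seed = seed)
    for (mode in c("undirected", "directed")) {
      fast <- node_betweenness(net, mode)
      slow <- oracle_betweenness(net, mode)
      expect_equal(fast$betweenness, slow$betweenness, tolerance = 1e-9)
    }
  }
  skip_if_not_installed("igraph")
  net <- random_network(15, 35, seed = 99)
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                     vertices = net$nodes$id)
  g <- igraph::simplify(g)
  ig <- igraph::betweenness(g, directed = FALSE)
  ours <- node_betweenness(net, "undirected")
  # igraph counts unordered pairs; the ordered-pair formula doubles it
  expect_equal(ours$betweenness, unname(2 * ig[ours$id]), tolerance = 1e-9)
})

test_that("hub calling keeps the top fraction with ties included", {
  deg <- tibble::tibble(id = sprintf("n%02d", 1:10), degree = 1:10)
  expect_setequal(call_hubs(deg, 0.2), c("n09", "n10"))
  all_equal <- tibble::tibble(id = c("a", "b", "c"), degree = 4L)
  expect_setequal(call_hubs(all_equal, 0.2), c("a", "b", "c"))
  expect_error(call_hubs(deg[0, ]), class = "ffldyn_input_error")
  # the maximum-degree node always qualifies
  set.seed(2)
  degr <- tibble::tibble(id = sprintf("x%d", 1:7),
                         degree = sample(1:20, 7))
  expect_true(degr$id[which.max(degr$degree)] %in% call_hubs(degr, 0.05))
})

test_that("centrality table joins degree, betweenness and hubs", {
  net <- merge_motifs(random_motifs(12, seed = 41), stage = 1)
  ct <- centrality_table(net)
  expect_setequal(ct$id, net$nodes$id)
  expect_true(all(c("degree", "betweenness", "hub") %in% names(ct)))
  # leaves of the undirected collapse have zero betweenness
  leaves <- ct$id[ct$degree == 1]
  expect_true(all(ct$betweenness[ct$id %in% leaves] == 0))
})
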