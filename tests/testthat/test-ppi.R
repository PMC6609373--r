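edge_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(node_a = m[, 1], node_b = m[, 2], stringsAsFactors = FALSE)
}

clique_edges <- function(ids) {
  cmb <- utils::combn(ids, 2)
  data.frame(node_a = cmb[1, ], node_b = cmb[2, ], stringsAsFactors = FALSE)
}

test_that("induced subnetworks drop outside nodes, isolates and self-loops", {
  tri <- edge_df("a", "b", "b", "c", "c", "a")
  g <- induce_subnetwork(tri, c("a", "b"))
  expect_equal(sort(igraph::V(g)$name), c("a", "b"))
  expect_equal(igraph::ecount(g), 1)

  empty <- induce_subnetwork(tri, c("x", "y"))
  expect_equal(igraph::vcount(empty), 0)

  loops <- rbind(tri, edge_df("a", "a"))
  g2 <- induce_subnetwork(loops, c("a", "b", "c", "z"))
  expect_equal(igraph::ecount(g2), 3)
  expect_equal(attr(g2, "n_self_loops_removed"), 1)
})

test_that("network_summary reports nodes, edges and mean neighbors", {
  tri <- induce_subnetwork(edge_df("a", "b", "b", "c", "c", "a"),
                           c("a", "b", "c"))
  expect_equal(network_summary(tri),
               list(n_nodes = 3, n_edges = 3, avg_neighbors = 2))
  star <- induce_subnetwork(edge_df("h", "l1", "h", "l2", "h", "l3",
                                    "h", "l4", "h", "l5", "h", "l6"),
                            c("h", paste0("l", 1:6)))
  expect_equal(network_summary(star)$avg_neighbors, round(12 / 7, 2))
  none <- induce_subnetwork(edge_df("a", "b"), "z")
  expect_equal(network_summary(none), list(n_nodes = 0, n_edges = 0,
                                           avg_neighbors = 0))
})

test_that("hubs are nodes with at least five neighbors", {
  path <- edge_df("n1", "n2", "n2", "n3", "n3", "n4", "n4", "n5", "n5", "n6",
                  "n6", "n7", "n7", "n8", "n8", "n9", "n9", "n10")
  g <- induce_subnetwork(path, paste0("n", 1:10))
  expect_equal(nrow(find_hubs(g)), 0)

  star <- induce_subnetwork(edge_df("h", "l1", "h", "l2", "h", "l3",
                                    "h", "l4", "h", "l5", "h", "l6"),
                            c("h", paste0("l", 1:6)))
  hubs <- find_hubs(star)
  expect_equal(hubs$gene, "h")
  expect_equal(hubs$degree, 6)

  six <- clique_edges(paste0("c", 1:6))
  sparse <- rbind(six, edge_df("c1", "x1", "x1", "x2", "x2", "x3"))
  g3 <- induce_subnetwork(sparse, c(paste0("c", 1:6), paste0("x", 1:3)))
  expect_setequal(find_hubs(g3)$gene, paste0("c", 1:6))
})

test_that("mcode scores the planted fixtures exactly", {
  # 6-clique plus a pendant: one module, the clique, score 6 after haircut
  fix <- rbind(clique_edges(paste0("c", 1:6)), edge_df("c1", "p"))
  g <- induce_subnetwork(fix, c(paste0("c", 1:6), "p"))
  mods <- mcode(g)
  expect_length(mods, 1)
  expect_equal(mods[[1]]$nodes, paste0("c", 1:6))
  expect_equal(mods[[1]]$score, 6)

  # a tree has no dense module
  set.seed(41)
  tree_edges <- data.frame(node_a = paste0("t", 2:20),
                           node_b = paste0("t", sapply(2:20, function(i)
                             sample(i - 1, 1))))
  gt <- induce_subnetwork(tree_edges, paste0("t", 1:20))
  expect_length(mcode(gt), 0)

  # two disjoint 5-cliques: two modules of score 5
  two <- rbind(clique_edges(paste0("a", 1:5)), clique_edges(paste0("b", 1:5)))
  g2 <- induce_subnetwork(two, c(paste0("a", 1:5), paste0("b", 1:5)))
  mods2 <- mcode(g2)
  expect_length(mods2, 2)
  expect_equal(vapply(mods2, `[[`, numeric(1), "score"), c(5, 5))
  expect_equal(mods2[[1]]$nodes, paste0("a", 1:5))

  expect_length(mcode(induce_subnetwork(edge_df("a", "b"), "z")), 0)
})

test_that("module scores recompute from their node sets and match the exhaustive oracle", {
  set.seed(43)
  for (i in 1:5) {
    # planted 5-clique plus sparse noise, <= 12 nodes total
    nodes <- c(paste0("k", 1:5), paste0("n", 1:6))
    edges <- clique_edges(paste0("k", 1:5))
    noise <- data.frame(node_a = sample(nodes, 6, TRUE),
                        node_b = sample(nodes, 6, TRUE))
    noise <- noise[noise$node_a != noise$node_b, ]
    g <- induce_subnetwork(rbind(edges, noise), nodes)
    mods <- mcode(g, mcode_params(score_min = 3))
    expect_gte(length(mods), 1)
    best <- oracle_best_module(g)
    expect_equal(mods[[1]]$score, best$score, tolerance = 1e-12)
    # score identity: density * n recomputed from the returned node set
    for (m in mods) {
      sub <- igraph::induced_subgraph(g, m$nodes)
      n <- length(m$nodes)
      expect_equal(m$score,
                   2 * igraph::ecount(sub) / (n * (n - 1)) * n,
                   tolerance = 1e-12)
    }
  }
})

test_that("mcode is invariant to node insertion order and modules are disjoint", {
  set.seed(44)
  fix <- rbind(clique_edges(paste0("a", 1:5)), clique_edges(paste0("b", 1:6)),
               edge_df("a1", "b1", "b2", "z1", "z1", "z2"))
  ids <- c(paste0("a", 1:5), paste0("b", 1:6), "z1", "z2")
  g1 <- induce_subnetwork(fix, ids)
  g2 <- induce_subnetwork(fix[sample(nrow(fix)), ], rev(ids))
  m1 <- mcode(g1)
  m2 <- mcode(g2)
  expect_equal(lapply(m1, `[[`, "nodes"), lapply(m2, `[[`, "nodes"))
  all_nodes <- unlist(lapply(m1, `[[`, "nodes"))
  expect_equal(anyDuplicated(all_nodes), 0)
  expect_true(all(vapply(m1, `[[`, numeric(1), "score") > 4))
})

test_that("the planted interaction clique is recovered across seeds", {
  hits <- 0
  for (seed in 1:20) {
    cfg <- sim_config(n_mrna = 120, n_lncrna = 5, n_circrna = 5,
                      n_mirna = 2, n_planted_triples = 0, module_size = 6,
                      rng_seed = seed)
    sim <- simulate_expression(cfg)
    ints <- simulate_interactions(cfg, sim$truth)
    g <- induce_subnetwork(ints$edges,
                           sim$truth$de_status$feature)
    mods <- mcode(g)
    if (length(mods) &&
        setequal(mods[[1]]$nodes, ints$truth$module_members)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("edge tables read with optional confidence filtering", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_a\tnode_b\tconfidence", "a\tb\t0.9", "b\tc\t0.2"), tf)
  expect_equal(nrow(read_edge_table(tf)), 2)
  expect_equal(read_edge_table(tf, min_confidence = 0.5)$node_a, "a")
  writeLines(c("a\tb", "b\tc"), tf)
  expect_equal(names(read_edge_table(tf))[1:2], c("node_a", "node_b"))
})
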