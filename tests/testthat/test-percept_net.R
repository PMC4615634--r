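test_that("graph construction keeps isolated descriptors and all co-occurrence weight", {
  C <- matrix(c(1L, 1L, 1L, 1L), 2, dimnames = list(c("a", "b"), c("a", "b")))
  g <- build_graph(C)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 1)

  A <- random_perceptual(120, 30, seed = 3)
  C2 <- cooccurrence(A)
  g2 <- build_graph(C2)
  expect_equal(igraph::vcount(g2), ncol(A))
  off <- C2; diag(off) <- 0L
  expect_equal(sum(igraph::E(g2)$weight), sum(off[upper.tri(off)]))

  # descriptor never co-occurring stays as an isolated node
  A3 <- rbind(c(1L, 1L, 0L), c(0L, 0L, 1L))
  dimnames(A3) <- list(c("m1", "m2"), c("a", "b", "solo"))
  g3 <- build_graph(cooccurrence(A3))
  expect_equal(igraph::degree(g3)[["solo"]], 0)
  expect_equal(igraph::vcount(g3), 3)
})

test_that("network summary matches closed forms and brute-force oracles", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  igraph::E(tri)$weight <- 1
  s <- summarize_network(tri, fit_strengths = FALSE)
  expect_equal(s$avg_weighted_degree, 2)
  expect_equal(s$diameter, 1)
  expect_equal(s$avg_path_length, 1)
  expect_equal(s$density, 1)
  expect_equal(s$clustering_avg, 1)

  # P4 assortativity is -0.5 (Pearson over the 6 oriented endpoint pairs)
  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  igraph::E(p4)$weight <- 1
  expect_equal(summarize_network(p4, fit_strengths = FALSE)$assortativity, -0.5)

  # 30-node random graph vs hand-rolled BFS / triangle counting / Pearson
  set.seed(7)
  adj <- matrix(0, 30, 30)
  adj[upper.tri(adj)] <- as.integer(runif(sum(upper.tri(adj))) < 0.12)
  adj <- adj + t(adj)
  dimnames(adj) <- list(sprintf("n%02d", 1:30), sprintf("n%02d", 1:30))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", weighted = TRUE)
  s <- summarize_network(g, fit_strengths = FALSE)
  D <- brute_distances(adj)
  comp <- igraph::components(g)
  in_giant <- comp$membership == which.max(comp$csize)
  Dg <- D[in_giant, in_giant]
  expect_equal(s$diameter, max(Dg))
  expect_equal(s$avg_path_length, mean(Dg[upper.tri(Dg)]))
  expect_equal(s$clustering_avg, mean(brute_clustering(adj)))
  expect_equal(s$assortativity, brute_assortativity(adj))

  expect_error(summarize_network(igraph::make_empty_graph(3, directed = FALSE)),
               "no edges")
})

test_that("regular graphs report assortativity as flagged undefined, not zero", {
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- paste0("r", 1:6)
  igraph::E(ring)$weight <- 1
  s <- summarize_network(ring, fit_strengths = FALSE)
  expect_true(is.na(s$assortativity))
  expect_false(s$assortativity_defined)
})

test_that("ER null ensemble behaves like its analytic expectations", {
  # complete graph: clustering exactly 1 with zero spread
  full <- er_null(8, 28, n_instances = 20, seed = 1)
  expect_equal(full$clustering_mean, 1)
  expect_equal(full$clustering_sd, 0)
  # degenerate sd flagged with p = 0 when the empirical value differs
  fl <- er_null(8, 28, n_instances = 20, cl_emp = 0.5, seed = 1)
  expect_true(fl$degenerate_sd)
  expect_equal(fl$p_value, 0)

  # dense G(n,m): mean clustering approaches (1 - P[deg<2]) * density
  nul <- er_null(60, 600, n_instances = 200, seed = 2)
  dens <- 600 / choose(60, 2)
  expect_lt(abs(nul$clustering_mean - dens), 0.01)

  # z-test wiring
  zt <- er_null(60, 600, n_instances = 200, cl_emp = 0.9, seed = 2)
  expect_gt(zt$z_score, 10)
  expect_lt(zt$p_value, 1e-10)

  # reproducible under seed
  expect_equal(er_null(40, 100, 50, seed = 9), er_null(40, 100, 50, seed = 9))
})

test_that("hub ranking sorts by strength with lexicographic ties", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("center", paste0("leaf", 1:5))
  igraph::E(star)$weight <- 1
  expect_identical(top_hubs(star, 1), "center")

  A <- random_perceptual(150, 25, seed = 13)
  g <- build_graph(cooccurrence(A))
  s <- node_strength(g)
  k <- igraph::vcount(g)
  full <- top_hubs(g, k)
  expect_setequal(full, igraph::V(g)$name)
  ord <- order(-s, names(s), method = "radix")
  expect_identical(full, names(s)[ord])
})

test_that("planted high-frequency descriptors dominate the hub ranking", {
  set.seed(21)
  hubs <- c("fruit", "floral", "sweet")
  rare <- sprintf("rare%02d", 1:15)
  recs <- lapply(1:200, function(i)
    unique(c(sample(hubs, 2), sample(rare, 2))))
  names(recs) <- sprintf("m%03d", 1:200)
  g <- build_graph(cooccurrence(build_perceptual_matrix(recs)))
  expect_setequal(top_hubs(g, 3), hubs)
})

test_that("Louvain communities recover clean structure and satisfy Q properties", {
  two <- igraph::disjoint_union(igraph::make_full_graph(5), igraph::make_full_graph(5))
  igraph::V(two)$name <- paste0("n", 1:10)
  cm <- detect_communities(two, seed = 1)
  expect_equal(cm$n_communities, 2)
  expect_equal(cm$modularity_q, 0.5)

  k2 <- igraph::make_graph(~ a - b)
  cm2 <- detect_communities(k2, seed = 1)
  expect_equal(cm2$n_communities, 1)
  expect_equal(cm2$modularity_q, 0)

  expect_error(detect_communities(igraph::make_empty_graph(3, directed = FALSE)),
               "edgeless")

  # merging partitions of two disconnected components never lowers Q
  g <- igraph::disjoint_union(
    igraph::delete_vertex_attr(planted_sbm(1, block = 10, nb = 2), "name"),
    igraph::delete_vertex_attr(planted_sbm(2, block = 10, nb = 2), "name"))
  igraph::V(g)$name <- paste0("w", seq_len(igraph::vcount(g)))
  whole <- detect_communities(g, seed = 3)
  sub1 <- detect_communities(igraph::induced_subgraph(g, 1:20), seed = 3)
  sub2 <- detect_communities(igraph::induced_subgraph(g, 21:40), seed = 3)
  merged <- c(sub1$membership, sub2$membership + max(sub1$membership))
  q_merged <- igraph::modularity(g, merged[igraph::V(g)$name])
  expect_gte(whole$modularity_q + 1e-9, q_merged)
})
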