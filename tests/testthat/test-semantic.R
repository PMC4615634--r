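test_that("windowed co-occurrence counts match hand-slid examples", {
  g <- build_semantic_network(c("a", "b", "c", "a", "b"), c("a", "b"), window = 2)
  df <- edge_weights_df(g)
  expect_equal(nrow(df), 1)
  expect_equal(df$weight, 2)
  expect_setequal(c(df$from, df$to), c("a", "b"))

  # vocabulary words never inside one window: found nodes but no edges
  g2 <- build_semantic_network(c("a", "x", "x", "x", "b"), c("a", "b"), window = 3)
  expect_equal(igraph::ecount(g2), 0)
  expect_setequal(igraph::V(g2)$name, c("a", "b"))

  expect_error(build_semantic_network(c("a", "b"), c("a", "b"), window = 1),
               "window")
})

test_that("windowed counts equal a brute-force double loop on random streams", {
  vocab <- c("fruit", "sweet", "green", "floral", "wood")
  for (win in 2:4) {
    set.seed(win * 100)
    tokens <- sample(c(vocab, sprintf("bg%02d", 1:10)), 600, replace = TRUE)
    g <- build_semantic_network(tokens, vocab, window = win)
    df <- edge_weights_df(g)
    brute <- brute_semantic_counts(tokens, vocab, win)
    expect_equal(nrow(df), length(brute))
    for (r in seq_len(nrow(df))) {
      key <- paste(sort(c(df$from[r], df$to[r])), collapse = "|")
      expect_equal(df$weight[r], brute[[key]])
    }
  }
})

test_that("matched subnetworks are exact induced subgraphs", {
  A <- random_perceptual(100, 20, seed = 17)
  g <- build_graph(cooccurrence(A))
  all_sub <- matched_subnetwork(g, igraph::V(g)$name)
  expect_equal(igraph::ecount(all_sub), igraph::ecount(g))

  e1 <- igraph::ends(g, 1)
  pair_sub <- matched_subnetwork(g, as.character(e1))
  expect_equal(igraph::ecount(pair_sub), 1)

  set.seed(2)
  sub_vocab <- sample(igraph::V(g)$name, 8)
  sub <- matched_subnetwork(g, sub_vocab)
  df_full <- edge_weights_df(g)
  expected <- df_full[df_full$from %in% sub_vocab & df_full$to %in% sub_vocab, ]
  df_sub <- edge_weights_df(sub)
  expect_equal(nrow(df_sub), nrow(expected))
  expect_equal(sort(df_sub$weight), sort(expected$weight))

  expect_error(matched_subnetwork(g, character()), "no overlap")
})

test_that("eigen similarity reproduces the K3-vs-P3 closed form and symmetry", {
  k3 <- igraph::make_full_graph(3)
  p3 <- igraph::make_graph(~ a - b, b - c)
  r <- eigen_similarity(k3, p3)
  expect_equal(r$lambda1, c(3, 3, 0), tolerance = 1e-10)
  expect_equal(r$lambda2, c(3, 1, 0), tolerance = 1e-10)
  expect_equal(r$k1, 2); expect_equal(r$k2, 2); expect_equal(r$k, 2)
  expect_equal(r$sim, 4, tolerance = 1e-10)
  expect_equal(eigen_similarity(p3, k3)$sim, r$sim)
})

test_that("self similarity is zero and spectra behave like Laplacians", {
  for (seed in 1:6) {
    set.seed(seed)
    g <- igraph::sample_gnp(12, 0.3)
    igraph::E(g)$weight <- sample(1:5, igraph::ecount(g), replace = TRUE)
    expect_equal(eigen_similarity(g, g)$sim, 0)
    lam <- eigen_similarity(g, g)$lambda1
    expect_true(all(lam > -1e-9))
    expect_lt(abs(min(lam)), 1e-9)
    # multiplicity of eigenvalue 0 = number of connected components
    expect_equal(sum(abs(lam) < 1e-9), igraph::components(g)$no)
  }
})

test_that("scaling both graphs' weights by c scales similarity by c^2", {
  set.seed(4)
  g1 <- igraph::sample_gnp(10, 0.4); igraph::E(g1)$weight <- sample(1:4, igraph::ecount(g1), TRUE)
  g2 <- igraph::sample_gnp(10, 0.4); igraph::E(g2)$weight <- sample(1:4, igraph::ecount(g2), TRUE)
  base <- eigen_similarity(g1, g2)
  g1c <- g1; igraph::E(g1c)$weight <- igraph::E(g1)$weight * 3
  g2c <- g2; igraph::E(g2c)$weight <- igraph::E(g2)$weight * 3
  scaled <- eigen_similarity(g1c, g2c)
  expect_equal(scaled$sim, 9 * base$sim, tolerance = 1e-8)
})

test_that("window size maps from average descriptors per molecule", {
  expect_equal(window_for_ap_m(1.72), 2)
  expect_equal(window_for_ap_m(2.60), 3)
  expect_equal(window_for_ap_m(3.51), 4)
  expect_equal(window_for_ap_m(9.9), 4)
  expect_equal(window_for_ap_m(0.4), 2)
})
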