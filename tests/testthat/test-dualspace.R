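test_that("feature preprocessing drops degenerate columns and min-max scales", {
  raw <- cbind(const = rep(2, 3), good = c(2, 4, 6), holey = c(1, NA, 3))
  rownames(raw) <- paste0("m", 1:3)
  X <- preprocess_features(raw)
  expect_identical(colnames(X), "good")
  expect_equal(unname(X[, "good"]), c(0, 0.5, 1))
  expect_setequal(attr(X, "dropped"), c("const", "holey"))
  expect_error(preprocess_features(cbind(a = rep(1, 4))), "survive")

  # DRAGON-shaped table: 1666 columns, 177 degenerate -> 1489 retained
  set.seed(30)
  big <- matrix(rnorm(60 * 1489), 60, 1489)
  colnames(big) <- sprintf("p%04d", 1:1489)
  bad <- matrix(rnorm(60 * 177), 60, 177)
  bad[cbind(sample(60, 90, TRUE), 1:90)] <- NA
  bad[, 91:177] <- 7
  colnames(bad) <- sprintf("bad%03d", 1:177)
  full <- cbind(big, bad)[, sample(1666)]
  rownames(full) <- sprintf("m%02d", 1:60)
  kept <- preprocess_features(full)
  expect_equal(ncol(kept), 1489)
  expect_true(all(kept >= 0 & kept <= 1))
})

test_that("perceptual similarity counts shared descriptors", {
  A <- rbind(m1 = c(1L, 1L, 0L), m2 = c(1L, 1L, 0L), m3 = c(0L, 0L, 1L))
  colnames(A) <- c("a", "b", "c")
  S <- perceptual_similarity(A)
  expect_equal(S["m1", "m2"], 2L)  # identical sets of size 2
  expect_equal(S["m1", "m3"], 0L)  # disjoint sets

  Ar <- random_perceptual(80, 20, seed = 12)
  Sr <- perceptual_similarity(Ar)
  for (pair in list(c(1, 2), c(3, 10), c(20, 40))) {
    i <- pair[1]; j <- pair[2]
    expect_equal(Sr[i, j], sum(Ar[i, ] & Ar[j, ]))
  }
  expect_identical(Sr, t(Sr))
})

test_that("locally scaled similarity reproduces the collinear worked case", {
  W <- local_scaled_similarity(matrix(c(0, 1, 3), ncol = 1), k_neighbor = 1)
  expect_equal(W[1, 2], exp(-1))
  expect_equal(W[2, 3], exp(-2))
  expect_equal(W[1, 3], exp(-9 / 2))
  expect_equal(diag(W), rep(1, 3), ignore_attr = TRUE)
  expect_identical(W, t(W))

  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  W2 <- local_scaled_similarity(X, 4)
  expect_identical(W2, t(W2))
  expect_true(all(is.finite(W2)))

  expect_warning(local_scaled_similarity(matrix(0, 6, 2), 2), "bandwidth")
})

test_that("spectral X-means finds planted cluster counts", {
  set.seed(1)
  X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 10), 30),
             matrix(rnorm(60, 20), 30))
  cl <- spectral_xmeans(local_scaled_similarity(X, 7), k_max = 10, seed = 1)
  expect_equal(cl$k, 3)
  expect_equal(hubert_index(cl$labels, rep(1:3, each = 30))$hubert_index, 1)

  Sb <- matrix(0.01, 40, 40)
  Sb[1:20, 1:20] <- 1; Sb[21:40, 21:40] <- 1; diag(Sb) <- 1
  expect_equal(spectral_xmeans(Sb, k_max = 8, seed = 1)$k, 2)

  Si <- suppressWarnings(local_scaled_similarity(matrix(0, 10, 2), 3))
  expect_equal(spectral_xmeans(Si, k_max = 5, seed = 1)$k, 1)

  expect_error(spectral_xmeans(Sb, k_max = 1), "k_max")
  # deterministic given (S, k_max, seed)
  expect_identical(spectral_xmeans(Sb, k_max = 8, seed = 7),
                   spectral_xmeans(Sb, k_max = 8, seed = 7))
})

test_that("Hubert index counts pair agreements", {
  r <- hubert_index(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(r$hubert_index, 1 / 3)
  expect_equal(r$both_same + r$both_different + r$discordant, 6)

  expect_equal(hubert_index(c(1, 2, 1, 3), c(1, 2, 1, 3))$hubert_index, 1)
  expect_equal(hubert_index(c(1, 1), c(1, 2))$hubert_index, 0)
  expect_error(hubert_index(1:3, 1:4), "equal length")

  for (seed in 1:4) {
    set.seed(seed)
    l1 <- sample(1:4, 25, TRUE); l2 <- sample(1:3, 25, TRUE)
    r <- hubert_index(l1, l2)
    expect_equal(r$hubert_index, brute_hubert(l1, l2))
    # symmetry and label-permutation invariance
    expect_equal(hubert_index(l2, l1)$hubert_index, r$hubert_index)
    expect_equal(hubert_index(5 - l1, l2)$hubert_index, r$hubert_index)
  }
})

test_that("random independent partitions sit near the combinatorial baseline", {
  set.seed(42)
  his <- replicate(60, {
    l1 <- sample(1:3, 80, TRUE); l2 <- sample(1:4, 80, TRUE)
    hubert_index(l1, l2)$hubert_index
  })
  p1 <- 1 / 3; p2 <- 1 / 4
  expected <- p1 * p2 + (1 - p1) * (1 - p2)
  expect_lt(abs(mean(his) - expected), 0.02)
})
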