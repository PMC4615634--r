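# fixtures and independent brute-force oracles shared across test files

random_records <- function(n_mol, descriptors, seed, max_len = 6) {
  set.seed(seed)
  recs <- lapply(seq_len(n_mol), function(i)
    sample(descriptors, sample.int(max_len, 1)))
  names(recs) <- sprintf("mol%04d", seq_len(n_mol))
  recs
}

random_perceptual <- function(n_mol, n_desc, seed, density = 0.1) {
  set.seed(seed)
  A <- matrix(as.integer(runif(n_mol * n_desc) < density), n_mol, n_desc,
              dimnames = list(sprintf("m%04d", seq_len(n_mol)),
                              sprintf("d%03d", seq_len(n_desc))))
  A <- A[rowSums(A) > 0, colSums(A) > 0, drop = FALSE]
  A
}

# brute-force corpus stats by explicit double loop
brute_stats <- function(A) {
  total <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) total <- total + A[i, j]
  list(ap_m = total / nrow(A), am_p = total / ncol(A),
       sparseness_pct = (1 - total / (nrow(A) * ncol(A))) * 100)
}

# brute-force co-occurrence: count molecules having both descriptors
brute_cooc <- function(A) {
  p <- ncol(A)
  C <- matrix(0L, p, p, dimnames = list(colnames(A), colnames(A)))
  for (i in seq_len(p)) for (j in seq_len(p))
    C[i, j] <- sum(A[, i] == 1 & A[, j] == 1)
  C
}

# all-pairs shortest paths by hand-rolled BFS on an adjacency matrix
brute_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] > 0))))
      nxt <- nxt[D[s, nxt] == Inf & nxt != s]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# per-node unweighted local clustering by triangle counting; deg<2 -> 0
brute_clustering <- function(adj) {
  adj <- (adj > 0) * 1
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# assortativity as Pearson correlation over both orientations of each edge
brute_assortativity <- function(adj) {
  deg <- rowSums(adj > 0)
  ends <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  xs <- c(deg[ends[, 1]], deg[ends[, 2]])
  ys <- c(deg[ends[, 2]], deg[ends[, 1]])
  suppressWarnings(stats::cor(xs, ys))
}

# brute-force windowed co-occurrence counting (independent of the package
# implementation: explicit double loop over anchor/offset)
brute_semantic_counts <- function(tokens, vocab, window) {
  counts <- list()
  n <- length(tokens)
  for (i in seq_len(n)) {
    if (!(tokens[i] %in% vocab)) next
    seen <- character(0)
    for (off in seq_len(window - 1)) {
      j <- i + off
      if (j > n) break
      w <- tokens[j]
      if (w %in% vocab && w != tokens[i] && !(w %in% seen)) {
        seen <- c(seen, w)
        key <- paste(sort(c(tokens[i], w)), collapse = "|")
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force pair agreement
brute_hubert <- function(l1, l2) {
  n <- length(l1); agree <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    agree <- agree + ((l1[i] == l1[j]) == (l2[i] == l2[j]))
  }
  agree / tot
}

edge_weights_df <- function(g) {
  df <- igraph::as_data_frame(g, what = "edges")
  if (!"weight" %in% names(df)) df$weight <- 1
  df[order(df$from, df$to), ]
}

planted_sbm <- function(seed, p_in = 0.3, p_out = 0.01, block = 25, nb = 4) {
  set.seed(seed)
  P <- matrix(p_out, nb, nb); diag(P) <- p_in
  g <- igraph::sample_sbm(nb * block, P, rep(block, nb))
  igraph::V(g)$name <- sprintf("v%03d", seq_len(nb * block))
  g
}

separable_dataset <- function(seed, n_per = 50, k = 3, n_inf = 10, n_noise = 50,
                              sep = 5) {
  set.seed(seed)
  y <- rep(seq_len(k), each = n_per)
  mu <- matrix(stats::rnorm(k * n_inf), k, n_inf) * sep
  X <- cbind(mu[y, ] + matrix(stats::rnorm(k * n_per * n_inf), ncol = n_inf),
             matrix(stats::rnorm(k * n_per * n_noise), ncol = n_noise))
  colnames(X) <- c(sprintf("inf%02d", seq_len(n_inf)),
                   sprintf("noise%02d", seq_len(n_noise)))
  list(X = X, y = y)
}
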