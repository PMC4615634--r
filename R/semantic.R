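#' Build a windowed bag-of-words semantic co-occurrence network
#'
#' Scans an ordered token stream with a forward-looking window: at every
#' position holding a vocabulary word (the anchor), each distinct vocabulary
#' word among the following `window - 1` positions increments the weight of
#' the anchor-word pair by 1. Self-pairs are never counted. Nodes are the
#' vocabulary words found in the stream, so a word that occurs but never
#' co-occurs is an isolated node.
#'
#' @param tokens character vector of lowercase tokens (no whitespace inside
#'   a token).
#' @param vocabulary descriptor set to restrict the network to (e.g. the
#'   columns of a perceptual matrix).
#' @param window window size, `>= 2`; a window of w pairs each anchor with
#'   the next w - 1 positions.
#' @return undirected weighted `igraph` graph on the found vocabulary.
#' @export
build_semantic_network <- function(tokens, vocabulary, window = 2L) {
  stopifnot(is.character(tokens), length(tokens) > 0)
  if (window < 2) stop("window must be >= 2")
  vocabulary <- unique(tolower(vocabulary))
  hit <- tokens %in% vocabulary
  found <- sort(unique(tokens[hit]), method = "radix")
  n <- length(tokens)
  pairs <- vector("list", 0L)
  anchors <- which(hit)
  for (i in anchors) {
    upto <- min(n, i + window - 1L)
    if (upto <= i) next
    ahead <- tokens[(i + 1L):upto]
    ahead <- unique(ahead[ahead %in% vocabulary & ahead != tokens[i]])
    if (length(ahead))
      pairs[[length(pairs) + 1L]] <-
        cbind(pmin(tokens[i], ahead), pmax(tokens[i], ahead))
  }
  g <- igraph::make_empty_graph(n = length(found), directed = FALSE)
  igraph::V(g)$name <- found
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    key <- paste(pm[, 1], pm[, 2], sep = "\r")
    w <- table(key)
    ends <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    g <- igraph::add_edges(g, t(matrix(match(ends, found), ncol = 2)))
    igraph::E(g)$weight <- as.integer(w)
  }
  g
}

#' Induced odour subnetwork on a matched vocabulary
#'
#' Restricts an odour co-occurrence network to the descriptors that were
#' also found in a text corpus, so the two networks share the same node set
#' for a fair comparison. Edge weights are preserved.
#'
#' @param g_odour weighted igraph odour network.
#' @param found_vocab character vector, subset of the network's node names.
#' @return induced weighted subgraph.
#' @export
matched_subnetwork <- function(g_odour, found_vocab) {
  found_vocab <- unique(found_vocab)
  if (!length(found_vocab)) stop("no overlap between corpus and odour vocabulary")
  missing <- setdiff(found_vocab, igraph::V(g_odour)$name)
  if (length(missing))
    stop("found_vocab contains nodes absent from the odour network: ",
         paste(utils::head(missing, 5), collapse = ", "))
  igraph::induced_subgraph(g_odour, found_vocab)
}

graph_laplacian_eigenvalues <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(
    g, attr = if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL,
    sparse = TRUE))
  if (sum(A) == 0) stop("graph has zero total edge weight")
  L <- diag(rowSums(A), nrow = nrow(A)) - A
  sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
}

#' Laplacian eigen-similarity of two graphs
#'
#' Compares two weighted graphs through the spectra of their Laplacians
#' \eqn{L = D - A}. Eigenvalues are sorted in decreasing order; for each
#' graph, \eqn{k_j} is the smallest number of leading eigenvalues holding
#' more than 90% of the spectral energy, and with \eqn{k = \min(k_1, k_2)}
#' the similarity is \eqn{sim = \sum_{i=1}^k (\lambda_{1i} -
#' \lambda_{2i})^2}. The measure is unbounded in \eqn{[0, \infty)}; 0 means
#' the leading spectra coincide (graphs look identical at this resolution).
#'
#' @param g1,g2 non-empty weighted igraph graphs with positive total edge
#'   weight.
#' @param energy spectral energy fraction defining k (default 0.9).
#' @return list of class `eigen_similarity`: `sim`, `k`, `k1`, `k2`,
#'   `lambda1`, `lambda2`.
#' @export
eigen_similarity <- function(g1, g2, energy = 0.9) {
  l1 <- graph_laplacian_eigenvalues(g1)
  l2 <- graph_laplacian_eigenvalues(g2)
  k_of <- function(l) which(cumsum(l) / sum(l) > energy)[1]
  k1 <- k_of(l1); k2 <- k_of(l2)
  k <- min(k1, k2)
  structure(list(
    sim = sum((l1[seq_len(k)] - l2[seq_len(k)])^2),
    k = k, k1 = k1, k2 = k2, lambda1 = l1, lambda2 = l2
  ), class = "eigen_similarity")
}

#' @export
print.eigen_similarity <- function(x, ...) {
  cat(sprintf("Eigen similarity: %.4g (k = %d; k1 = %d, k2 = %d)\n",
              x$sim, x$k, x$k1, x$k2))
  invisible(x)
}

#' Map a corpus' descriptor load to a co-occurrence window size
#'
#' Window sizes follow the average number of perceptual descriptors per
#' molecule in the dataset being compared: the average is rounded to the
#' nearest integer and clamped to the 2-4 range used for bag-of-words
#' scanning.
#'
#' @param ap_m average descriptors per molecule (from [matrix_stats()]).
#' @return integer window in `{2, 3, 4}`.
#' @export
window_for_ap_m <- function(ap_m) {
  as.integer(min(4L, max(2L, round(ap_m))))
}
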