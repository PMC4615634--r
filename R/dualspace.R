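#' Preprocess a physico-chemical feature table
#'
#' Drops columns containing any missing value and columns with zero
#' variance, then min-max scales every remaining column to [0, 1] — the
#' standard preparation of DRAGON-style descriptor exports before
#' similarity computations.
#'
#' @param raw numeric matrix or data.frame, molecules x features, with
#'   molecule ids as rownames.
#' @return numeric matrix in [0, 1] with attribute `dropped` listing removed
#'   column names.
#' @export
preprocess_features <- function(raw) {
  X <- as.matrix(raw)
  storage.mode(X) <- "double"
  if (is.null(rownames(X))) rownames(X) <- seq_len(nrow(X))
  has_na <- apply(X, 2, anyNA)
  rng <- apply(X, 2, function(v) if (anyNA(v)) 0 else diff(range(v)))
  keep <- !has_na & rng > 0
  if (!any(keep)) stop("no feature columns survive preprocessing")
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  X <- apply(X, 2, function(v) (v - min(v)) / (max(v) - min(v)))
  rownames(X) <- rownames(raw)
  attr(X, "dropped") <- dropped
  X
}

#' Perceptual similarity between molecules
#'
#' Shared-descriptor counts \eqn{A A^T}: entry (i, j) is the number of
#' descriptors applied to both molecule i and molecule j — the
#' molecule-level analogue of the descriptor co-occurrence matrix.
#'
#' @param A perceptual matrix.
#' @return symmetric integer similarity matrix with molecule dimnames.
#' @export
perceptual_similarity <- function(A) {
  stopifnot_perceptual(A)
  S <- tcrossprod(A)
  storage.mode(S) <- "integer"
  S
}

#' Locally scaled Gaussian similarity
#'
#' Self-tuning similarity kernel: \eqn{w_{ij} = \exp(-d_{ij}^2 / (\sigma_i
#' \sigma_j))} with Euclidean distances d and per-point bandwidth
#' \eqn{\sigma_i} equal to the distance from point i to its
#' `k_neighbor`-th nearest neighbour. The diagonal is 1. Duplicated points
#' can make a bandwidth zero; it is then floored at machine epsilon with a
#' warning.
#'
#' @param X numeric feature matrix (rows = molecules).
#' @param k_neighbor which neighbour sets the local scale (default 7).
#' @return symmetric similarity matrix in (0, 1].
#' @export
local_scaled_similarity <- function(X, k_neighbor = 7L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k_neighbor >= n) stop("k_neighbor must be smaller than the number of molecules")
  D <- as.matrix(stats::dist(X))
  # k-th nearest excluding self = (k+1)-th smallest including the 0 self-distance
  sigma <- apply(D, 1, function(d) sort(d)[k_neighbor + 1])
  if (any(sigma == 0)) {
    warning("zero local bandwidth from duplicated points; flooring at machine epsilon")
    sigma[sigma == 0] <- .Machine$double.eps
  }
  W <- exp(-D^2 / outer(sigma, sigma))
  diag(W) <- 1
  dimnames(W) <- list(rownames(X), rownames(X))
  W
}

#' Diagonal-Gaussian BIC of a k-means solution
#'
#' Gaussian-mixture BIC with per-cluster axis-aligned (diagonal)
#' covariances, mixture weights from cluster sizes, and
#' (k - 1) + 2 k d free parameters. The diagonal form is what keeps model
#' selection honest on spectral embeddings, whose within-cluster spread is
#' strongly anisotropic (smooth diffusion harmonics concentrate residual
#' variance in a few directions); a pooled spherical variance lets any
#' split of such a direction inflate the likelihood across all d
#' dimensions and over-splits badly. Larger is better.
#'
#' @keywords internal
kmeans_bic <- function(X, labels, centers) {
  n <- nrow(X); d <- ncol(X); k <- nrow(centers)
  if (n <= k) return(-Inf)
  ll <- 0
  for (j in seq_len(k)) {
    idx <- labels == j
    nj <- sum(idx)
    if (nj == 0) next
    v <- pmax(colMeans((X[idx, , drop = FALSE] -
                          matrix(centers[j, ], nj, d, byrow = TRUE))^2), 1e-9)
    ll <- ll + nj * log(nj / n) - nj / 2 * sum(log(2 * pi * v)) - nj * d / 2
  }
  p <- (k - 1) + 2 * k * d
  ll - p / 2 * log(n)
}

xmeans_embedded <- function(E, k_max, seed) {
  set.seed(seed)
  n <- nrow(E)
  fits <- vector("list", k_max)
  bics <- numeric(k_max)
  for (k in seq_len(k_max)) {
    fits[k] <- list(if (k == 1) {
      list(cluster = rep(1L, n), centers = matrix(colMeans(E), nrow = 1))
    } else {
      km <- tryCatch(
        suppressWarnings(stats::kmeans(E, centers = k, nstart = 10,
                                       iter.max = 50)),
        error = function(e) NULL)   # k exceeds distinct points
      if (is.null(km)) NULL else list(cluster = km$cluster, centers = km$centers)
    })
    bics[k] <- if (is.null(fits[[k]])) -Inf else
      kmeans_bic(E, fits[[k]]$cluster, fits[[k]]$centers)
  }
  best <- which.max(bics)
  list(labels = fits[[best]]$cluster, k = best,
       bic_trace = data.frame(k = seq_len(k_max), bic = bics))
}

#' Spectral clustering with X-means/BIC model selection
#'
#' Embeds the molecules with the symmetric-normalised Laplacian of a
#' similarity matrix (top `k_max` eigenvectors of
#' \eqn{D^{-1/2} S D^{-1/2}}), weights each eigenvector by its eigenvalue
#' raised to `diffusion_power` — a diffusion-map damping that keeps the
#' near-unit eigendirections carrying cluster structure while shrinking
#' within-cluster noise directions — row-normalises to unit length, and
#' clusters the embedding X-means style: every cluster count from 1 to
#' `k_max` is fitted by k-means (10 restarts) and scored with a
#' diagonal-Gaussian BIC, and the reported model is the k with the best
#' BIC; the whole (k, BIC) trace is returned.
#'
#' @param S symmetric non-negative similarity matrix.
#' @param k_max largest admissible number of clusters (default 20).
#' @param diffusion_power exponent applied to the embedding eigenvalues
#'   (default 8; 0 recovers the unweighted eigenvector embedding).
#' @param seed integer RNG seed; results are deterministic given
#'   `(S, k_max, seed)`.
#' @return list of class `clustering_result`: `labels` (named, ids 1..k),
#'   `k`, `bic_trace` (data.frame of visited k and BIC), `seed`.
#' @export
spectral_xmeans <- function(S, k_max = 20L, diffusion_power = 8, seed = 1L) {
  S <- as.matrix(S)
  n <- nrow(S)
  stopifnot(n == ncol(S), isTRUE(all.equal(unname(S), unname(t(S)))))
  if (k_max < 2) stop("k_max must be >= 2")
  if (k_max >= n) stop("k_max must be smaller than the number of molecules")
  d <- rowSums(S)
  d[d <= 0] <- .Machine$double.eps
  M <- S / sqrt(outer(d, d))
  eig <- eigen(M, symmetric = TRUE)
  lam <- pmax(eig$values[seq_len(k_max)], 0)
  E <- eig$vectors[, seq_len(k_max), drop = FALSE] %*%
    diag(lam^diffusion_power, nrow = k_max)
  len <- sqrt(rowSums(E^2))
  len[len == 0] <- 1
  E <- E / len
  fit <- xmeans_embedded(E, k_max, seed)
  labels <- fit$labels
  # relabel so that ids are 1..k in order of first appearance (deterministic)
  labels <- match(labels, unique(labels))
  names(labels) <- rownames(S)
  structure(list(labels = labels, k = length(unique(labels)),
                 bic_trace = fit$bic_trace, seed = seed),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("Spectral/X-means clustering: k = %d over %d molecules (seed %d)\n",
              x$k, length(x$labels), x$seed))
  invisible(x)
}

#' Hubert pair-agreement index between two partitions
#'
#' Over all unordered molecule pairs, counts pairs placed in the same
#' cluster by both partitions, in different clusters by both, and treated
#' discordantly; the index is the concordant fraction (the Rand form of
#' pair agreement). 0 is least overlap, 1 is perfect agreement.
#'
#' @param labels1,labels2 equal-length cluster label vectors aligned by
#'   molecule.
#' @return list of class `cluster_concordance`: `hubert_index`,
#'   `both_same`, `both_different`, `discordant`, `n_pairs`.
#' @export
hubert_index <- function(labels1, labels2) {
  if (length(labels1) != length(labels2))
    stop("label vectors must have equal length")
  n <- length(labels1)
  if (n < 2) stop("need at least two molecules")
  same1 <- outer(labels1, labels1, "==")[upper.tri(diag(n))]
  same2 <- outer(labels2, labels2, "==")[upper.tri(diag(n))]
  both_same <- sum(same1 & same2)
  both_diff <- sum(!same1 & !same2)
  n_pairs <- n * (n - 1) / 2
  structure(list(hubert_index = (both_same + both_diff) / n_pairs,
                 both_same = both_same, both_different = both_diff,
                 discordant = n_pairs - both_same - both_diff,
                 n_pairs = n_pairs),
            class = "cluster_concordance")
}

#' @export
print.cluster_concordance <- function(x, ...) {
  cat(sprintf("Hubert index %.3f (%d same/same, %d diff/diff, %d discordant of %d pairs)\n",
              x$hubert_index, x$both_same, x$both_different, x$discordant,
              x$n_pairs))
  invisible(x)
}
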