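#' Build the weighted descriptor co-occurrence graph
#'
#' Nodes are all descriptors (isolated descriptors are kept); an undirected
#' edge joins descriptors i and j with integer weight `C[i, j]` for every
#' positive off-diagonal entry of the co-occurrence matrix.
#'
#' @param C symmetric co-occurrence matrix from [cooccurrence()].
#' @return an undirected `igraph` graph with an integer `weight` edge
#'   attribute and no self-loops.
#' @export
build_graph <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C),
            isTRUE(all.equal(unname(C), unname(t(C)))))
  if (is.null(colnames(C))) colnames(C) <- rownames(C) <- paste0("d", seq_len(ncol(C)))
  diag(C) <- 0
  igraph::graph_from_adjacency_matrix(C, mode = "undirected", weighted = TRUE)
}

#' Node strengths (weighted degrees)
#'
#' @param g weighted igraph graph.
#' @return named numeric vector of weighted degrees; unweighted graphs fall
#'   back to plain degree.
#' @export
node_strength <- function(g) {
  w <- igraph::E(g)$weight
  igraph::strength(g, weights = if (is.null(w)) rep(1, igraph::ecount(g)) else w)
}

avg_local_clustering <- function(g) {
  # unweighted local clustering; degree < 2 counts as 0 and stays in the mean
  mean(igraph::transitivity(g, type = "local", isolates = "zero"))
}

#' Summarise a descriptor network
#'
#' Computes the standard characterisation bundle of an odour co-occurrence
#' network: node count, total edge weight, average weighted degree
#' (2 * sum of weights / n), unweighted edge count, diameter and average
#' path length (unweighted hops on the largest connected component), graph
#' density (unweighted), average local clustering coefficient (unweighted;
#' nodes of degree < 2 contribute 0), degree assortativity (Pearson
#' correlation of endpoint degrees over both edge orientations; undefined on
#' regular graphs and then reported as `NA` with `assortativity_defined =
#' FALSE`), and a discrete power-law fit to the node strengths.
#'
#' @param g weighted igraph graph with at least 2 nodes and 1 edge.
#' @param fit_strengths logical; fit the power law to node strengths
#'   (skipped automatically when the strength distribution is degenerate).
#' @return list of class `network_summary`.
#' @export
summarize_network <- function(g, fit_strengths = TRUE) {
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  if (n < 2) stop("graph must have at least 2 nodes")
  if (igraph::ecount(g) == 0) stop("no edges")
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  deg <- igraph::degree(g)
  r <- if (stats::sd(deg) == 0) NA_real_ else igraph::assortativity_degree(g)
  strengths <- node_strength(g)
  pl <- NULL
  if (fit_strengths) {
    s <- strengths[strengths > 0]
    if (length(s) >= 10 && length(unique(s)) > 1)
      pl <- fit_power_law(round(s))
  }
  structure(list(
    n_nodes = n,
    weighted_edge_total = sum(w),
    avg_weighted_degree = 2 * sum(w) / n,
    n_unweighted_edges = igraph::ecount(g),
    diameter = igraph::diameter(giant, weights = NA),
    avg_path_length = igraph::mean_distance(giant, weights = NA),
    density = igraph::ecount(g) / (n * (n - 1) / 2),
    clustering_avg = avg_local_clustering(g),
    assortativity = r,
    assortativity_defined = !is.na(r),
    powerlaw = pl
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Descriptor network: %d nodes, %d edges (total weight %s)\n",
           "  avg weighted degree %.2f | density %.3f | diameter %d | ",
           "avg path %.2f\n  clustering %.3f | assortativity %s\n"),
    x$n_nodes, x$n_unweighted_edges, format(x$weighted_edge_total),
    x$avg_weighted_degree, x$density, x$diameter, x$avg_path_length,
    x$clustering_avg,
    if (x$assortativity_defined) sprintf("%.3f", x$assortativity)
    else "undefined (regular graph)"))
  if (!is.null(x$powerlaw))
    cat(sprintf("  power law: alpha %.2f, x_min %d (KS %.3f, n_tail %d)\n",
                x$powerlaw$alpha, x$powerlaw$x_min,
                x$powerlaw$ks_statistic, x$powerlaw$n_tail))
  invisible(x)
}

#' Erdős–Rényi G(n, m) clustering-coefficient null ensemble
#'
#' Generates `n_instances` independent G(n, m) graphs, records each graph's
#' average local clustering coefficient (degree < 2 nodes counted as 0 and
#' kept in the denominator), and, when an empirical clustering value is
#' supplied, reports a two-sided z-test of that value against the simulated
#' null mean and standard deviation.
#'
#' @param n node count.
#' @param m edge count, `0 <= m <= n(n-1)/2`.
#' @param n_instances ensemble size (the reference analysis uses 1000).
#' @param cl_emp optional empirical average clustering coefficient to test.
#' @param seed integer RNG seed.
#' @return list of class `er_null` with `clustering_mean`, `clustering_sd`,
#'   and when `cl_emp` is given `z_score`, `p_value` and `degenerate_sd`
#'   (TRUE when sd = 0 forced p to 0).
#' @export
er_null <- function(n, m, n_instances = 1000, cl_emp = NULL, seed = 1L) {
  stopifnot(n >= 2, m >= 0, m <= n * (n - 1) / 2, n_instances >= 2)
  set.seed(seed)
  cls <- vapply(seq_len(n_instances), function(i)
    avg_local_clustering(igraph::sample_gnm(n, m)), numeric(1))
  out <- list(n = n, m = m, n_instances = n_instances,
              clustering_mean = mean(cls), clustering_sd = stats::sd(cls))
  if (!is.null(cl_emp)) {
    if (out$clustering_sd == 0) {
      out$degenerate_sd <- TRUE
      out$z_score <- if (cl_emp == out$clustering_mean) 0 else Inf * sign(cl_emp - out$clustering_mean)
      out$p_value <- if (cl_emp == out$clustering_mean) 1 else 0
    } else {
      out$degenerate_sd <- FALSE
      out$z_score <- (cl_emp - out$clustering_mean) / out$clustering_sd
      out$p_value <- 2 * stats::pnorm(-abs(out$z_score))
    }
    out$cl_emp <- cl_emp
  }
  structure(out, class = "er_null")
}

#' @export
print.er_null <- function(x, ...) {
  cat(sprintf("G(%d, %d) null, %d instances: clustering %.4f +/- %.4f\n",
              x$n, x$m, x$n_instances, x$clustering_mean, x$clustering_sd))
  if (!is.null(x$z_score))
    cat(sprintf("  empirical %.4f: z = %.2f, two-sided p = %.3g%s\n",
                x$cl_emp, x$z_score, x$p_value,
                if (isTRUE(x$degenerate_sd)) " (degenerate null sd)" else ""))
  invisible(x)
}

#' Top hub descriptors by weighted degree
#'
#' @param g weighted igraph graph.
#' @param k number of hubs to return, `k <= vcount(g)`.
#' @return character vector of node names, strongest first; ties broken
#'   lexicographically.
#' @export
top_hubs <- function(g, k = 10L) {
  stopifnot(k <= igraph::vcount(g))
  s <- node_strength(g)
  nm <- names(s)
  nm[order(-s, nm, method = "radix")][seq_len(k)]
}

#' Louvain community detection with restarts
#'
#' Runs weighted Louvain modularity maximisation at a given resolution.
#' Because the algorithm's greedy sweep depends on vertex order, the graph's
#' vertices are randomly permuted on each of `restarts` runs (under a
#' recorded seed) and the partition with the highest weighted modularity is
#' kept.
#'
#' @param g weighted igraph graph with at least one edge.
#' @param resolution resolution parameter of the modularity objective
#'   (default 1, the classical Newman-Girvan modularity).
#' @param seed integer RNG seed.
#' @param restarts number of randomised restarts.
#' @return list of class `community_partition` with `membership` (named
#'   integer vector, community ids 1..k), `modularity_q`, `n_communities`,
#'   `resolution`, `seed`.
#' @export
detect_communities <- function(g, resolution = 1, seed = 1L, restarts = 10L) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::ecount(g) == 0) stop("cannot detect communities in an edgeless graph")
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  set.seed(seed)
  n <- igraph::vcount(g)
  best <- NULL
  for (r in seq_len(restarts)) {
    perm <- sample.int(n)
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight,
                                  resolution = resolution)
    # permute() sends original vertex i to gp vertex perm[i]
    memb <- as.integer(igraph::membership(cl))[perm]
    q <- igraph::modularity(g, memb, weights = w, resolution = resolution)
    if (is.null(best) || q > best$modularity_q)
      best <- list(membership = memb, modularity_q = q)
  }
  names(best$membership) <- igraph::V(g)$name
  structure(list(membership = best$membership,
                 modularity_q = best$modularity_q,
                 n_communities = length(unique(best$membership)),
                 resolution = resolution, seed = seed),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Louvain partition: %d communities, Q = %.3f (resolution %g)\n",
              x$n_communities, x$modularity_q, x$resolution))
  invisible(x)
}
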