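#' Read a molecule description table
#'
#' @param path TSV (default) or CSV file with columns `molecule_id` and
#'   `description`.
#' @return data.frame.
#' @export
read_molecule_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("molecule_id", "description") %in% names(tab)))
    stop("molecule table needs columns molecule_id and description: ", path)
  tab
}

#' Read a molecules-by-features numeric table
#'
#' @param path TSV/CSV keyed by a `molecule_id` first column.
#' @return numeric matrix with molecule rownames.
#' @export
read_feature_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "")
  idcol <- if ("molecule_id" %in% names(tab)) "molecule_id" else names(tab)[1]
  ids <- as.character(tab[[idcol]])
  X <- as.matrix(tab[setdiff(names(tab), idcol)])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  X
}

#' Write a perceptual matrix as TSV and sparse triplets
#'
#' @param A perceptual matrix.
#' @param path output TSV path; a `<path>.triplets.tsv` companion holds the
#'   (molecule, descriptor, value) triplets of the non-zero entries.
#' @return invisibly, the paths written.
#' @export
write_perceptual_matrix <- function(A, path) {
  df <- data.frame(molecule_id = rownames(A), A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- which(A == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  trip <- data.frame(molecule_id = rownames(A)[idx[, 1]],
                     descriptor = colnames(A)[idx[, 2]], value = 1L)
  tpath <- paste0(path, ".triplets.tsv")
  utils::write.table(trip, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, tpath))
}

#' Write a weighted graph as GraphML and GEXF
#'
#' @param g weighted igraph graph.
#' @param stem output path without extension; writes `<stem>.graphml` and
#'   `<stem>.gexf`.
#' @return invisibly, the paths written.
#' @export
write_graph_files <- function(g, stem) {
  gml <- paste0(stem, ".graphml")
  igraph::write_graph(g, gml, format = "graphml")
  gexf <- paste0(stem, ".gexf")
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  con <- file(gexf, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph defaultedgetype="undirected">',
    '    <nodes>',
    sprintf('      <node id="%d" label="%s"/>', seq_along(nodes), nodes),
    '    </nodes>',
    '    <edges>',
    if (nrow(el)) sprintf('      <edge id="%d" source="%d" target="%d" weight="%g"/>',
                          seq_len(nrow(el)), el[, 1], el[, 2], w) else character(),
    '    </edges>',
    '  </graph>',
    '</gexf>'), con)
  invisible(c(gml, gexf))
}

#' Write a network summary (and optional null result) as JSON
#'
#' @param summary a `network_summary`.
#' @param null optional `er_null`.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
write_network_summary <- function(summary, path, null = NULL) {
  x <- unclass(summary)
  if (!is.null(x$powerlaw)) x$powerlaw <- unclass(x$powerlaw)
  if (!is.null(null)) x$random_null <- unclass(null)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
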