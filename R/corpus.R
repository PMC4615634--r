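#' Curation configuration for free-text odour descriptions
#'
#' Bundles the three curation rules applied to raw odour descriptions:
#' a stoplist of words that carry no qualitative olfactory information
#' (conjunctions, adverbs, suffix-like words, auxiliary verbs, intensity
#' words), a merge map collapsing semantically equivalent descriptor
#' variants onto a canonical form, and a set of drop tokens whose presence
#' marks a molecule as non-odorous and removes it from the corpus.
#'
#' @param stoplist character vector of words to remove. The default seeds
#'   the list with common fill words used in odour databases.
#' @param merge_map named character vector mapping variant -> canonical
#'   descriptor (e.g. `c(fruity = "fruit")`). Values must themselves be
#'   canonical: no entry may map onto another variant.
#' @param drop_tokens descriptors whose presence removes the whole molecule.
#' @return An object of class `curation_config`.
#' @examples
#' cfg <- curation_config(merge_map = c(fruity = "fruit"))
#' curate_description("somewhat fruity and sweet", cfg)
#' @export
curation_config <- function(stoplist = default_stoplist(),
                            merge_map = c(alcoholic = "alcohol", fruity = "fruit"),
                            drop_tokens = "odorless") {
  stoplist <- tolower(as.character(stoplist))
  drop_tokens <- tolower(as.character(drop_tokens))
  merge_map <- merge_map[!duplicated(names(merge_map))]
  if (length(merge_map)) {
    names(merge_map) <- tolower(names(merge_map))
    merge_map[] <- tolower(merge_map)
    chained <- intersect(unname(merge_map), names(merge_map))
    if (length(chained))
      stop("merge_map values must be canonical; chained entries: ",
           paste(chained, collapse = ", "))
    clash <- intersect(names(merge_map), stoplist)
    if (length(clash))
      stop("stoplist and merge_map keys must be disjoint: ",
           paste(clash, collapse = ", "))
  }
  structure(list(stoplist = stoplist, merge_map = merge_map,
                 drop_tokens = drop_tokens),
            class = "curation_config")
}

#' Default stoplist of non-olfactory fill words
#'
#' @return character vector.
#' @export
default_stoplist <- function() {
  c("and", "or", "with", "a", "an", "the", "of", "in", "to",
    "less", "somewhat", "slightly", "very", "strong", "weak", "mild",
    "like", "note", "notes", "nuance", "nuances",
    "has", "is", "was", "have",
    "over", "preserves", "powerful", "other", "odor", "odour", "aroma")
}

#' Curate one raw odour description into descriptor tokens
#'
#' Lowercases, splits on whitespace (punctuation at token edges is stripped),
#' removes stoplist words, applies the merge map, and collapses duplicates
#' keeping first occurrence. If any drop token (e.g. "odorless") is present
#' the result is an empty vector, flagging the molecule for removal.
#'
#' @param raw a single character string (may be empty).
#' @param config a [curation_config()].
#' @return character vector of curated descriptors (possibly empty).
#' @export
curate_description <- function(raw, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"))
  if (length(raw) != 1L || is.na(raw)) raw <- ""
  tokens <- strsplit(tolower(raw), "\\s+")[[1]]
  tokens <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", tokens)
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) return(character())
  tokens <- tokens[!tokens %in% config$stoplist]
  hit <- match(tokens, names(config$merge_map))
  tokens[!is.na(hit)] <- unname(config$merge_map[hit[!is.na(hit)]])
  tokens <- tokens[!duplicated(tokens)]
  if (any(tokens %in% config$drop_tokens)) return(character())
  tokens
}

#' Curate a whole molecule table
#'
#' @param table data.frame with columns `molecule_id` and `description`.
#' @param config a [curation_config()].
#' @return named list of descriptor vectors, one per molecule (molecules
#'   curated to an empty set are kept as empty entries; matrix construction
#'   drops them).
#' @export
curate_records <- function(table, config = curation_config()) {
  stopifnot(is.data.frame(table),
            all(c("molecule_id", "description") %in% names(table)))
  ids <- as.character(table$molecule_id)
  if (anyDuplicated(ids))
    stop("molecule_id must be unique within a corpus")
  recs <- lapply(table$description, curate_description, config = config)
  names(recs) <- ids
  recs
}

#' Build the dichotomous perceptual matrix
#'
#' Assembles curated descriptor sets into a binary molecules x descriptors
#' incidence matrix A: `A[i, j] = 1` iff descriptor j was used for molecule
#' i. Molecules with no descriptors are dropped; descriptor columns are
#' ordered lexicographically (radix sort, locale independent) so repeated
#' runs give byte-identical matrices.
#'
#' @param records named list of descriptor character vectors, as returned by
#'   [curate_records()].
#' @return integer matrix with molecule ids as rownames and descriptors as
#'   colnames; every row and column has at least one 1.
#' @export
build_perceptual_matrix <- function(records) {
  stopifnot(is.list(records), !is.null(names(records)))
  keep <- lengths(records) > 0L
  records <- records[keep]
  if (!length(records)) stop("empty corpus: no molecule has any descriptor")
  descriptors <- sort(unique(unlist(records, use.names = FALSE)),
                      method = "radix")
  A <- matrix(0L, nrow = length(records), ncol = length(descriptors),
              dimnames = list(names(records), descriptors))
  for (i in seq_along(records))
    A[i, records[[i]]] <- 1L
  A
}

stopifnot_perceptual <- function(A) {
  stopifnot(is.matrix(A), all(A %in% c(0L, 1L)),
            !is.null(rownames(A)), !is.null(colnames(A)))
  if (any(rowSums(A) == 0)) stop("perceptual matrix has an empty row")
  if (any(colSums(A) == 0)) stop("perceptual matrix has an empty column")
  invisible(A)
}

#' Summary statistics of a perceptual matrix
#'
#' Computes the average number of percepts per molecule
#' \eqn{AP_m = \sum_{ij} A_{ij} / m}, the average occurrence of a percept
#' \eqn{AM_p = \sum_{ij} A_{ij} / p}, and the percentage of sparseness
#' \eqn{S_p = (1 - \sum_{ij} A_{ij} / (mp)) \times 100}, together with the
#' per-molecule and per-descriptor count ranges.
#'
#' @param A perceptual matrix from [build_perceptual_matrix()].
#' @return list of class `corpus_stats` with elements `n_molecules`,
#'   `n_descriptors`, `ap_m`, `ap_m_range`, `am_p`, `am_p_range`,
#'   `sparseness_pct`.
#' @export
matrix_stats <- function(A) {
  stopifnot_perceptual(A)
  total <- sum(A)
  m <- nrow(A); p <- ncol(A)
  rs <- rowSums(A); cs <- colSums(A)
  structure(list(
    n_molecules = m,
    n_descriptors = p,
    ap_m = total / m,
    ap_m_range = c(min(rs), max(rs)),
    am_p = total / p,
    am_p_range = c(min(cs), max(cs)),
    sparseness_pct = (1 - total / (m * p)) * 100
  ), class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf(
    paste0("Perceptual corpus: %d molecules x %d descriptors\n",
           "  descriptors per molecule: %.2f (%d-%d)\n",
           "  molecules per descriptor: %.2f (%d-%d)\n",
           "  sparseness: %.2f%%\n"),
    x$n_molecules, x$n_descriptors,
    x$ap_m, x$ap_m_range[1], x$ap_m_range[2],
    x$am_p, x$am_p_range[1], x$am_p_range[2],
    x$sparseness_pct))
  invisible(x)
}

#' Descriptor co-occurrence matrix
#'
#' \eqn{C = A^T A} over the integers. `C[i, j]` counts the molecules whose
#' descriptions contain both descriptor i and descriptor j; the diagonal
#' holds descriptor frequencies.
#'
#' @param A perceptual matrix.
#' @return symmetric integer matrix with descriptor dimnames.
#' @export
cooccurrence <- function(A) {
  stopifnot_perceptual(A)
  C <- crossprod(A)
  storage.mode(C) <- "integer"
  C
}
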