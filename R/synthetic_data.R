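#' Specification for a synthetic odour corpus
#'
#' Collects the knobs of the synthetic generators in one validated object.
#' Defaults emulate the structure of curated odour databases: a few
#' thousand molecules, a few hundred descriptors, ~99% sparseness,
#' heavy-tailed descriptor popularity and a small number of planted
#' descriptor communities.
#'
#' @param m molecules.
#' @param p descriptors.
#' @param target_sparseness_pct percentage of zeros in the perceptual
#'   matrix, in (0, 100).
#' @param exponent descriptor-popularity power-law exponent (> 1).
#' @param n_communities planted descriptor communities (default 7, the
#'   community count of a combined odour network).
#' @param preference probability mass a molecule puts on its own
#'   community's descriptors (1 = never crosses communities).
#' @param n_features physico-chemical feature count.
#' @param n_informative features carrying class signal.
#' @param congruence in [0, 1]: how faithfully feature-space classes follow
#'   the perceptual communities (1 = identical geometry, 0 = no relation).
#' @param noise_sd within-class feature noise standard deviation.
#' @param seed integer RNG seed.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(m = 3000, p = 500, target_sparseness_pct = 99.3,
                       exponent = 2.5, n_communities = 7, preference = 0.9,
                       n_features = 100, n_informative = 20,
                       congruence = 1, noise_sd = 0.5, seed = 1L) {
  stopifnot(m >= 2, p >= 2, target_sparseness_pct > 0,
            target_sparseness_pct < 100, exponent > 1,
            n_communities >= 1, preference >= 0, preference <= 1,
            congruence >= 0, congruence <= 1, noise_sd > 0)
  structure(as.list(environment()), class = "synth_spec")
}

#' Generate a synthetic perceptual matrix with planted communities
#'
#' Descriptor popularity is drawn from a discrete power law with the
#' requested exponent; descriptors are split round-robin into
#' `n_communities` communities. Each molecule is assigned a community and a
#' descriptor count (Poisson, truncated at 1, with rate matched to the
#' target sparseness), then samples descriptors without replacement with
#' probability proportional to popularity, weighted by `preference` for its
#' own community and `1 - preference` elsewhere.
#'
#' @param spec a [synth_spec()].
#' @return list with `A` (perceptual matrix; empty columns removed),
#'   `descriptor_community` (named, for retained descriptors),
#'   `molecule_community` (named), `spec`.
#' @export
gen_perceptual_matrix <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  lambda <- spec$p * (1 - spec$target_sparseness_pct / 100)
  if (lambda < 1)
    stop("infeasible sparseness: implied descriptor count per molecule is below 1")
  # correct the Poisson rate for the >= 1 truncation so the realised mean
  # stays on target
  lam0 <- max(lambda - exp(-lambda), 0.01)
  set.seed(spec$seed)
  pop <- gen_power_law_degrees(spec$exponent, x_min = 1, n = spec$p,
                               seed = spec$seed + 1L)
  desc_comm <- rep_len(seq_len(spec$n_communities), spec$p)
  mol_comm <- sample(seq_len(spec$n_communities), spec$m, replace = TRUE)
  counts <- pmax(1L, stats::rpois(spec$m, lam0))
  counts <- pmin(counts, spec$p)
  descs <- sprintf("d%03d", seq_len(spec$p))
  records <- vector("list", spec$m)
  for (i in seq_len(spec$m)) {
    w <- pop * ifelse(desc_comm == mol_comm[i], spec$preference,
                      1 - spec$preference)
    if (all(w == 0)) w <- pop
    records[[i]] <- descs[sample.int(spec$p, counts[i], prob = w)]
  }
  names(records) <- sprintf("M%05d", seq_len(spec$m))
  A <- build_perceptual_matrix(records)
  names(desc_comm) <- descs
  names(mol_comm) <- names(records)
  list(A = A, descriptor_community = desc_comm[colnames(A)],
       molecule_community = mol_comm[rownames(A)], spec = spec)
}

#' Generate a synthetic physico-chemical feature table
#'
#' Informative features get class-dependent means whose separation scales
#' with `congruence` (at 0 every class shares one mean; at 1 classes sit
#' `separation` apart in units of `noise_sd`); the remaining features are
#' pure noise. Optionally injects constant and missing-value columns so
#' that [preprocess_features()] has something to drop.
#'
#' @param labels class label per molecule (e.g. planted communities).
#' @param spec a [synth_spec()].
#' @param n_constant,n_missing counts of injected degenerate columns.
#' @param separation between-class mean separation in noise-sd units.
#' @return numeric matrix, molecules x features, with molecule rownames.
#' @export
gen_feature_matrix <- function(labels, spec, n_constant = 0L, n_missing = 0L,
                               separation = 6) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$n_informative > spec$n_features)
    stop("n_informative cannot exceed n_features")
  labels <- as.integer(as.factor(labels))
  n <- length(labels)
  k <- max(labels)
  set.seed(spec$seed + 2L)
  mu <- matrix(stats::rnorm(k * spec$n_informative), k, spec$n_informative)
  mu <- spec$congruence * separation * spec$noise_sd * mu
  X_inf <- mu[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * spec$n_informative, sd = spec$noise_sd),
           n, spec$n_informative)
  n_noise <- spec$n_features - spec$n_informative
  X <- cbind(X_inf,
             matrix(stats::rnorm(n * n_noise), n, n_noise))
  colnames(X) <- c(sprintf("inf%03d", seq_len(spec$n_informative)),
                   if (n_noise) sprintf("noise%03d", seq_len(n_noise)))
  if (n_constant > 0) {
    Xc <- matrix(1, n, n_constant,
                 dimnames = list(NULL, sprintf("const%03d", seq_len(n_constant))))
    X <- cbind(X, Xc)
  }
  if (n_missing > 0) {
    Xm <- matrix(stats::rnorm(n * n_missing), n, n_missing,
                 dimnames = list(NULL, sprintf("miss%03d", seq_len(n_missing))))
    for (j in seq_len(n_missing)) Xm[sample.int(n, 1), j] <- NA
    X <- cbind(X, Xm)
  }
  rownames(X) <- if (!is.null(names(labels))) names(labels) else
    sprintf("M%05d", seq_len(n))
  X
}

#' Generate a token stream with planted co-occurring pairs
#'
#' Emits `length` slots: each slot is, with probability `rate`, a planted
#' vocabulary pair written adjacently (a uniform choice among
#' `planted_pairs`), otherwise one background token from a vocabulary
#' disjoint from `vocabulary`.
#'
#' @param vocabulary descriptor vocabulary the pairs are drawn from.
#' @param length number of slots.
#' @param planted_pairs 2-column character matrix of vocabulary pairs (may
#'   have zero rows).
#' @param rate per-slot probability of emitting a planted pair.
#' @param seed integer RNG seed.
#' @return character vector of tokens.
#' @export
gen_token_stream <- function(vocabulary, length, planted_pairs = NULL,
                             rate = 0.05, seed = 1L) {
  if (!is.null(planted_pairs)) {
    planted_pairs <- matrix(as.character(planted_pairs), ncol = 2)
    if (nrow(planted_pairs) && !all(planted_pairs %in% vocabulary))
      stop("planted_pairs must be drawn from the vocabulary")
  }
  set.seed(seed)
  bg <- sprintf("bg%04d", seq_len(200))
  out <- vector("list", length)
  plant <- if (is.null(planted_pairs) || nrow(planted_pairs) == 0)
    logical(length) else stats::runif(length) < rate
  pick <- if (any(plant))
    sample.int(max(nrow(planted_pairs), 1), length, replace = TRUE) else NULL
  for (i in seq_len(length)) {
    out[[i]] <- if (plant[i]) planted_pairs[pick[i], ] else sample(bg, 1)
  }
  unlist(out, use.names = FALSE)
}

#' Draw i.i.d. discrete power-law variates
#'
#' Exact inverse-CDF sampling of \eqn{p(x) \propto x^{-\alpha}}, \eqn{x \ge
#' x_{min}}: the probability mass function is tabulated out to the point
#' where the complementary CDF drops below 1e-8 and sampled directly.
#'
#' @param alpha exponent, > 1.
#' @param x_min smallest value, integer >= 1.
#' @param n sample size.
#' @param seed integer RNG seed.
#' @return integer vector of length n, all values >= x_min.
#' @export
gen_power_law_degrees <- function(alpha, x_min = 1L, n, seed = 1L) {
  stopifnot(alpha > 1, x_min >= 1, n >= 1)
  set.seed(seed)
  z <- hurwitz_zeta(alpha, x_min)
  # support cutoff where the remaining tail mass zeta(alpha, x)/z ~ x^(1-alpha)/((alpha-1) z)
  # falls below 1e-8
  xmax <- ceiling((1e-8 * (alpha - 1) * z)^(1 / (1 - alpha)))
  xmax <- min(max(xmax, x_min + 1000), x_min + 5e6)
  xs <- x_min:xmax
  pmf <- xs^(-alpha) / z
  sample(xs, n, replace = TRUE, prob = pmf)
}
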