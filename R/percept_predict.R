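#' Correlation-based feature selection (CFS), greedy forward search
#'
#' Selects a feature subset maximising the CFS merit
#' \deqn{merit(S) = k \bar r_{cf} / \sqrt{k + k (k - 1) \bar r_{ff}}}
#' where \eqn{\bar r_{cf}} is the mean absolute feature-class correlation
#' over the k features of S and \eqn{\bar r_{ff}} the mean absolute
#' pairwise correlation inside S. Feature-class correlation for a
#' multiclass label is the point-biserial correlation against each
#' one-vs-rest class indicator, averaged over classes. The forward search
#' adds the merit-maximising feature until no addition improves the merit.
#'
#' @param X numeric feature matrix (rows = molecules).
#' @param y class labels (>= 2 classes).
#' @return character vector (or column indices when X is unnamed) of the
#'   selected features, in order of inclusion; the merit trace is attached
#'   as attribute `merit`.
#' @export
cfs_select <- function(X, y) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  p <- ncol(X)
  sds <- apply(X, 2, stats::sd)
  ok <- sds > 0
  r_cf <- numeric(p)
  ind <- sapply(levels(y), function(l) as.numeric(y == l))
  r_cf[ok] <- rowMeans(abs(suppressWarnings(stats::cor(X[, ok, drop = FALSE], ind))))
  sel <- integer(0)
  merit_trace <- numeric(0)
  best_merit <- -Inf
  # mean |r| between each candidate and the selected set, updated incrementally
  sum_rff <- numeric(p)
  repeat {
    cand <- setdiff(which(ok), sel)
    if (!length(cand)) break
    k <- length(sel) + 1
    mean_cf <- (sum(r_cf[sel]) + r_cf[cand]) / k
    mean_ff <- if (k == 1) 0 else
      (2 * (if (length(sel) < 2) 0 else sum_rff_sel) + 2 * sum_rff[cand]) /
      (k * (k - 1))
    merit <- k * mean_cf / sqrt(k + k * (k - 1) * mean_ff)
    j <- cand[which.max(merit)]
    if (max(merit) <= best_merit + 1e-12) break
    best_merit <- max(merit)
    merit_trace <- c(merit_trace, best_merit)
    # update pairwise-correlation bookkeeping with the new member
    new_r <- abs(suppressWarnings(stats::cor(X, X[, j])))
    new_r[!ok | !is.finite(new_r)] <- 0
    sum_rff_sel <- if (length(sel)) sum_rff_sel + sum_rff[j] else 0
    sum_rff <- sum_rff + as.numeric(new_r)
    sel <- c(sel, j)
  }
  out <- colnames(X)[sel]
  attr(out, "merit") <- merit_trace
  out
}

macro_ovr_auc <- function(y, prob) {
  y <- as.factor(y)
  aucs <- vapply(levels(y), function(l) {
    resp <- as.integer(y == l)
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, prob[, l], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

stratified_folds <- function(y, folds) {
  y <- as.factor(y)
  assign <- integer(length(y))
  for (l in levels(y)) {
    idx <- which(y == l)
    assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assign
}

#' Cross-validated random-forest prediction of perceptual classes
#'
#' Stratified k-fold cross-validation of a random forest mapping
#' physico-chemical features to perceptual cluster labels. When
#' `with_selection` is on, CFS feature selection runs on each training
#' split only — never on held-out molecules — and the per-fold selections
#' are aggregated into a consensus set (features picked in at least half
#' the folds). Performance is the macro-averaged one-vs-rest ROC AUC of the
#' pooled out-of-fold class probabilities.
#'
#' @param X numeric feature matrix.
#' @param y perceptual class labels; every class must have at least `folds`
#'   members.
#' @param folds number of CV folds (default 10).
#' @param with_selection run CFS inside each fold (default TRUE).
#' @param n_trees random forest size (default 500).
#' @param seed integer RNG seed.
#' @return list of class `prediction_report`: `roc_auc`, `per_fold_auc`,
#'   `selected_features_per_fold`, `consensus_features`,
#'   `n_features_consensus`, `fold_assignment`, `oof_prob`, `seed`.
#' @export
crossval_rf <- function(X, y, folds = 10L, with_selection = TRUE,
                        n_trees = 500L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  counts <- table(y)
  if (any(counts < folds))
    stop("class '", names(counts)[which.min(counts)], "' has ", min(counts),
         " members, fewer than ", folds,
         " folds; reduce the fold count or merge small classes")
  set.seed(seed)
  assign <- stratified_folds(y, folds)
  prob <- matrix(NA_real_, nrow(X), nlevels(y),
                 dimnames = list(rownames(X), levels(y)))
  sel_per_fold <- vector("list", folds)
  per_fold_auc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- assign != f
    feats <- colnames(X)
    if (with_selection) {
      feats <- cfs_select(X[tr, , drop = FALSE], y[tr])
      if (!length(feats)) feats <- colnames(X)
    }
    sel_per_fold[[f]] <- feats
    fit <- randomForest::randomForest(
      x = X[tr, feats, drop = FALSE], y = y[tr], ntree = n_trees)
    prob[!tr, ] <- stats::predict(fit, X[!tr, feats, drop = FALSE],
                                  type = "prob")[, levels(y)]
    per_fold_auc[f] <- macro_ovr_auc(y[!tr], prob[!tr, , drop = FALSE])
  }
  consensus <- character(0)
  if (with_selection) {
    tab <- table(unlist(sel_per_fold))
    consensus <- sort(names(tab)[tab >= folds / 2], method = "radix")
  }
  structure(list(
    roc_auc = macro_ovr_auc(y, prob),
    per_fold_auc = per_fold_auc,
    selected_features_per_fold = sel_per_fold,
    consensus_features = consensus,
    n_features_consensus = length(consensus),
    fold_assignment = assign,
    oof_prob = prob,
    with_selection = with_selection,
    seed = seed
  ), class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("Random forest, %d-fold CV%s: macro OvR AUC = %.3f\n",
              length(x$per_fold_auc),
              if (x$with_selection)
                sprintf(" with CFS (%d consensus features)",
                        x$n_features_consensus) else "",
              x$roc_auc))
  invisible(x)
}
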