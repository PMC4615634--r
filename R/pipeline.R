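#' Default pipeline configuration
#'
#' Builds the configuration list consumed by [run_pipeline()]. Every
#' stochastic stage carries an explicit seed derived from the master seed,
#' so a configuration pins down the whole run. The list round-trips
#' losslessly through YAML.
#'
#' @param out_dir output directory.
#' @param seed master seed; stage seeds default to offsets of it.
#' @param molecule_table,feature_table,corpus_file optional input paths;
#'   when `molecule_table` is `NULL` a synthetic corpus is generated from
#'   `synth`.
#' @param stages character vector among
#'   `c("curate", "network", "semantic", "cluster", "predict")`.
#' @param synth named list of [synth_spec()] overrides.
#' @param window semantic window size; `NULL` = derive from the corpus'
#'   average descriptors per molecule.
#' @param n_instances ER null ensemble size.
#' @param resolution,restarts Louvain parameters.
#' @param k_max,k_neighbor dual-space clustering parameters.
#' @param folds,n_trees prediction parameters.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            molecule_table = NULL, feature_table = NULL,
                            corpus_file = NULL,
                            stages = c("curate", "network", "semantic",
                                       "cluster", "predict"),
                            synth = list(), window = NULL,
                            n_instances = 200L, resolution = 1,
                            restarts = 10L, k_max = 20L, k_neighbor = 7L,
                            folds = 10L, n_trees = 500L) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              molecule_table = molecule_table, feature_table = feature_table,
              corpus_file = corpus_file, stages = stages, synth = synth,
              window = window, n_instances = as.integer(n_instances),
              resolution = as.numeric(resolution), restarts = as.integer(restarts),
              k_max = as.integer(k_max), k_neighbor = as.integer(k_neighbor),
              folds = as.integer(folds), n_trees = as.integer(n_trees))
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file of [pipeline_config()] fields.
#' @return `run_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the odour-space analysis pipeline
#'
#' Executes the enabled stages in order — curation to perceptual matrices,
#' co-occurrence network with null model, power-law fit and communities,
#' semantic comparison, dual-space clustering concordance, and perceptual
#' class prediction — writing each artifact under `config$out_dir` and a
#' `manifest.json` recording the configuration, seeds and per-artifact MD5
#' checksums. Stage failures abort with a stage-named error; artifacts
#' already written are retained next to a `FAILED` marker naming the stage.
#'
#' @param config a [pipeline_config()] or path to its YAML form.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  results <- list()
  stage <- function(name, enabled, fun) {
    if (!enabled) return(invisible(NULL))
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      writeLines(paste0("failed stage: ", name, "\n", conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    invisible(ok)
  }
  on <- function(s) s %in% config$stages

  # --- inputs -------------------------------------------------------------
  planted <- NULL
  if (!is.null(config$molecule_table)) {
    if (!file.exists(config$molecule_table))
      stop("missing input: molecule_table '", config$molecule_table, "'")
    records <- curate_records(read_molecule_table(config$molecule_table))
  } else {
    spec <- do.call(synth_spec, utils::modifyList(
      list(seed = config$seed), config$synth))
    planted <- gen_perceptual_matrix(spec)
    records <- apply(planted$A, 1, function(r) colnames(planted$A)[r == 1],
                     simplify = FALSE)
    results$synth <- planted
  }

  A <- NULL
  stage("curate", on("curate"), function() {
    A <<- build_perceptual_matrix(records)
    stats <- matrix_stats(A)
    results$stats <<- stats
    artifacts <<- c(artifacts,
                    write_perceptual_matrix(A, file.path(out, "perceptual_matrix.tsv")))
    sp <- file.path(out, "corpus_stats.json")
    jsonlite::write_json(unclass(stats), sp, auto_unbox = TRUE, digits = NA)
    artifacts <<- c(artifacts, sp)
  })
  if (is.null(A)) A <- build_perceptual_matrix(records)

  g <- NULL
  stage("network", on("network"), function() {
    C <- cooccurrence(A)
    g <<- build_graph(C)
    summ <- summarize_network(g)
    null <- er_null(summ$n_nodes, summ$n_unweighted_edges,
                    n_instances = config$n_instances,
                    cl_emp = summ$clustering_avg, seed = config$seed + 10L)
    comm <- detect_communities(g, resolution = config$resolution,
                               seed = config$seed + 11L,
                               restarts = config$restarts)
    results$network <<- list(summary = summ, null = null, communities = comm)
    artifacts <<- c(artifacts,
                    write_graph_files(g, file.path(out, "odour_network")),
                    write_network_summary(summ, file.path(out, "network_summary.json"),
                                          null = null))
    cp <- file.path(out, "communities.tsv")
    utils::write.table(
      data.frame(descriptor = names(comm$membership),
                 community = unname(comm$membership)),
      cp, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <<- c(artifacts, cp)
  })

  stage("semantic", on("semantic"), function() {
    if (is.null(g)) g <- build_graph(cooccurrence(A))
    if (!is.null(config$corpus_file)) {
      if (!file.exists(config$corpus_file))
        stop("missing input: corpus_file '", config$corpus_file, "'")
      tokens <- tolower(scan(config$corpus_file, what = character(),
                             quiet = TRUE))
    } else {
      vocab <- colnames(A)
      pairs <- cbind(vocab[seq_len(min(10, length(vocab) - 1))],
                     vocab[1 + seq_len(min(10, length(vocab) - 1))])
      tokens <- gen_token_stream(vocab, length = 20000, planted_pairs = pairs,
                                 rate = 0.05, seed = config$seed + 20L)
    }
    win <- if (is.null(config$window))
      window_for_ap_m(matrix_stats(A)$ap_m) else config$window
    sem <- build_semantic_network(tokens, colnames(A), window = win)
    found <- igraph::V(sem)$name
    if (!length(found)) stop("corpus contains no olfactory vocabulary")
    sub <- matched_subnetwork(g, found)
    sim <- eigen_similarity(sem, sub)
    results$semantic <<- list(window = win, semantic_graph = sem,
                              odour_subnetwork = sub, eigen = sim)
    artifacts <<- c(artifacts,
                    write_graph_files(sem, file.path(out, "semantic_network")),
                    write_graph_files(sub, file.path(out, "odour_subnetwork")))
    sj <- file.path(out, "semantic_comparison.json")
    jsonlite::write_json(
      list(window = win, n_found = length(found),
           eigen_similarity = sim$sim, k = sim$k, k1 = sim$k1, k2 = sim$k2),
      sj, auto_unbox = TRUE, digits = NA)
    artifacts <<- c(artifacts, sj)
  })

  percept_cl <- NULL
  features <- NULL
  stage("cluster", on("cluster"), function() {
    Sp <- perceptual_similarity(A)
    percept_cl <<- spectral_xmeans(Sp, k_max = min(config$k_max, nrow(A) - 1),
                                   seed = config$seed + 30L)
    if (!is.null(config$feature_table)) {
      if (!file.exists(config$feature_table))
        stop("missing input: feature_table '", config$feature_table, "'")
      features <<- preprocess_features(read_feature_table(config$feature_table))
    } else {
      spec <- do.call(synth_spec, utils::modifyList(
        list(seed = config$seed), config$synth))
      features <<- preprocess_features(
        gen_feature_matrix(results$synth$molecule_community, spec))
    }
    features <<- features[rownames(A), , drop = FALSE]
    Sf <- local_scaled_similarity(features,
                                  k_neighbor = min(config$k_neighbor, nrow(A) - 1))
    feat_cl <- spectral_xmeans(Sf, k_max = min(config$k_max, nrow(A) - 1),
                               seed = config$seed + 31L)
    conc <- hubert_index(percept_cl$labels, feat_cl$labels)
    results$cluster <<- list(perceptual = percept_cl, structural = feat_cl,
                             concordance = conc)
    for (nm in c("perceptual", "structural")) {
      cl <- results$cluster[[nm]]
      lp <- file.path(out, paste0("clusters_", nm, ".tsv"))
      utils::write.table(
        data.frame(molecule_id = names(cl$labels), cluster = unname(cl$labels)),
        lp, sep = "\t", quote = FALSE, row.names = FALSE)
      bp <- file.path(out, paste0("bic_trace_", nm, ".csv"))
      utils::write.csv(cl$bic_trace, bp, row.names = FALSE)
      artifacts <<- c(artifacts, lp, bp)
    }
    cj <- file.path(out, "concordance.json")
    jsonlite::write_json(
      list(k_perceptual = percept_cl$k, k_structural = feat_cl$k,
           hubert_index = conc$hubert_index),
      cj, auto_unbox = TRUE, digits = NA)
    artifacts <<- c(artifacts, cj)
  })

  stage("predict", on("predict"), function() {
    if (is.null(features) && is.null(config$feature_table) &&
        is.null(results$synth))
      stop("missing input: feature_table (required by the predict stage)")
    if (is.null(features)) {
      if (!is.null(config$feature_table)) {
        if (!file.exists(config$feature_table))
          stop("missing input: feature_table '", config$feature_table, "'")
        features <- preprocess_features(read_feature_table(config$feature_table))
        features <- features[rownames(A), , drop = FALSE]
      } else {
        spec <- do.call(synth_spec, utils::modifyList(
          list(seed = config$seed), config$synth))
        features <- preprocess_features(
          gen_feature_matrix(results$synth$molecule_community, spec))
      }
    }
    y <- if (!is.null(percept_cl)) percept_cl$labels else {
      cl <- spectral_xmeans(perceptual_similarity(A),
                            k_max = min(config$k_max, nrow(A) - 1),
                            seed = config$seed + 30L)
      cl$labels
    }
    keep <- names(y)[y %in% as.integer(names(which(table(y) >= config$folds)))]
    if (length(unique(y[keep])) < 2)
      stop("fewer than two perceptual classes are large enough for ",
           config$folds, "-fold cross-validation")
    rep_with <- crossval_rf(features[keep, , drop = FALSE], y[keep],
                            folds = config$folds, with_selection = TRUE,
                            n_trees = config$n_trees, seed = config$seed + 40L)
    rep_without <- crossval_rf(features[keep, , drop = FALSE], y[keep],
                               folds = config$folds, with_selection = FALSE,
                               n_trees = config$n_trees,
                               seed = config$seed + 40L)
    results$predict <<- list(with_selection = rep_with,
                             without_selection = rep_without)
    pj <- file.path(out, "prediction_report.json")
    jsonlite::write_json(
      list(roc_with_selection = rep_with$roc_auc,
           roc_without_selection = rep_without$roc_auc,
           n_features_consensus = rep_with$n_features_consensus),
      pj, auto_unbox = TRUE, digits = NA)
    fp <- file.path(out, "consensus_features.tsv")
    utils::write.table(
      data.frame(feature = rep_with$consensus_features),
      fp, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <<- c(artifacts, pj, fp)
  })

  # --- manifest -----------------------------------------------------------
  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    stages = config$stages,
    artifacts = lapply(stats::setNames(nm = sort(basename(artifacts))),
                       function(a) unname(tools::md5sum(file.path(out, a)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
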