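# Internal: an association table whose canonical id universe is wider than
# the pairs it holds (used by leakage-safe evaluation, where the training
# fold's edges must be laid out over the full node set).
assoc_with_universe <- function(pairs, drug_universe, disease_universe) {
  tbl <- tibble::tibble(drug_id = pairs$drug_id, disease_id = pairs$disease_id)
  structure(
    tbl,
    drug_ids = drug_universe,
    disease_ids = disease_universe,
    class = c("assoc_tbl", class(tbl))
  )
}

#' Evaluate the association-prediction pipeline on one input bundle
#'
#' Runs the full method: disease semantic similarities and drug
#' fingerprints are assembled into the node attribute matrix, propagated
#' over the self-looped association adjacency (graph convolution), the
#' association graph is embedded with biased random walks and skip-gram,
#' per-pair features are fused, and the classifier is scored under
#' stratified k-fold cross-validation on the positives plus sampled
#' negatives.
#'
#' By default the node representations are computed once on the full
#' association graph (transductive protocol — test edges influence the
#' representations, which inflates performance; the report records the
#' protocol). With `transductive = FALSE` the walks and the graph
#' convolution are recomputed inside every fold on the training edges
#' only, at extra cost.
#'
#' @param assoc Association table.
#' @param fingerprints Binary drug fingerprint matrix (row names = drug
#'   ids; superset of the network's drugs is allowed).
#' @param tree_numbers Long tibble of disease tree numbers; ignored when
#'   `sims` is given.
#' @param sims Precomputed disease similarity matrix (optional).
#' @param mode Feature mode: `"fused"` (default), `"attribute"`,
#'   `"embedding"`.
#' @param classifier,folds,ratio,threshold Evaluation settings (see
#'   [cross_validate()] and [sample_negatives()]).
#' @param mu Semantic decay factor for disease similarity. Default 0.5.
#' @param gcn_m,gcn_mode,gcn_activation Graph-convolution settings (see
#'   [gcn_propagate()]).
#' @param dim,p,q,walk_length,walks_per_node,window,epochs Walk-embedding
#'   settings (see [node2vec_embed()]).
#' @param seed Single pipeline seed; all stage seeds derive from it.
#' @param transductive Compute node representations once on the full graph
#'   (default) or per fold on training edges only.
#' @param ... Classifier options passed on.
#' @return A `cv_result` whose `$config` snapshots every hyperparameter.
#' @export
evaluate_pipeline <- function(assoc, fingerprints = NULL, tree_numbers = NULL,
                              sims = NULL,
                              mode = c("fused", "attribute", "embedding"),
                              classifier = "rf", folds = 5, ratio = 1,
                              threshold = 0.5, mu = 0.5,
                              gcn_m = 64, gcn_mode = "simplified",
                              gcn_activation = "relu",
                              dim = 64, p = 1, q = 1, walk_length = 80,
                              walks_per_node = 10, window = 10, epochs = 5,
                              seed = 1, transductive = TRUE, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(assoc, "assoc_tbl"))
  need_attr <- mode %in% c("fused", "attribute")
  need_embed <- mode %in% c("fused", "embedding")

  X <- NULL
  if (need_attr) {
    if (is.null(sims)) {
      if (is.null(tree_numbers)) {
        abort("Attribute features need `tree_numbers` or `sims`.")
      }
      sims <- disease_similarity_matrix(
        tree_numbers[tree_numbers$disease_id %in% disease_ids(assoc), ],
        mu = mu
      )
    }
    if (is.null(fingerprints)) abort("Attribute features need `fingerprints`.")
    missing_d <- setdiff(drug_ids(assoc), rownames(fingerprints))
    if (length(missing_d) > 0L) {
      abort(sprintf("No fingerprints for drug(s): %s",
                    paste(head(missing_d, 5L), collapse = ", ")))
    }
    missing_z <- setdiff(disease_ids(assoc), rownames(sims))
    if (length(missing_z) > 0L) {
      abort(sprintf("No similarity profile for disease(s): %s",
                    paste(head(missing_z, 5L), collapse = ", ")))
    }
    X <- build_attribute_matrix(
      fingerprints[drug_ids(assoc), , drop = FALSE],
      unclass(sims)[disease_ids(assoc), disease_ids(assoc), drop = FALSE],
      assoc = assoc
    )
  }

  labeled <- sample_negatives(assoc, ratio = ratio, seed = derive_seed(seed, 101L))
  config_extra <- list(
    feature_mode = mode, ratio = ratio, mu = mu, gcn_m = gcn_m,
    gcn_mode = gcn_mode, gcn_activation = gcn_activation, dim = dim,
    p = p, q = q, walk_length = walk_length, walks_per_node = walks_per_node,
    window = window, epochs = epochs, pipeline_seed = seed,
    transductive = transductive
  )

  if (transductive) {
    H <- if (need_attr) {
      gcn_propagate(build_adjacency(assoc), X, m = gcn_m, mode = gcn_mode,
                    activation = gcn_activation, seed = derive_seed(seed, 211L))
    }
    E <- if (need_embed) {
      node2vec_embed(assoc, dim = dim, p = p, q = q,
                     walk_length = walk_length,
                     walks_per_node = walks_per_node, window = window,
                     epochs = epochs, seed = derive_seed(seed, 307L))
    }
    feats <- fuse_features(labeled, H = H, E = E, mode = mode)
    cv <- cross_validate(feats, labeled$label, folds = folds,
                         classifier = classifier,
                         seed = derive_seed(seed, 401L),
                         threshold = threshold, ...)
    cv$config <- c(cv$config, config_extra)
    cv$representations <- list(H = H, E = E)
    cv$labeled_pairs <- labeled
    return(cv)
  }

  # leakage-safe: per-fold representations from training edges only
  labels <- labeled$label
  fold_id <- stratified_folds(labels, folds, derive_seed(seed, 401L))
  fold_metrics <- vector("list", folds)
  fold_preds <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    train_pos <- labeled[!test & labels == 1L, ]
    assoc_f <- assoc_with_universe(train_pos, drug_ids(assoc), disease_ids(assoc))
    H_f <- if (need_attr) {
      gcn_propagate(build_adjacency(assoc_f), X, m = gcn_m, mode = gcn_mode,
                    activation = gcn_activation,
                    seed = derive_seed(seed, 211L))
    }
    E_f <- if (need_embed) {
      suppressWarnings(
        node2vec_embed(as_association_table(train_pos[, 1:2]), dim = dim,
                       p = p, q = q, walk_length = walk_length,
                       walks_per_node = walks_per_node, window = window,
                       epochs = epochs, seed = derive_seed(seed, 307L))
      )
    }
    tr <- suppressWarnings(
      fuse_features(labeled[!test, ], H = H_f, E = E_f, mode = mode)
    )
    te <- suppressWarnings(
      fuse_features(labeled[test, ], H = H_f, E = E_f, mode = mode)
    )
    model <- fit_classifier(tr, labels[!test], classifier,
                            seed = derive_seed(seed, 401L + f), ...)
    scores <- predict(model, te)
    fold_metrics[[f]] <- dplyr::mutate(
      compute_metrics(labels[test], scores, threshold = threshold),
      fold = f, .before = 1L
    )
    fold_preds[[f]] <- tibble::tibble(fold = f, row = which(test),
                                      label = labels[test],
                                      score = as.numeric(scores))
  }
  per_fold <- dplyr::bind_rows(fold_metrics)
  metric_cols <- setdiff(names(per_fold), "fold")
  structure(
    list(
      folds = per_fold,
      summary = list(
        mean = vapply(per_fold[metric_cols], mean, 0),
        sd = vapply(per_fold[metric_cols], sd, 0)
      ),
      predictions = dplyr::bind_rows(fold_preds),
      config = c(list(folds = folds, classifier = classifier,
                      seed = derive_seed(seed, 401L), threshold = threshold,
                      n_pairs = length(labels)),
                 config_extra),
      labeled_pairs = labeled
    ),
    class = "cv_result"
  )
}

pipeline_config_defaults <- function() {
  list(
    associations = NULL, fingerprints = NULL, smiles = NULL,
    tree_numbers = NULL, simulate = NULL, out_dir = NULL,
    feature_mode = "fused", classifier = "rf", folds = 5, ratio = 1,
    threshold = 0.5, mu = 0.5, radius = 2, n_bits = 1024,
    gcn_m = 64, gcn_mode = "simplified", gcn_activation = "relu",
    dim = 64, p = 1, q = 1, walk_length = 80, walks_per_node = 10,
    window = 10, epochs = 5, seed = 1, transductive = TRUE,
    rank_drugs = NULL, top_k = 10
  )
}

#' Resolve and validate a pipeline configuration
#'
#' @param config Named list of settings, or the path to a YAML file of
#'   them. Unknown keys are rejected; missing keys take the documented
#'   defaults.
#' @return The resolved configuration list.
#' @export
resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  defaults <- pipeline_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown config key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  resolved <- utils::modifyList(defaults, config)
  if (is.null(resolved$out_dir)) abort("Config must set `out_dir`.")
  simulated <- !is.null(resolved$simulate)
  if (!simulated && is.null(resolved$associations)) {
    abort("Config must set `associations` (or `simulate`).")
  }
  if (resolved$feature_mode %in% c("fused", "attribute") && !simulated) {
    if (is.null(resolved$fingerprints) && is.null(resolved$smiles)) {
      abort(sprintf(
        "feature_mode '%s' needs `fingerprints` or `smiles` in the config.",
        resolved$feature_mode
      ))
    }
    if (is.null(resolved$tree_numbers)) {
      abort(sprintf("feature_mode '%s' needs `tree_numbers` in the config.",
                    resolved$feature_mode))
    }
  }
  resolved
}

#' Run the full pipeline from a configuration
#'
#' Executes every stage in order — input loading (or synthetic benchmark
#' generation), disease similarity, fingerprints, attribute assembly,
#' graph convolution, walk embedding, feature fusion, cross-validated
#' evaluation and optional per-drug candidate ranking — persisting every
#' intermediate artifact plus a resolved-configuration snapshot under
#' `out_dir`. Reruns with the same configuration reproduce the report
#' byte-identically.
#'
#' @param config See [resolve_config()].
#' @return Invisibly, a list with the `cv_result` (`$report`) and the
#'   written `$paths`.
#' @export
run_pipeline <- function(config) {
  cfg <- resolve_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(config = file.path(cfg$out_dir, "config_used.yaml"))

  if (!is.null(cfg$simulate)) {
    spec <- do.call(synthetic_spec, cfg$simulate)
    in_dir <- file.path(cfg$out_dir, "inputs")
    bench <- make_benchmark(spec, in_dir)
    cfg$associations <- bench$associations
    cfg$fingerprints <- bench$fingerprints
    cfg$tree_numbers <- bench$tree_numbers
    paths$inputs <- in_dir
  }
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)], paths$config)

  assoc <- read_associations(cfg$associations)
  need_attr <- cfg$feature_mode %in% c("fused", "attribute")

  fps <- NULL
  sims <- NULL
  if (need_attr) {
    fps <- if (!is.null(cfg$fingerprints)) {
      read_fingerprints(cfg$fingerprints)
    } else {
      fingerprint_matrix(read_smiles_table(cfg$smiles),
                         radius = cfg$radius, n_bits = cfg$n_bits)
    }
    trees <- read_tree_numbers(cfg$tree_numbers)
    sims <- disease_similarity_matrix(
      trees[trees$disease_id %in% disease_ids(assoc), ], mu = cfg$mu
    )
    paths$similarity <- file.path(cfg$out_dir, "disease_similarity.tsv")
    write_matrix_tsv(unclass(sims), paths$similarity)
  }

  cv <- evaluate_pipeline(
    assoc, fingerprints = fps, sims = sims, mode = cfg$feature_mode,
    classifier = cfg$classifier, folds = cfg$folds, ratio = cfg$ratio,
    threshold = cfg$threshold, mu = cfg$mu, gcn_m = cfg$gcn_m,
    gcn_mode = cfg$gcn_mode, gcn_activation = cfg$gcn_activation,
    dim = cfg$dim, p = cfg$p, q = cfg$q, walk_length = cfg$walk_length,
    walks_per_node = cfg$walks_per_node, window = cfg$window,
    epochs = cfg$epochs, seed = cfg$seed, transductive = cfg$transductive
  )

  if (!is.null(cv$representations)) {
    if (!is.null(cv$representations$H)) {
      paths$gcn <- file.path(cfg$out_dir, "gcn_features.tsv")
      write_matrix_tsv(cv$representations$H$H, paths$gcn)
    }
    if (!is.null(cv$representations$E)) {
      paths$embeddings <- file.path(cfg$out_dir, "embeddings.txt")
      write_embeddings(cv$representations$E, paths$embeddings)
    }
  }
  paths$labeled_pairs <- file.path(cfg$out_dir, "labeled_pairs.tsv")
  utils::write.table(cv$labeled_pairs, paths$labeled_pairs, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  paths$report_json <- file.path(cfg$out_dir, "report.json")
  paths$report_csv <- file.path(cfg$out_dir, "report.csv")
  write_metrics_report(cv, paths$report_json)
  write_metrics_report(cv, paths$report_csv)

  if (!is.null(cfg$rank_drugs) && cfg$transductive &&
      cfg$feature_mode == "fused") {
    labeled <- cv$labeled_pairs
    feats <- fuse_features(labeled, H = cv$representations$H,
                           E = cv$representations$E, mode = cfg$feature_mode)
    model <- train_pair_classifier(feats, labeled$label,
                                   classifier = cfg$classifier,
                                   seed = derive_seed(cfg$seed, 997L))
    paths$rankings <- character(0)
    for (d in cfg$rank_drugs) {
      rk <- rank_candidates(model, d, assoc, H = cv$representations$H,
                            E = cv$representations$E, mode = cfg$feature_mode,
                            top_k = cfg$top_k)
      p_d <- file.path(cfg$out_dir, sprintf("ranking_%s.tsv", d))
      utils::write.table(rk, p_d, sep = "\t", row.names = FALSE, quote = FALSE)
      paths$rankings <- c(paths$rankings, p_d)
    }
  }

  invisible(list(report = cv, paths = paths))
}
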