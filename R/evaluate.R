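#' Sample negative drug-disease pairs
#'
#' Known associations are the positives; negatives are drawn uniformly
#' without replacement from the unobserved cells of the drug x disease
#' grid. The draw is deterministic given the seed.
#'
#' @param assoc An [as_association_table()] tibble.
#' @param ratio Negatives per positive. Default 1 (balanced).
#' @param seed RNG seed.
#' @return A `labeled_pairs` tibble with columns `drug_id`, `disease_id`
#'   and `label` (1 = known association, 0 = sampled negative), positives
#'   first.
#' @export
sample_negatives <- function(assoc, ratio = 1, seed = 1) {
  stopifnot(inherits(assoc, "assoc_tbl"))
  if (ratio <= 0) abort("`ratio` must be positive.")
  nd <- n_drugs(assoc)
  nz <- n_diseases(assoc)
  n_pos <- nrow(assoc)
  n_neg <- round(ratio * n_pos)
  pos_cells <- (match(assoc$drug_id, drug_ids(assoc)) - 1L) * nz +
    match(assoc$disease_id, disease_ids(assoc))
  complement <- setdiff(seq_len(nd * nz), pos_cells)
  if (n_neg > length(complement)) {
    abort(sprintf(
      "Requested %d negatives but only %d unobserved pairs exist.",
      n_neg, length(complement)
    ))
  }
  neg_cells <- with_seed(seed, sample(complement, n_neg))
  out <- tibble::tibble(
    drug_id = c(assoc$drug_id, drug_ids(assoc)[(neg_cells - 1L) %/% nz + 1L]),
    disease_id = c(assoc$disease_id, disease_ids(assoc)[(neg_cells - 1L) %% nz + 1L]),
    label = rep(c(1L, 0L), c(n_pos, n_neg))
  )
  structure(out, seed = seed, ratio = ratio,
            class = c("labeled_pairs", class(out)))
}

#' Fuse per-node representations into per-pair feature rows
#'
#' Each labelled pair is represented by concatenating the two node
#' representations of its endpoints. The fused layout is
#' `[H_drug | H_disease | E_drug | E_disease]` (graph-convolution features
#' then walk embeddings); the ablation modes keep a single block. Nodes
#' missing from the embedding matrix (never walked) fall back to a zero
#' vector with a warning.
#'
#' @param pairs Data frame with columns `drug_id` and `disease_id`.
#' @param H Graph-convolution features ([gcn_propagate()] object or a
#'   matrix with node ids as row names). Required unless
#'   `mode = "embedding"`.
#' @param E Walk-embedding matrix (node ids as row names). Required unless
#'   `mode = "attribute"`.
#' @param mode `"fused"` (default), `"attribute"` or `"embedding"`.
#' @return Numeric matrix with one row per pair and attributes `layout`
#'   and `mode`.
#' @export
fuse_features <- function(pairs, H = NULL, E = NULL,
                          mode = c("fused", "attribute", "embedding")) {
  mode <- match.arg(mode)
  if (!is.data.frame(pairs) ||
      !all(c("drug_id", "disease_id") %in% names(pairs))) {
    abort("`pairs` needs columns `drug_id` and `disease_id`.")
  }
  if (inherits(H, "gcn_features")) H <- H$H
  blocks <- list()
  layout <- character(0)
  lookup <- function(mat, ids, what, zero_fallback) {
    hit <- match(ids, rownames(mat))
    if (anyNA(hit)) {
      missing_ids <- unique(ids[is.na(hit)])
      if (!zero_fallback) {
        abort(sprintf("Node(s) missing from %s: %s", what,
                      paste(head(missing_ids, 5L), collapse = ", ")))
      }
      warn(sprintf("%d node(s) missing from %s; using zero vectors (e.g. %s).",
                   length(missing_ids), what, missing_ids[1L]))
    }
    out <- matrix(0, length(ids), ncol(mat))
    ok <- !is.na(hit)
    out[ok, ] <- mat[hit[ok], , drop = FALSE]
    out
  }
  if (mode %in% c("fused", "attribute")) {
    if (is.null(H)) abort("`H` is required for attribute features.")
    blocks <- c(blocks, list(
      lookup(H, pairs$drug_id, "graph-convolution features", FALSE),
      lookup(H, pairs$disease_id, "graph-convolution features", FALSE)
    ))
    layout <- c(layout, "H_drug", "H_disease")
  }
  if (mode %in% c("fused", "embedding")) {
    if (is.null(E)) abort("`E` is required for embedding features.")
    blocks <- c(blocks, list(
      lookup(E, pairs$drug_id, "walk embeddings", TRUE),
      lookup(E, pairs$disease_id, "walk embeddings", TRUE)
    ))
    layout <- c(layout, "E_drug", "E_disease")
  }
  feats <- do.call(cbind, blocks)
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  structure(feats, layout = layout, mode = mode)
}

#' Threshold and rank metrics for one set of predictions
#'
#' Thresholded confusion counts give accuracy, sensitivity, specificity,
#' precision and the Matthews correlation coefficient; AUC is the rank
#' (Wilcoxon) statistic with midranks for tied scores, and AUPR integrates
#' the precision-recall step curve over distinct score thresholds. MCC is
#' defined as 0 when its denominator vanishes.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores Predicted scores in `[0, 1]`.
#' @param threshold Operating point for the confusion counts. Default 0.5.
#' @return One-row tibble with columns `acc`, `sen`, `spec`, `prec`,
#'   `mcc`, `auc`, `aupr`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    abort("`labels` and `scores` must have equal length.")
  }
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L) {
    abort("`labels` must contain both classes (0 and 1).")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  tibble::tibble(
    acc = (tp + tn) / length(labels),
    sen = tp / (tp + fn),
    spec = tn / (tn + fp),
    prec = if (tp + fp == 0L) 0 else tp / (tp + fp),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
    auc = rank_auc(labels, scores),
    aupr = pr_auc(labels, scores)
  )
}

# Wilcoxon rank-statistic AUC with midranks for ties.
rank_auc <- function(labels, scores) {
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  r <- rank(scores)  # "average" handles ties as midranks
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Step integration of the precision-recall curve: sweep distinct score
# thresholds from high to low; each recall increment contributes the
# precision at that threshold.
pr_auc <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]
  scores <- scores[ord]
  cut <- which(!duplicated(scores, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(labels)[cut]
  k <- cut  # predictions made at each threshold
  n1 <- sum(labels)
  precision <- tp / k
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}

classifier_names <- c("rf", "svm", "logistic", "knn", "gbdt")

fit_classifier <- function(x, y, classifier, seed, num_trees = 500, knn_k = 5,
                           gbdt_rounds = 100) {
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(y, levels = c(0L, 1L))
  fit <- switch(classifier,
    rf = ranger::ranger(
      x = x, y = y, probability = TRUE, num.trees = num_trees,
      seed = seed, num.threads = 1
    ),
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE)) abort("Package e1071 is required for `classifier = \"svm\"`.")
      keep <- which(apply(x, 2L, sd) > 0)
      m <- e1071::svm(x[, keep, drop = FALSE], y, probability = TRUE)
      list(model = m, keep = keep)
    },
    logistic = {
      df <- data.frame(.y = y, x)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    knn = list(train = x, y = y, k = knn_k),
    gbdt = {
      if (!requireNamespace("xgboost", quietly = TRUE)) abort("Package xgboost is required for `classifier = \"gbdt\"`.")
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.1,
                      max_depth = 6, nthread = 1, seed = seed),
        data = dtrain, nrounds = gbdt_rounds, verbose = 0
      )
    },
    abort(sprintf("Unknown classifier '%s'; available: %s.",
                  classifier, paste(classifier_names, collapse = ", ")))
  )
  structure(list(fit = fit, classifier = classifier, seed = seed),
            class = "pair_model")
}

#' @export
predict.pair_model <- function(object, newdata, ...) {
  x <- newdata
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  switch(object$classifier,
    rf = predict(object$fit, data = x, num.threads = 1)$predictions[, "1"],
    svm = {
      pr <- predict(object$fit$model, x[, object$fit$keep, drop = FALSE],
                    probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    logistic = {
      suppressWarnings(
        as.numeric(predict(object$fit, newdata = data.frame(x), type = "response"))
      )
    },
    knn = {
      if (!requireNamespace("class", quietly = TRUE)) abort("Package class is required for `classifier = \"knn\"`.")
      pr <- class::knn(object$fit$train, x, object$fit$y, k = object$fit$k,
                       prob = TRUE)
      p_win <- attr(pr, "prob")
      ifelse(pr == "1", p_win, 1 - p_win)
    },
    gbdt = as.numeric(predict(object$fit, xgboost::xgb.DMatrix(x)))
  )
}

#' Train a pair classifier on the full labelled set
#'
#' @param features Pair feature matrix from [fuse_features()].
#' @param labels 0/1 labels, one per feature row.
#' @param classifier One of `"rf"` (Random Forest, default), `"svm"`,
#'   `"logistic"`, `"knn"`, `"gbdt"`.
#' @param seed RNG seed for the classifier.
#' @param ... Classifier options (`num_trees`, `knn_k`, `gbdt_rounds`).
#' @return A `pair_model` usable with [predict()] and [rank_candidates()].
#' @export
train_pair_classifier <- function(features, labels, classifier = "rf",
                                  seed = 1, ...) {
  if (nrow(features) != length(labels)) {
    abort("`features` rows and `labels` length differ.")
  }
  fit_classifier(features, as.integer(labels), classifier, seed, ...)
}

#' Stratified k-fold cross-validation of a pair classifier
#'
#' Splits the labelled pairs into `folds` stratified folds (both classes in
#' every fold), trains the configured classifier on each training split and
#' scores the held-out fold, reporting the full metric panel per fold plus
#' mean and standard deviation. Every pair is tested exactly once. All
#' seeds are recorded in the result's configuration.
#'
#' @param features Pair feature matrix ([fuse_features()]).
#' @param labels 0/1 labels, one per row.
#' @param folds Number of folds, at least 2. Default 5.
#' @param classifier See [train_pair_classifier()]. Default `"rf"`.
#' @param seed Seed controlling the fold assignment and classifier. Default 1.
#' @param threshold Operating point for thresholded metrics. Default 0.5.
#' @param ... Classifier options.
#' @return A `cv_result`: per-fold metrics (`$folds`), `$summary` with
#'   `mean` and `sd`, held-out predictions (`$predictions`), and `$config`.
#' @export
cross_validate <- function(features, labels, folds = 5, classifier = "rf",
                           seed = 1, threshold = 0.5, ...) {
  labels <- as.integer(labels)
  if (folds < 2L) abort("`folds` must be at least 2.")
  if (nrow(features) != length(labels)) {
    abort("`features` rows and `labels` length differ.")
  }
  if (!classifier %in% classifier_names) {
    abort(sprintf("Unknown classifier '%s'; available: %s.",
                  classifier, paste(classifier_names, collapse = ", ")))
  }
  fold_id <- stratified_folds(labels, folds, seed)
  fold_metrics <- vector("list", folds)
  fold_preds <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    model <- fit_classifier(features[!test, , drop = FALSE], labels[!test],
                            classifier, seed = derive_seed(seed, f), ...)
    scores <- predict(model, features[test, , drop = FALSE])
    fold_metrics[[f]] <- dplyr::mutate(
      compute_metrics(labels[test], scores, threshold = threshold),
      fold = f, .before = 1L
    )
    fold_preds[[f]] <- tibble::tibble(
      fold = f, row = which(test), label = labels[test], score = as.numeric(scores)
    )
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
      config = c(list(folds = folds, classifier = classifier, seed = seed,
                      threshold = threshold, n_pairs = length(labels)),
                 list(...))
    ),
    class = "cv_result"
  )
}

stratified_folds <- function(labels, folds, seed) {
  if (min(table(labels)) < folds) {
    abort("Too few members of one class to fill every fold.")
  }
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })
  fold_id
}

#' Rank candidate diseases for a drug
#'
#' Scores every disease not already associated with the drug using a
#' trained pair classifier and returns the strongest candidates in
#' descending score order (ties broken by disease id for determinism).
#'
#' @param model A [train_pair_classifier()] model.
#' @param drug_id Drug to rank candidates for; must be in `assoc`.
#' @param assoc The association table the model's features were built on.
#' @param H,E,mode Node representations and feature mode, exactly as passed
#'   to [fuse_features()] for training.
#' @param top_k Number of candidates returned. Default 10.
#' @return Tibble with columns `rank`, `disease_id`, `score`; empty when
#'   the drug is already associated with every disease.
#' @export
rank_candidates <- function(model, drug_id, assoc, H = NULL, E = NULL,
                            mode = "fused", top_k = 10) {
  stopifnot(inherits(model, "pair_model"), inherits(assoc, "assoc_tbl"))
  if (!drug_id %in% drug_ids(assoc)) {
    abort(sprintf("Drug '%s' is not in the association table.", drug_id))
  }
  known <- assoc$disease_id[assoc$drug_id == drug_id]
  candidates <- setdiff(disease_ids(assoc), known)
  if (length(candidates) == 0L) {
    return(tibble::tibble(rank = integer(0), disease_id = character(0),
                          score = numeric(0)))
  }
  pairs <- tibble::tibble(drug_id = drug_id, disease_id = candidates)
  feats <- fuse_features(pairs, H = H, E = E, mode = mode)
  scores <- predict(model, feats)
  ord <- order(-scores, candidates)
  keep <- head(ord, top_k)
  tibble::tibble(
    rank = seq_along(keep),
    disease_id = candidates[keep],
    score = as.numeric(scores[keep])
  )
}
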