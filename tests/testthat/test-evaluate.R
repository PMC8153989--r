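test_that("negative sampling draws from the unobserved complement", {
  # 2x2 grid with 2 positives: the 2 remaining cells are forced
  assoc <- as_association_table(data.frame(
    drug_id = c("d1", "d2"), disease_id = c("z1", "z2")
  ))
  lp <- sample_negatives(assoc, ratio = 1, seed = 1)
  negs <- lp[lp$label == 0L, ]
  expect_setequal(paste(negs$drug_id, negs$disease_id),
                  c("d1 z2", "d2 z1"))
  expect_equal(sum(lp$label), 2L)

  # determinism and disjointness on a larger table
  assoc <- random_assoc(6, 8, 0.3)
  a <- sample_negatives(assoc, ratio = 1, seed = 42)
  b <- sample_negatives(assoc, ratio = 1, seed = 42)
  expect_identical(a, b)
  keys <- paste(a$drug_id, a$disease_id)
  expect_false(any(duplicated(keys)))
  pos_keys <- paste(assoc$drug_id, assoc$disease_id)
  expect_length(intersect(keys[a$label == 0L], pos_keys), 0L)

  expect_error(sample_negatives(assoc, ratio = 1e6), "unobserved")
})

test_that("feature fusion concatenates blocks in the declared layout", {
  nodes <- c("d1", "d2", "z1", "z2")
  H <- matrix(seq_len(4 * 3), 4, dimnames = list(nodes, NULL))
  E <- matrix(seq_len(4 * 2) / 10, 4, dimnames = list(nodes, NULL))
  pairs <- tibble::tibble(drug_id = c("d1", "d2", "d1"),
                          disease_id = c("z1", "z2", "z1"))
  fused <- fuse_features(pairs, H, E, mode = "fused")
  expect_equal(dim(fused), c(3L, 10L))
  expect_equal(unname(fused[1L, ]),
               c(H["d1", ], H["z1", ], E["d1", ], E["z1", ]))
  # duplicated pair -> identical row
  expect_equal(fused[1L, ], fused[3L, ])

  expect_equal(ncol(fuse_features(pairs, H = H, mode = "attribute")), 6L)
  expect_equal(ncol(fuse_features(pairs, E = E, mode = "embedding")), 4L)

  # nodes absent from the embedding fall back to zeros with a warning
  expect_warning(
    out <- fuse_features(pairs, H, E[-1L, , drop = FALSE], mode = "fused"),
    "zero vectors"
  )
  expect_equal(unname(out[1L, 7:8]), c(0, 0))
  expect_error(fuse_features(pairs, H[-1L, ], E, mode = "fused"), "missing")
})

test_that("the worked confusion example reproduces its metric panel", {
  # TP = 3, TN = 2, FP = 1, FN = 0 at threshold 0.5
  labels <- c(1, 1, 1, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.3, 0.2)
  m <- compute_metrics(labels, scores)
  expect_equal(m$acc, 5 / 6, tolerance = 1e-4)
  expect_equal(m$sen, 1)
  expect_equal(m$spec, 2 / 3, tolerance = 1e-4)
  expect_equal(m$prec, 0.75)
  expect_equal(m$mcc, 0.7071, tolerance = 1e-4)

  # perfect separation
  m <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(m$auc, 1)
  expect_equal(m$mcc, 1)
  expect_equal(m$aupr, 1)

  # all-tied scores: midrank AUC is exactly 1/2
  m <- compute_metrics(c(0, 1, 0, 1), rep(0.5, 4))
  expect_equal(m$auc, 0.5)

  expect_error(compute_metrics(c(1, 1), c(0.2, 0.9)), "both classes")
})

test_that("metrics agree with brute-force recomputation on random vectors", {
  set.seed(55)
  for (i in 1:200) {
    n <- sample(10:40, 1L)
    labels <- c(0L, 1L, rbinom(n - 2L, 1L, 0.5))
    scores <- round(runif(n), sample(1:3, 1L))  # coarse rounding forces ties
    m <- compute_metrics(labels, scores)
    expect_equal(m$auc, oracle_auc(labels, scores), tolerance = 1e-10)
    o <- oracle_confusion_metrics(labels, scores)
    expect_equal(m$acc, o$acc, tolerance = 1e-10)
    expect_equal(m$sen, o$sen, tolerance = 1e-10)
    expect_equal(m$spec, o$spec, tolerance = 1e-10)
    expect_equal(m$prec, o$prec, tolerance = 1e-10)
    expect_equal(m$mcc, o$mcc, tolerance = 1e-10)
  }
})

test_that("MCC is antisymmetric under prediction inversion", {
  set.seed(56)
  labels <- rbinom(60, 1, 0.5)
  labels[1:2] <- c(0L, 1L)
  scores <- runif(60)
  m <- compute_metrics(labels, scores)
  flipped <- compute_metrics(1L - labels, scores)
  expect_equal(flipped$mcc, -m$mcc, tolerance = 1e-10)
  # simultaneous flip of labels and scores preserves MCC
  both <- compute_metrics(1L - labels, 1 - scores + 1e-9)
  expect_equal(both$mcc, m$mcc, tolerance = 1e-6)
})

test_that("cross-validation folds partition the pairs and summarise", {
  set.seed(60)
  n <- 120
  x <- matrix(rnorm(n * 6), n)
  y <- rep(c(0L, 1L), each = n / 2)
  cv <- cross_validate(x, y, folds = 5, classifier = "rf", seed = 3,
                       num_trees = 50)
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(nrow(tidy(cv)), 5L)
  expect_setequal(sort(cv$predictions$row), seq_len(n))
  g <- glance(cv)
  expect_true(all(c("auc_mean", "auc_sd", "mcc_mean") %in% names(g)))
  expect_true(all(cv$folds$acc >= 0 & cv$folds$acc <= 1))
  expect_true(all(cv$folds$mcc >= -1 & cv$folds$mcc <= 1))

  expect_error(cross_validate(x, y, classifier = "nope"),
               "rf, svm, logistic, knn, gbdt")
})

test_that("null features score at chance; leaked labels score perfectly", {
  set.seed(61)
  n <- 300
  y <- rep(c(0L, 1L), each = n / 2)
  noise <- matrix(rnorm(n * 8), n)
  cv_null <- cross_validate(noise, y, folds = 5, seed = 7, num_trees = 100)
  expect_lt(abs(cv_null$summary$mean[["auc"]] - 0.5), 0.05)

  leak <- cbind(noise, y)
  cv_leak <- cross_validate(leak, y, folds = 5, seed = 7, num_trees = 100)
  expect_equal(cv_leak$summary$mean[["auc"]], 1)
})

test_that("alternative classifiers run and are seeded", {
  set.seed(62)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 4), n) + 0.8 * y
  for (clf in c("svm", "logistic", "knn", "gbdt")) {
    cv <- cross_validate(x, y, folds = 3, classifier = clf, seed = 2)
    expect_gt(cv$summary$mean[["auc"]], 0.6)
  }
})

test_that("candidate ranking excludes known pairs and sorts descending", {
  set.seed(63)
  assoc <- random_assoc(5, 8, 0.35)
  H <- matrix(rnorm(length(node_ids(assoc)) * 4), ncol = 4,
              dimnames = list(node_ids(assoc), NULL))
  E <- matrix(rnorm(length(node_ids(assoc)) * 4), ncol = 4,
              dimnames = list(node_ids(assoc), NULL))
  lp <- sample_negatives(assoc, seed = 2)
  feats <- fuse_features(lp, H, E, mode = "fused")
  model <- train_pair_classifier(feats, lp$label, seed = 4, num_trees = 50)

  drug <- drug_ids(assoc)[1L]
  known <- assoc$disease_id[assoc$drug_id == drug]
  rk <- rank_candidates(model, drug, assoc, H = H, E = E, top_k = 5)
  expect_lte(nrow(rk), 5L)
  expect_length(intersect(rk$disease_id, known), 0L)
  expect_true(all(diff(rk$score) <= 0))
  expect_equal(rk$rank, seq_len(nrow(rk)))

  # drug associated with every disease -> empty ranking
  full <- as_association_table(
    expand.grid(drug_id = c("dA", "dB"), disease_id = c("z1", "z2"),
                stringsAsFactors = FALSE)
  )
  H2 <- matrix(0, 4, 2, dimnames = list(node_ids(full), NULL))
  rk0 <- rank_candidates(model, "dA", full, H = H2, E = H2)
  expect_equal(nrow(rk0), 0L)
})
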