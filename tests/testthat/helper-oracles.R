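# Independent brute-force oracles and random-input generators used across
# the suite. Everything here recomputes quantities from first principles,
# without reusing the package's dynamic-programming / rank-based code paths.

# Semantic contribution by exhaustive downward path enumeration: a node's
# value is the best mu^hops over every path leading from it to one of the
# disease's own codes.
oracle_contribution <- function(dag, mu) {
  kids <- split(dag$edges$child, dag$edges$parent)
  value_of <- function(node) {
    if (node %in% dag$self_codes) return(1)
    best <- -Inf
    for (ch in kids[[node]]) best <- max(best, mu * value_of(ch))
    best
  }
  setNames(vapply(dag$nodes, value_of, 0), dag$nodes)
}

oracle_similarity <- function(dag_a, dag_b, mu) {
  ca <- oracle_contribution(dag_a, mu)
  cb <- oracle_contribution(dag_b, mu)
  shared <- intersect(names(ca), names(cb))
  if (length(shared) == 0L) return(0)
  sum(ca[shared] + cb[shared]) / (sum(ca) + sum(cb))
}

# Random tree-number sets over a small shared alphabet, so independently
# drawn diseases frequently share ancestor prefixes.
random_tree_numbers <- function(max_codes = 2, max_depth = 3) {
  n_codes <- sample(seq_len(max_codes), 1L)
  unique(vapply(seq_len(n_codes), function(i) {
    depth <- sample(seq_len(max_depth), 1L)
    paste(c(sample(c("C1", "C2"), 1L),
            sample(c("10", "20", "30"), depth - 1L, replace = TRUE)),
          collapse = ".")
  }, ""))
}

# O(n_pos * n_neg) pairwise AUC count with explicit tie handling.
oracle_auc <- function(labels, scores) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  total <- 0
  for (a in sp) total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  total / (length(sp) * length(sn))
}

oracle_confusion_metrics <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred & labels); tn <- sum(!pred & !labels)
  fp <- sum(pred & !labels); fn <- sum(!pred & labels)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    acc = (tp + tn) / (tp + tn + fp + fn),
    sen = tp / (tp + fn),
    spec = tn / (tn + fp),
    prec = if (tp + fp == 0) 0 else tp / (tp + fp),
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den
  )
}

# Small random connected-ish undirected graphs as edge data frames.
random_edge_graph <- function(n_nodes, edge_prob = 0.5) {
  nodes <- paste0("v", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2L)
  keep <- runif(ncol(pairs)) < edge_prob
  if (!any(keep)) keep[sample(ncol(pairs), 1L)] <- TRUE
  data.frame(from = pairs[1L, keep], to = pairs[2L, keep])
}

tiny_assoc <- function() {
  as_association_table(data.frame(
    drug_id = c("d1", "d1", "d2", "d3"),
    disease_id = c("z1", "z2", "z1", "z3")
  ))
}

random_assoc <- function(n_drugs = 5, n_diseases = 5, edge_prob = 0.4) {
  grid <- expand.grid(
    drug_id = sprintf("d%02d", seq_len(n_drugs)),
    disease_id = sprintf("z%02d", seq_len(n_diseases)),
    stringsAsFactors = FALSE
  )
  keep <- runif(nrow(grid)) < edge_prob
  if (!any(keep)) keep[sample(nrow(grid), 1L)] <- TRUE
  as_association_table(grid[keep, ])
}
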