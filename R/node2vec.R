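#' Build a walk graph from edges or an association table
#'
#' Internal representation used by the biased random-walk sampler: node ids
#' plus a compressed sparse adjacency with sorted neighbour lists. An
#' association table yields the undirected, unit-weight bipartite graph over
#' the canonical node order; a generic edge data frame (columns `from`,
#' `to`, optional `weight`) yields an undirected weighted graph over the
#' sorted node ids.
#'
#' @param x An `assoc_tbl` or a data frame of edges.
#' @param ... Unused.
#' @return A `walk_graph`: list with `nodes`, 0-based CSR vectors `indptr`
#'   and `indices`, and `weights`.
#' @export
walk_graph <- function(x, ...) UseMethod("walk_graph")

#' @rdname walk_graph
#' @export
walk_graph.assoc_tbl <- function(x, ...) {
  edges <- data.frame(from = x$drug_id, to = x$disease_id, weight = 1)
  build_walk_graph(edges, nodes = node_ids(x))
}

#' @rdname walk_graph
#' @export
walk_graph.data.frame <- function(x, ...) {
  if (ncol(x) < 2L) abort("Edge data frame needs columns `from` and `to`.")
  edges <- data.frame(
    from = as.character(x[[1L]]),
    to = as.character(x[[2L]]),
    weight = if (ncol(x) >= 3L) as.numeric(x[[3L]]) else 1
  )
  build_walk_graph(edges, nodes = sort(unique(c(edges$from, edges$to))))
}

build_walk_graph <- function(edges, nodes) {
  if (nrow(edges) == 0L) abort("Graph has no edges.")
  if (any(edges$weight <= 0)) abort("Edge weights must be positive.")
  if (any(edges$from == edges$to)) abort("Self-loop edges are not supported.")
  i <- match(edges$from, nodes)
  j <- match(edges$to, nodes)
  # undirected: both directions, duplicates collapsed (first weight kept)
  df <- unique(data.frame(a = c(i, j), b = c(j, i),
                          w = rep(edges$weight, 2L)))
  df <- df[!duplicated(df[, c("a", "b")]), ]
  df <- df[order(df$a, df$b), ]
  deg <- tabulate(df$a, nbins = length(nodes))
  structure(
    list(
      nodes = nodes,
      indptr = as.integer(c(0L, cumsum(deg))),
      indices = as.integer(df$b - 1L),
      weights = as.numeric(df$w)
    ),
    class = "walk_graph"
  )
}

graph_neighbors <- function(graph, v_idx) {
  span <- seq.int(graph$indptr[v_idx] + 1L, length.out = graph$indptr[v_idx + 1L] - graph$indptr[v_idx])
  list(idx = graph$indices[span] + 1L, w = graph$weights[span])
}

#' Second-order walk bias for a candidate step
#'
#' In a walk that moved `t -> v`, a candidate next node `x` is biased by its
#' hop distance from `t`: returning (`d = 0`) is weighted `1/p`, staying in
#' `t`'s neighbourhood (`d = 1`) is weighted 1, and moving outward (`d = 2`)
#' is weighted `1/q`.
#'
#' @param d_tx Hop distance between `t` and `x`: 0, 1 or 2.
#' @param p Return parameter, > 0.
#' @param q In-out parameter, > 0.
#' @return The bias multiplier.
#' @export
transition_bias <- function(d_tx, p, q) {
  if (any(p <= 0) || any(q <= 0)) abort("`p` and `q` must be positive.")
  if (!all(d_tx %in% c(0, 1, 2))) abort("`d_tx` must be 0, 1 or 2.")
  ifelse(d_tx == 0, 1 / p, ifelse(d_tx == 1, 1, 1 / q))
}

#' Exact next-step distribution of the biased walk
#'
#' For a walk currently at `cur` having arrived from `prev`, every
#' neighbour `x` of `cur` receives unnormalised probability
#' `bias(d(prev, x)) * weight(cur, x)`, normalised over the neighbour set.
#' At the first step of a walk there is no predecessor: pass
#' `prev = NULL` and the bias is identically 1 (a weight-proportional
#' step).
#'
#' @param graph A [walk_graph()].
#' @param prev Previous node id, or `NULL` at the walk start.
#' @param cur Current node id.
#' @param p,q Walk bias parameters.
#' @return A tibble with columns `node` and `prob`, summing to 1 over the
#'   neighbours of `cur`.
#' @export
step_distribution <- function(graph, prev, cur, p = 1, q = 1) {
  stopifnot(inherits(graph, "walk_graph"))
  v <- match(cur, graph$nodes)
  if (is.na(v)) abort(sprintf("Node '%s' not in graph.", cur))
  nb <- graph_neighbors(graph, v)
  if (length(nb$idx) == 0L) abort(sprintf("Node '%s' is isolated.", cur))
  if (is.null(prev) || (length(prev) == 1L && is.na(prev))) {
    alpha <- rep(1, length(nb$idx))
  } else {
    t <- match(prev, graph$nodes)
    if (is.na(t)) abort(sprintf("Node '%s' not in graph.", prev))
    t_nb <- graph_neighbors(graph, t)$idx
    if (!(v %in% t_nb)) {
      abort(sprintf("'%s' is not a neighbour of '%s'.", cur, prev))
    }
    d <- ifelse(nb$idx == t, 0, ifelse(nb$idx %in% t_nb, 1, 2))
    alpha <- transition_bias(d, p, q)
  }
  pi_vx <- alpha * nb$w
  tibble::tibble(node = graph$nodes[nb$idx], prob = pi_vx / sum(pi_vx))
}

#' Draw single biased steps from a walk context
#'
#' Diagnostic sampler: repeatedly draws the next node of a walk that moved
#' `prev -> cur`, using exactly the sampling routine of
#' [generate_walks()]. Useful for checking the sampler's empirical law
#' against [step_distribution()].
#'
#' @inheritParams step_distribution
#' @param n Number of draws.
#' @param seed RNG seed.
#' @return Character vector of `n` sampled node ids.
#' @export
sample_steps <- function(graph, prev, cur, p = 1, q = 1, n = 1000, seed = 1) {
  stopifnot(inherits(graph, "walk_graph"))
  v <- match(cur, graph$nodes)
  if (is.na(v)) abort(sprintf("Node '%s' not in graph.", cur))
  t <- if (is.null(prev) || (length(prev) == 1L && is.na(prev))) {
    -1L
  } else {
    ti <- match(prev, graph$nodes)
    if (is.na(ti)) abort(sprintf("Node '%s' not in graph.", prev))
    ti - 1L
  }
  drawn <- cpp_sample_steps(graph$indptr, graph$indices, graph$weights,
                            t, v - 1L, p, q, as.integer(n), as.numeric(seed))
  if (any(drawn < 0L)) abort(sprintf("Node '%s' is isolated.", cur))
  graph$nodes[drawn + 1L]
}

#' Generate a corpus of biased random walks
#'
#' Runs `walks_per_node` second-order biased walks of length `walk_length`
#' from every non-isolated node; isolated nodes are skipped with a warning.
#' Walks truncate early only at dead ends. The corpus is reproducible given
#' the seed.
#'
#' @param graph A [walk_graph()].
#' @param p,q Bias parameters (defaults 1, 1: the uniform weight-
#'   proportional walk).
#' @param walk_length Nodes per walk (including the start). Default 80.
#' @param walks_per_node Walks started from each node. Default 10.
#' @param seed RNG seed. Default 1.
#' @return A `walk_corpus`: list with `walks` (list of node-id character
#'   vectors) and the configuration.
#' @export
generate_walks <- function(graph, p = 1, q = 1, walk_length = 80,
                           walks_per_node = 10, seed = 1) {
  stopifnot(inherits(graph, "walk_graph"))
  if (p <= 0 || q <= 0) abort("`p` and `q` must be positive.")
  if (walk_length < 2L) abort("`walk_length` must be at least 2.")
  if (walks_per_node < 1L) abort("`walks_per_node` must be at least 1.")
  deg <- diff(graph$indptr)
  if (all(deg == 0L)) abort("Graph has no edges.")
  if (any(deg == 0L)) {
    warn(sprintf("Skipping %d isolated node(s) with no walks.", sum(deg == 0L)))
  }
  raw <- cpp_generate_walks(graph$indptr, graph$indices, graph$weights,
                            p, q, as.integer(walk_length),
                            as.integer(walks_per_node), as.numeric(seed))
  structure(
    list(
      walks = lapply(raw, function(w) graph$nodes[w + 1L]),
      config = list(p = p, q = q, walk_length = walk_length,
                    walks_per_node = walks_per_node, seed = seed)
    ),
    class = "walk_corpus"
  )
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf("Walk corpus: %d walks (length <= %d, p = %g, q = %g, seed %d)\n",
              length(x$walks), x$config$walk_length, x$config$p, x$config$q,
              x$config$seed))
  invisible(x)
}

#' Train skip-gram node embeddings on a walk corpus
#'
#' Learns a `dim`-dimensional vector for every node that appears in at
#' least one walk, by skip-gram with negative sampling (single-threaded
#' stochastic gradient descent, 5 negative samples per context, linearly
#' decaying learning rate), treating each walk as a sentence. Deterministic
#' given the seed.
#'
#' @param corpus A [generate_walks()] corpus.
#' @param dim Embedding dimension. Default 64.
#' @param window Context window half-width. Default 10.
#' @param epochs Passes over the corpus. Default 5.
#' @param negative Negative samples per context pair. Default 5.
#' @param alpha Initial learning rate. Default 0.025.
#' @param seed RNG seed. Default 1.
#' @return Numeric matrix, one row per walked node (ids as row names).
#' @export
train_skipgram <- function(corpus, dim = 64, window = 10, epochs = 5,
                           negative = 5, alpha = 0.025, seed = 1) {
  stopifnot(inherits(corpus, "walk_corpus"))
  if (length(corpus$walks) == 0L) abort("Walk corpus is empty.")
  if (dim < 1L || window < 1L || epochs < 1L) {
    abort("`dim`, `window` and `epochs` must be at least 1.")
  }
  vocab <- sort(unique(unlist(corpus$walks, use.names = FALSE)))
  idx_walks <- lapply(corpus$walks, function(w) match(w, vocab) - 1L)
  mat <- cpp_train_skipgram(idx_walks, length(vocab), as.integer(dim),
                            as.integer(window), as.integer(epochs),
                            as.integer(negative), alpha, 1e-4,
                            as.numeric(seed))
  rownames(mat) <- vocab
  mat
}

#' Node embeddings of an association network via biased walks + skip-gram
#'
#' Convenience wrapper chaining [walk_graph()], [generate_walks()] and
#' [train_skipgram()] with the published walk defaults.
#'
#' @param x An `assoc_tbl` or edge data frame.
#' @param dim Embedding dimension. Default 64.
#' @param p,q Walk bias parameters. Default 1.
#' @param walk_length,walks_per_node,window,epochs Walk/training
#'   hyperparameters (defaults 80, 10, 10, 5).
#' @param seed RNG seed used for both walks and training. Default 1.
#' @return Embedding matrix with node ids as row names.
#' @export
node2vec_embed <- function(x, dim = 64, p = 1, q = 1, walk_length = 80,
                           walks_per_node = 10, window = 10, epochs = 5,
                           seed = 1) {
  graph <- walk_graph(x)
  corpus <- generate_walks(graph, p = p, q = q, walk_length = walk_length,
                           walks_per_node = walks_per_node, seed = seed)
  train_skipgram(corpus, dim = dim, window = window, epochs = epochs,
                 seed = derive_seed(seed, 1013L))
}
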