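#' Unified adjacency of the drug-disease association network
#'
#' Builds the `n x n` symmetric bipartite adjacency over the canonical node
#' order (drugs first, diseases second): `A[i, n_d + j] = 1` iff drug `i`
#' associates with disease `j`; within-drug and within-disease blocks are
#' zero. The self-looped adjacency `A~ = A + I` and its degree vector are
#' computed alongside, ready for graph-convolution propagation.
#'
#' @param assoc An [as_association_table()] tibble.
#' @return A `unified_adjacency`: list with matrices `A`, `A_tilde`, the
#'   degree vector `degree` (row sums of `A_tilde`), and the id vectors.
#' @export
build_adjacency <- function(assoc) {
  stopifnot(inherits(assoc, "assoc_tbl"))
  ids <- node_ids(assoc)
  n <- length(ids)
  nd <- n_drugs(assoc)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(assoc$drug_id, drug_ids(assoc))
  j <- nd + match(assoc$disease_id, disease_ids(assoc))
  A[cbind(i, j)] <- 1
  A[cbind(j, i)] <- 1
  A_tilde <- A + diag(n)
  structure(
    list(
      A = A,
      A_tilde = A_tilde,
      degree = rowSums(A_tilde),
      drug_ids = drug_ids(assoc),
      disease_ids = disease_ids(assoc)
    ),
    class = "unified_adjacency"
  )
}

#' Random weight initialisation for the graph-convolution projection
#'
#' @param k Input (attribute) dimension.
#' @param m Output dimension.
#' @param seed Integer RNG seed; the draw is deterministic given the seed.
#' @param scheme `"glorot_uniform"` (uniform on
#'   `±sqrt(6 / (k + m))`) or `"gaussian"` (`N(0, 1/k)`).
#' @return Numeric `k x m` matrix.
#' @export
init_weights <- function(k, m, seed, scheme = c("glorot_uniform", "gaussian")) {
  scheme <- match.arg(scheme)
  if (k < 1L || m < 1L) abort("`k` and `m` must be at least 1.")
  with_seed(seed, {
    if (scheme == "glorot_uniform") {
      lim <- sqrt(6 / (k + m))
      matrix(runif(k * m, -lim, lim), k, m)
    } else {
      matrix(stats::rnorm(k * m, sd = sqrt(1 / k)), k, m)
    }
  })
}

#' One-pass graph-convolution feature propagation
#'
#' Propagates node attributes over the self-looped association adjacency
#' with a random linear projection and a nonlinearity. The default
#' (`mode = "simplified"`) computes `H = sigma(A~ X W)`: each node's
#' attributes are summed with its neighbours' (the self-loop keeps its own)
#' and projected to `m` dimensions. The `"normalized"` mode applies the
#' symmetric degree normalisation first:
#' `H = sigma(D~^{-1/2} A~ D~^{-1/2} X W)`. `W` is a single random,
#' untrained projection: the stage is a fixed random graph filter, not a
#' trained network (see the methods vignette), so the seed is part of the
#' configuration and recorded in the result.
#'
#' @param adj A [build_adjacency()] object.
#' @param X Attribute matrix `n x k` (see [build_attribute_matrix()]).
#' @param W Optional `k x m` weight matrix; drawn by [init_weights()] from
#'   `seed` when omitted.
#' @param m Output dimension when `W` is drawn internally. Default 64.
#' @param mode `"simplified"` (default) or `"normalized"`.
#' @param activation `"relu"` (default) or `"identity"`.
#' @param seed Seed for the weight draw. Default 1.
#' @param scheme Weight initialisation scheme, see [init_weights()].
#' @return A `gcn_features` object: list with the `n x m` matrix `H` (node
#'   ids as row names) and the configuration used.
#' @export
gcn_propagate <- function(adj, X, W = NULL, m = 64,
                          mode = c("simplified", "normalized"),
                          activation = c("relu", "identity"),
                          seed = 1, scheme = "glorot_uniform") {
  stopifnot(inherits(adj, "unified_adjacency"))
  mode <- match.arg(mode)
  activation <- match.arg(activation)
  n <- nrow(adj$A_tilde)
  if (!is.matrix(X) || nrow(X) != n) {
    abort(sprintf("`X` must have %d rows (one per node); got %s.",
                  n, if (is.matrix(X)) nrow(X) else class(X)[1L]))
  }
  if (is.null(W)) {
    W <- init_weights(ncol(X), m, seed = seed, scheme = scheme)
  }
  if (nrow(W) != ncol(X)) {
    abort(sprintf("Dimension mismatch: X is %dx%d but W has %d rows.",
                  nrow(X), ncol(X), nrow(W)))
  }
  P <- if (mode == "simplified") {
    adj$A_tilde
  } else {
    dinv <- 1 / sqrt(adj$degree)
    # D^{-1/2} A~ D^{-1/2} as row/column scaling
    adj$A_tilde * tcrossprod(dinv)
  }
  H <- P %*% (X %*% W)
  if (activation == "relu") H <- relu(H)
  rownames(H) <- rownames(adj$A_tilde)
  structure(
    list(H = H, mode = mode, activation = activation, seed = seed,
         m = ncol(W), scheme = scheme),
    class = "gcn_features"
  )
}

#' @export
as.matrix.gcn_features <- function(x, ...) x$H

#' @export
print.gcn_features <- function(x, ...) {
  cat(sprintf(
    "Graph-convolution features: %d nodes x %d dims (%s mode, %s activation, seed %d)\n",
    nrow(x$H), ncol(x$H), x$mode, x$activation, x$seed
  ))
  invisible(x)
}
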