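#' Build the ancestor DAG of a disease from its tree numbers
#'
#' A MeSH-style tree number encodes the full path from a hierarchy root to
#' the disease: every dot-prefix of a code is an ancestor. The DAG of a
#' disease therefore contains every prefix of every code as a node, with an
#' edge from each prefix to its one-component extension. A disease holding
#' several tree numbers occupies several positions in the hierarchy; all of
#' its full codes are "self" nodes.
#'
#' @param tree_numbers Character vector of dot-separated codes
#'   (e.g. `"C04.557.337"`).
#' @param disease_id Optional identifier attached for error reporting.
#' @return A `disease_dag`: list with `disease_id`, `nodes` (character),
#'   `edges` (tibble `parent`, `child`), and `self_codes` (the disease's own
#'   full codes).
#' @examples
#' dag <- build_disease_dag(c("C04.557", "C04.588"))
#' dag$nodes
#' @export
build_disease_dag <- function(tree_numbers, disease_id = NULL) {
  tree_numbers <- unique(tree_numbers[nzchar(tree_numbers)])
  if (length(tree_numbers) == 0L) {
    abort(sprintf("Disease %shas no tree numbers.",
                  if (is.null(disease_id)) "" else paste0("'", disease_id, "' ")))
  }
  bad <- tree_numbers[!grepl(tree_number_regex, tree_numbers)]
  if (length(bad) > 0L) {
    abort(sprintf("Invalid tree number '%s'%s.", bad[1L],
                  if (is.null(disease_id)) "" else paste0(" for disease '", disease_id, "'")))
  }
  parts <- strsplit(tree_numbers, ".", fixed = TRUE)
  nodes <- character(0)
  parent <- character(0)
  child <- character(0)
  for (p in parts) {
    prefixes <- vapply(seq_along(p), function(k) paste(p[seq_len(k)], collapse = "."), "")
    nodes <- c(nodes, prefixes)
    if (length(prefixes) > 1L) {
      parent <- c(parent, prefixes[-length(prefixes)])
      child <- c(child, prefixes[-1L])
    }
  }
  edges <- dplyr::distinct(tibble::tibble(parent = parent, child = child))
  structure(
    list(
      disease_id = disease_id,
      nodes = sort(unique(nodes)),
      edges = edges,
      self_codes = sort(tree_numbers)
    ),
    class = "disease_dag"
  )
}

node_depth <- function(codes) {
  lengths(strsplit(codes, ".", fixed = TRUE))
}

#' Semantic contribution of every DAG node to its disease
#'
#' The disease's own codes contribute exactly 1. Every ancestor node `t`
#' contributes the maximum, over its children `t'` in the DAG, of
#' `mu * D(t')`: one decay factor per edge separating the ancestor from the
#' disease, taking the best (shortest) path when several exist. Computed by
#' dynamic programming in reverse topological (deepest-first) order.
#'
#' @param dag A [build_disease_dag()] object.
#' @param mu Semantic decay factor per edge, in (0, 1). Default 0.5.
#' @return A `contribution_map`: list with `disease_id`, named numeric
#'   `contributions` over DAG nodes (all in (0, 1]), and `mu`.
#' @examples
#' dag <- build_disease_dag("C04.557.337")
#' semantic_contribution(dag, mu = 0.5)$contributions
#' @export
semantic_contribution <- function(dag, mu = 0.5) {
  stopifnot(inherits(dag, "disease_dag"))
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0 || mu >= 1) {
    abort("`mu` must be a single number in (0, 1).")
  }
  nodes <- dag$nodes
  depth <- node_depth(nodes)
  # prefix DAGs are acyclic by construction: every edge increases depth by 1
  if (nrow(dag$edges) > 0L) {
    dp <- node_depth(dag$edges$parent)
    dc <- node_depth(dag$edges$child)
    if (any(dc <= dp)) {
      abort(sprintf("Cycle or malformed edge detected in DAG%s.",
                    if (is.null(dag$disease_id)) "" else paste0(" of '", dag$disease_id, "'")))
    }
  }
  contrib <- setNames(rep(NA_real_, length(nodes)), nodes)
  contrib[dag$self_codes] <- 1
  children_of <- split(dag$edges$child, dag$edges$parent)
  for (t in nodes[order(depth, decreasing = TRUE)]) {
    if (!is.na(contrib[[t]])) next  # self code
    ch <- children_of[[t]]
    if (is.null(ch)) {
      abort(sprintf("Node '%s' is neither a self code nor has children.", t))
    }
    contrib[[t]] <- mu * max(contrib[ch])
  }
  structure(
    list(disease_id = dag$disease_id, contributions = contrib, mu = mu),
    class = "contribution_map"
  )
}

#' Semantic value of a disease: the sum of all node contributions
#' @param cmap A [semantic_contribution()] map.
#' @return A number `>= 1` (the disease's own code alone contributes 1).
#' @export
semantic_value <- function(cmap) {
  stopifnot(inherits(cmap, "contribution_map"))
  if (length(cmap$contributions) == 0L) abort("Empty contribution map.")
  sum(cmap$contributions)
}

#' Semantic similarity between two diseases
#'
#' Shared ancestors contribute from both sides; the sum of their paired
#' contributions is normalised by the two semantic values:
#' `sum_{t in A∩B} (D_a(t) + D_b(t)) / (DV(a) + DV(b))`. The measure lies in
#' `[0, 1]`, is symmetric, equals 1 for identical DAGs and 0 for disjoint
#' ones.
#'
#' @param cmap_a,cmap_b Contribution maps from [semantic_contribution()].
#' @return A similarity value in `[0, 1]`.
#' @export
disease_similarity <- function(cmap_a, cmap_b) {
  stopifnot(inherits(cmap_a, "contribution_map"),
            inherits(cmap_b, "contribution_map"))
  shared <- intersect(names(cmap_a$contributions), names(cmap_b$contributions))
  if (length(shared) == 0L) return(0)
  num <- sum(cmap_a$contributions[shared] + cmap_b$contributions[shared])
  num / (semantic_value(cmap_a) + semantic_value(cmap_b))
}

#' Pairwise disease semantic similarity matrix
#'
#' Builds each disease's ancestor DAG, evaluates semantic contributions at
#' decay `mu`, and fills the full symmetric similarity matrix over the
#' canonical (lexicographic) disease order.
#'
#' @param tree_tbl Long tibble with columns `disease_id` and `tree_number`
#'   (as returned by [read_tree_numbers()]).
#' @param mu Semantic decay factor, default 0.5.
#' @return A symmetric numeric matrix of class `similarity_matrix` with unit
#'   diagonal and disease ids as dimnames.
#' @export
disease_similarity_matrix <- function(tree_tbl, mu = 0.5) {
  if (!is.data.frame(tree_tbl) ||
      !all(c("disease_id", "tree_number") %in% names(tree_tbl))) {
    abort("`tree_tbl` needs columns `disease_id` and `tree_number`.")
  }
  ids <- sort(unique(tree_tbl$disease_id))
  if (length(ids) == 0L) abort("No diseases in tree-number table.")
  codes <- split(tree_tbl$tree_number, tree_tbl$disease_id)
  cmaps <- lapply(ids, function(id) {
    tryCatch(
      semantic_contribution(build_disease_dag(codes[[id]], disease_id = id), mu = mu),
      error = function(e) {
        abort(sprintf("Disease '%s': %s", id, conditionMessage(e)))
      }
    )
  })
  n <- length(ids)
  sims <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        s <- disease_similarity(cmaps[[i]], cmaps[[j]])
        sims[i, j] <- s
        sims[j, i] <- s
      }
    }
  }
  dimnames(sims) <- list(ids, ids)
  structure(sims, mu = mu, class = c("similarity_matrix", "matrix", "array"))
}

#' @export
tidy.similarity_matrix <- function(x, ...) {
  tibble::tibble(
    disease_a = rep(rownames(x), times = ncol(x)),
    disease_b = rep(colnames(x), each = nrow(x)),
    similarity = as.vector(x)
  )
}

#' Heatmap of a disease similarity matrix
#' @param object A [disease_similarity_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- tidy.similarity_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$disease_a, .data$disease_b,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Semantic\nsimilarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
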