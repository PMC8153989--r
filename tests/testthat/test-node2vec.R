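path_graph <- function() {
  # t - v - x with no t-x edge
  walk_graph(data.frame(from = c("t", "v"), to = c("v", "x")))
}

test_that("transition bias implements the p/q step weighting", {
  expect_equal(transition_bias(0, p = 4, q = 1), 0.25)
  expect_equal(transition_bias(1, p = 4, q = 9), 1)
  expect_equal(transition_bias(2, p = 1, q = 2), 0.5)
  expect_equal(transition_bias(c(0, 1, 2), p = 1, q = 1), c(1, 1, 1))
  expect_error(transition_bias(3, 1, 1), "0, 1 or 2")
  expect_error(transition_bias(1, -1, 1), "positive")
})

test_that("step distribution matches hand-derived cases", {
  # triangle: both neighbours of v are at distance <= 1 from t
  tri <- walk_graph(data.frame(from = c("t", "v", "t"), to = c("v", "x", "x")))
  d <- step_distribution(tri, "t", "v", p = 1, q = 1)
  expect_equal(sort(d$prob), c(0.5, 0.5))

  # path t-v-x: returning has bias 1/p = 1, moving out 1/q = 1/2
  d <- step_distribution(path_graph(), "t", "v", p = 1, q = 2)
  expect_equal(d$prob[d$node == "t"], 2 / 3)
  expect_equal(d$prob[d$node == "x"], 1 / 3)

  # star centre v with three leaves including t
  star <- walk_graph(data.frame(from = "v", to = c("t", "a", "b")))
  d <- step_distribution(star, "t", "v", p = 2, q = 3)
  expect_equal(d$prob[d$node == "t"], 3 / 7)
  expect_equal(d$prob[d$node == "a"], 2 / 7)
  expect_equal(d$prob[d$node == "b"], 2 / 7)

  # no predecessor: first step is weight-proportional
  d0 <- step_distribution(star, NULL, "v", p = 9, q = 9)
  expect_equal(d0$prob, rep(1 / 3, 3))
})

test_that("step distributions are proper and vanish off the neighbour set", {
  set.seed(91)
  for (i in 1:20) {
    g <- walk_graph(random_edge_graph(sample(4:6, 1L)))
    # pick a random traversed edge (t, v)
    deg <- diff(g$indptr)
    v <- sample(which(deg > 0), 1L)
    t <- g$indices[g$indptr[v] + 1L] + 1L
    p <- runif(1, 0.3, 3); q <- runif(1, 0.3, 3)
    d <- step_distribution(g, g$nodes[t], g$nodes[v], p, q)
    expect_equal(sum(d$prob), 1)
    nb <- g$nodes[g$indices[(g$indptr[v] + 1L):g$indptr[v + 1L]] + 1L]
    expect_setequal(d$node, nb)

    # p = q = 1 reduces exactly to the weight-proportional walk
    d1 <- step_distribution(g, g$nodes[t], g$nodes[v], 1, 1)
    expect_equal(d1$prob, rep(1 / length(nb), length(nb)))
  }
})

test_that("walks are valid paths, reproducible, and respect dead ends", {
  two <- walk_graph(data.frame(from = "a", to = "b"))
  corpus <- generate_walks(two, walk_length = 4, walks_per_node = 3, seed = 1)
  expect_length(corpus$walks, 6L)
  for (w in corpus$walks) {
    expect_length(w, 4L)
    expect_true(all(w == c("a", "b", "a", "b") | w == c("b", "a", "b", "a")))
  }

  g <- walk_graph(random_edge_graph(6, 0.5))
  c1 <- generate_walks(g, p = 2, q = 0.5, walk_length = 10,
                       walks_per_node = 4, seed = 9)
  c2 <- generate_walks(g, p = 2, q = 0.5, walk_length = 10,
                       walks_per_node = 4, seed = 9)
  expect_identical(c1$walks, c2$walks)
  # consecutive nodes are neighbours; each walk starts at its source
  edge_set <- paste(rep(g$nodes, diff(g$indptr)), g$nodes[g$indices + 1L])
  for (w in c1$walks) {
    steps <- paste(head(w, -1L), w[-1L])
    expect_true(all(steps %in% edge_set))
  }

  # isolated node: warned and skipped
  iso <- walk_graph(data.frame(from = "a", to = "b"))
  iso$nodes <- c(iso$nodes, "lonely")
  iso$indptr <- c(iso$indptr, iso$indptr[length(iso$indptr)])
  expect_warning(generate_walks(iso, walk_length = 3, walks_per_node = 1),
                 "isolated")
})

test_that("empirical first-step frequencies match the exact distribution", {
  g <- path_graph()
  drawn <- sample_steps(g, "t", "v", p = 1, q = 2, n = 100000, seed = 3)
  freq <- table(drawn) / length(drawn)
  exact <- step_distribution(g, "t", "v", p = 1, q = 2)
  expect_equal(as.numeric(freq[exact$node]), exact$prob, tolerance = 0.01)
})

test_that("skip-gram embeds walked nodes deterministically", {
  g <- walk_graph(random_edge_graph(6, 0.6))
  corpus <- generate_walks(g, walk_length = 10, walks_per_node = 20, seed = 4)
  E1 <- train_skipgram(corpus, dim = 8, window = 3, epochs = 2, seed = 5)
  E2 <- train_skipgram(corpus, dim = 8, window = 3, epochs = 2, seed = 5)
  expect_identical(E1, E2)
  expect_equal(ncol(E1), 8L)
  expect_setequal(rownames(E1), unique(unlist(corpus$walks)))
  expect_true(all(is.finite(E1)))

  expect_error(
    train_skipgram(structure(list(walks = list(), config = list()),
                             class = "walk_corpus")),
    "empty"
  )
})

test_that("structurally equivalent nodes embed closer than distant ones", {
  # two 4-cliques joined by one bridge: members of the same clique must be
  # more similar than members of opposite cliques
  cl1 <- t(utils::combn(paste0("a", 1:4), 2L))
  cl2 <- t(utils::combn(paste0("b", 1:4), 2L))
  edges <- rbind(as.data.frame(cl1), as.data.frame(cl2),
                 data.frame(V1 = "a1", V2 = "b1"))
  E <- node2vec_embed(edges, dim = 16, walk_length = 20, walks_per_node = 30,
                      window = 4, epochs = 5, seed = 11)
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  within <- cosine(E["a2", ], E["a3", ])
  across <- cosine(E["a2", ], E["b3", ])
  expect_gt(within, across)
})
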