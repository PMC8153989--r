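test_that("ancestor DAGs expand every dot-prefix of every code", {
  dag <- build_disease_dag("C04.557")
  expect_setequal(dag$nodes, c("C04", "C04.557"))
  expect_equal(nrow(dag$edges), 1L)

  dag <- build_disease_dag(c("C04.557", "C04.588"))
  expect_setequal(dag$nodes, c("C04", "C04.557", "C04.588"))
  expect_equal(nrow(dag$edges), 2L)

  # shared prefixes deduplicate; a self code may be an internal node
  dag <- build_disease_dag(c("C04.557.337", "C04.557"))
  expect_setequal(dag$nodes, c("C04", "C04.557", "C04.557.337"))
  expect_equal(nrow(dag$edges), 2L)
  expect_equal(dag$self_codes, c("C04.557", "C04.557.337"))

  expect_error(build_disease_dag(character(0)), "no tree numbers")
  expect_error(build_disease_dag("c04.1"), "Invalid tree number")
})

test_that("semantic contributions decay by mu per edge up the chain", {
  # 3-node chain: the disease's own code gets 1, each ancestor mu * child
  cmap <- semantic_contribution(build_disease_dag("C1.10.20"), mu = 0.5)
  expect_equal(cmap$contributions[["C1.10.20"]], 1)
  expect_equal(cmap$contributions[["C1.10"]], 0.5)
  expect_equal(cmap$contributions[["C1"]], 0.25)

  # single node
  cmap <- semantic_contribution(build_disease_dag("C1"), mu = 0.9)
  expect_equal(cmap$contributions, c(C1 = 1))

  # diamond: two self codes at depths 1 and 2 below the root; the root
  # takes the better (shorter) path: max(0.5 * 1, 0.5 * 0.5) = 0.5
  dag <- build_disease_dag(c("C1.10", "C1.20.30"))
  cmap <- semantic_contribution(dag, mu = 0.5)
  expect_equal(cmap$contributions[["C1"]], 0.5)

  expect_error(semantic_contribution(build_disease_dag("C1.1"), mu = 1), "mu")
})

test_that("semantic value sums the contribution map", {
  cmap <- semantic_contribution(build_disease_dag("C1.10.20"), mu = 0.5)
  expect_equal(semantic_value(cmap), 1.75)
  expect_equal(semantic_value(semantic_contribution(build_disease_dag("C1"), 0.5)), 1)
  expect_equal(semantic_value(semantic_contribution(build_disease_dag("C1.10"), 0.5)), 1.5)
})

test_that("pairwise similarity matches hand-computed values", {
  mu <- 0.5
  a <- semantic_contribution(build_disease_dag("C1.10.20"), mu)
  expect_equal(disease_similarity(a, a), 1)

  b <- semantic_contribution(build_disease_dag("D1.10.20"), mu)
  expect_equal(disease_similarity(a, b), 0)

  # two length-2 chains sharing only the root: (0.25 + 0.25) / (1.75 + 1.75)
  c2 <- semantic_contribution(build_disease_dag("C1.30.40"), mu)
  expect_equal(disease_similarity(a, c2), 0.5 / 3.5)
  expect_equal(disease_similarity(a, c2), disease_similarity(c2, a))
})

test_that("similarity matrix is symmetric with unit diagonal", {
  tbl <- tibble::tibble(
    disease_id = c("z1", "z2", "z3"),
    tree_number = c("C1.10.20", "C1.30.40", "D9.10")
  )
  sims <- disease_similarity_matrix(tbl, mu = 0.5)
  expect_equal(diag(sims), setNames(rep(1, 3), c("z1", "z2", "z3")))
  expect_equal(unclass(sims), t(unclass(sims)), ignore_attr = TRUE)
  expect_equal(sims["z1", "z2"], 0.5 / 3.5)
  expect_equal(sims["z1", "z3"], 0)

  one <- disease_similarity_matrix(tbl[1L, ])
  expect_equal(unclass(one), matrix(1, 1, 1, dimnames = list("z1", "z1")),
               ignore_attr = TRUE)
  expect_error(
    disease_similarity_matrix(tibble::tibble(disease_id = "z", tree_number = "bad")),
    "Disease 'z'"
  )
})

test_that("dynamic programming agrees with path-enumeration oracle", {
  set.seed(401)
  for (i in 1:60) {
    mu <- runif(1, 0.2, 0.8)
    dag_a <- build_disease_dag(random_tree_numbers())
    dag_b <- build_disease_dag(random_tree_numbers())
    ca <- semantic_contribution(dag_a, mu)
    expect_equal(ca$contributions, oracle_contribution(dag_a, mu),
                 tolerance = 1e-12)
    cb <- semantic_contribution(dag_b, mu)
    expect_equal(disease_similarity(ca, cb), oracle_similarity(dag_a, dag_b, mu),
                 tolerance = 1e-12)
    expect_equal(disease_similarity(ca, cb), disease_similarity(cb, ca))
    expect_equal(disease_similarity(ca, ca), 1)
  }
})

test_that("adding a shared ancestor never decreases similarity", {
  # argued directly on contribution maps: appending equal-keyed entries to
  # both maps adds the same mass to numerator and denominators
  set.seed(402)
  for (i in 1:25) {
    mu <- 0.5
    a <- semantic_contribution(build_disease_dag(random_tree_numbers()), mu)
    b <- semantic_contribution(build_disease_dag(random_tree_numbers()), mu)
    before <- disease_similarity(a, b)
    extra <- runif(1, 0.05, 1)
    a$contributions <- c(a$contributions, SHARED = extra)
    b$contributions <- c(b$contributions, SHARED = extra)
    expect_gte(disease_similarity(a, b) + 1e-12, before)
  }
})
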