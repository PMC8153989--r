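test_that("extreme block settings produce the expected topology", {
  # density 1, background 0: the biadjacency is exactly block-diagonal
  spec <- synthetic_spec(n_drugs = 12, n_diseases = 15, n_blocks = 3,
                         density = 1, background = 0, seed = 3)
  net <- simulate_network(spec)
  same <- net$drug_blocks[net$associations$drug_id] ==
    net$disease_blocks[net$associations$disease_id]
  expect_true(all(same))
  expect_equal(nrow(net$associations),
               sum(outer(net$drug_blocks, net$disease_blocks, "==")))

  # density == background degenerates to a binomial edge draw
  spec <- synthetic_spec(n_drugs = 40, n_diseases = 40, n_blocks = 2,
                         density = 0.2, background = 0.199999, seed = 4)
  net <- simulate_network(spec)
  expected <- 40 * 40 * 0.2
  sigma <- sqrt(40 * 40 * 0.2 * 0.8)
  expect_lt(abs(nrow(net$associations) - expected), 3 * sigma)
})

test_that("generators are pure functions of the spec", {
  spec <- synthetic_spec(n_drugs = 10, n_diseases = 12, seed = 99)
  n1 <- simulate_network(spec)
  n2 <- simulate_network(spec)
  expect_identical(n1$associations, n2$associations)
  expect_identical(n1$drug_blocks, n2$drug_blocks)
  a1 <- simulate_attributes(spec, n1)
  a2 <- simulate_attributes(spec, n2)
  expect_identical(a1, a2)
})

test_that("attributes carry the planted block signal", {
  spec <- synthetic_spec(n_drugs = 20, n_diseases = 30, n_blocks = 3,
                         attr_noise = 0, seed = 5)
  net <- simulate_network(spec)
  attrs <- simulate_attributes(spec, net)

  # zero noise: within-block fingerprints are identical
  for (b in unique(net$drug_blocks)) {
    rows <- attrs$fingerprints[net$drug_blocks == b, , drop = FALSE]
    expect_true(all(apply(rows, 2L, function(col) length(unique(col)) == 1L)))
  }

  # within-block semantic similarity exceeds between-block similarity
  sims <- disease_similarity_matrix(attrs$tree_numbers, mu = 0.5)
  blocks <- net$disease_blocks[rownames(sims)]
  same_block <- outer(blocks, blocks, "==") & upper.tri(sims)
  diff_block <- !outer(blocks, blocks, "==") & upper.tri(sims)
  expect_gt(mean(sims[same_block]), mean(sims[diff_block]))

  # maximal noise destroys the fingerprint-block association
  spec50 <- synthetic_spec(n_drugs = 60, n_diseases = 30, n_blocks = 2,
                           attr_noise = 0.5, attr_bits = 64, seed = 6)
  net50 <- simulate_network(spec50)
  attrs50 <- simulate_attributes(spec50, net50)
  # mean within-block Hamming agreement ~ mean across-block agreement
  fp <- attrs50$fingerprints
  agree <- 1 - as.matrix(stats::dist(fp, method = "manhattan")) / ncol(fp)
  blocks <- net50$drug_blocks[rownames(fp)]
  same <- outer(blocks, blocks, "==") & upper.tri(agree)
  diff <- !outer(blocks, blocks, "==") & upper.tri(agree)
  expect_lt(abs(mean(agree[same]) - mean(agree[diff])), 0.05)
})

test_that("the canonical benchmark writes parseable, reproducible files", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- synthetic_spec()
  p1 <- make_benchmark(spec, dir1)
  p2 <- make_benchmark(spec, dir2)

  # all files parse through the io layer
  assoc <- read_associations(p1$associations)
  fps <- read_fingerprints(p1$fingerprints)
  trees <- read_tree_numbers(p1$tree_numbers)
  expect_true(all(drug_ids(assoc) %in% rownames(fps)))
  expect_true(all(disease_ids(assoc) %in% trees$disease_id))
  expect_equal(ncol(fps), spec$attr_bits)

  # positive-pair count sits in the binomial band implied by the spec
  # (expectation 60*100*(0.25*0.30 + 0.75*0.02) = 540, sd ~ 22)
  expect_gt(nrow(assoc), 460)
  expect_lt(nrow(assoc), 620)

  # byte-identical regeneration from the same spec
  for (f in c("associations", "fingerprints", "tree_numbers", "manifest")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }

  manifest <- jsonlite::read_json(p1$manifest)
  expect_equal(manifest$spec$seed, spec$seed)
  expect_equal(manifest$n_positive_pairs, nrow(assoc))
})
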