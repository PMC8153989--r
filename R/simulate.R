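#' Specification of a synthetic drug-disease benchmark
#'
#' Describes a planted-block bipartite benchmark that mimics the
#' statistical shape of a curated drug-disease association corpus: a
#' sparse bipartite graph whose edges concentrate within latent
#' drug/disease blocks, binary drug fingerprints correlated with the
#' blocks, and small block-structured disease ontologies whose semantic
#' similarities separate the blocks. The defaults are the package's
#' canonical test fixture: 60 drugs x 100 diseases in 4 blocks at
#' within-block edge density 0.30 over background 0.02 (overall density
#' about 9%), 256 fingerprint bits flipped with probability 0.05, ontology
#' depth 4, seed 7.
#'
#' @param n_drugs,n_diseases,n_blocks Network dimensions.
#' @param density Edge probability for same-block pairs.
#' @param background Edge probability for cross-block pairs
#'   (`background < density`).
#' @param attr_bits Fingerprint length.
#' @param attr_noise Per-bit flip probability applied to each drug's block
#'   prototype, in `[0, 0.5]`.
#' @param dag_depth Maximum tree-number depth of the simulated ontology.
#' @param seed Seed; every generator below is a pure function of the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_drugs = 60, n_diseases = 100, n_blocks = 4,
                           density = 0.30, background = 0.02,
                           attr_bits = 256, attr_noise = 0.05,
                           dag_depth = 4, seed = 7) {
  if (background < 0 || background >= density || density > 1) {
    abort("Need 0 <= background < density <= 1.")
  }
  if (n_blocks > min(n_drugs, n_diseases)) {
    abort("`n_blocks` cannot exceed min(n_drugs, n_diseases).")
  }
  if (attr_noise < 0 || attr_noise > 0.5) {
    abort("`attr_noise` must lie in [0, 0.5].")
  }
  if (dag_depth < 2) abort("`dag_depth` must be at least 2.")
  structure(
    list(n_drugs = n_drugs, n_diseases = n_diseases, n_blocks = n_blocks,
         density = density, background = background, attr_bits = attr_bits,
         attr_noise = attr_noise, dag_depth = dag_depth, seed = seed),
    class = "synthetic_spec"
  )
}

#' Simulate a planted-block association network
#'
#' Drugs and diseases are assigned to blocks uniformly at random; each
#' drug-disease cell becomes an edge with probability `density` when the
#' two blocks match and `background` otherwise.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `associations` (an [as_association_table()]),
#'   `drug_blocks` and `disease_blocks` (named integer vectors over all
#'   simulated ids, including any left isolated by the edge draw).
#' @export
simulate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d_ids <- sprintf("drug%03d", seq_len(spec$n_drugs))
  z_ids <- sprintf("dis%03d", seq_len(spec$n_diseases))
  with_seed(spec$seed, {
    drug_blocks <- setNames(sample.int(spec$n_blocks, spec$n_drugs, replace = TRUE), d_ids)
    disease_blocks <- setNames(sample.int(spec$n_blocks, spec$n_diseases, replace = TRUE), z_ids)
    same <- outer(drug_blocks, disease_blocks, "==")
    prob <- ifelse(same, spec$density, spec$background)
    edge <- matrix(runif(length(prob)) < prob, nrow = spec$n_drugs)
    hit <- which(edge, arr.ind = TRUE)
    if (nrow(hit) == 0L) abort("Simulated network has no edges; increase density.")
    list(
      associations = as_association_table(data.frame(
        drug_id = d_ids[hit[, 1L]], disease_id = z_ids[hit[, 2L]]
      )),
      drug_blocks = drug_blocks,
      disease_blocks = disease_blocks
    )
  })
}

#' Simulate block-correlated node attributes
#'
#' Each block owns a random prototype fingerprint (balanced bits); a
#' drug's fingerprint is its block prototype with independent bit flips at
#' rate `attr_noise`. Each block also owns a random ontology "spine" (a
#' chain of tree-number components under a block-specific root); a
#' disease's tree numbers extend a random prefix of its block's spine by a
#' private component, so within-block semantic similarities exceed
#' between-block ones (which are exactly 0 across distinct roots).
#'
#' @param spec A [synthetic_spec()].
#' @param network The [simulate_network()] result carrying the block
#'   assignments.
#' @return List with `fingerprints` (binary matrix over all drug ids) and
#'   `tree_numbers` (long tibble over all disease ids).
#' @export
simulate_attributes <- function(spec, network) {
  stopifnot(inherits(spec, "synthetic_spec"))
  drug_blocks <- network$drug_blocks
  disease_blocks <- network$disease_blocks
  with_seed(derive_seed(spec$seed, 7919L), {
    protos <- matrix(rbinom(spec$n_blocks * spec$attr_bits, 1L, 0.5),
                     nrow = spec$n_blocks)
    flips <- matrix(rbinom(length(drug_blocks) * spec$attr_bits, 1L, spec$attr_noise),
                    nrow = length(drug_blocks))
    fps <- (protos[drug_blocks, , drop = FALSE] + flips) %% 2L
    rownames(fps) <- names(drug_blocks)

    spines <- lapply(seq_len(spec$n_blocks), function(b) {
      c(sprintf("C%02d", b), as.character(sample(100:999, spec$dag_depth - 1L)))
    })
    ids <- character(0)
    codes <- character(0)
    for (i in seq_along(disease_blocks)) {
      spine <- spines[[disease_blocks[i]]]
      n_codes <- sample(1:2, 1L)
      for (k in seq_len(n_codes)) {
        depth <- sample(seq_len(spec$dag_depth - 1L), 1L)
        own <- as.character(sample(100:999, 1L))
        ids <- c(ids, names(disease_blocks)[i])
        codes <- c(codes, paste(c(spine[seq_len(depth)], own), collapse = "."))
      }
    }
    list(
      fingerprints = fps,
      tree_numbers = dplyr::distinct(tibble::tibble(disease_id = ids, tree_number = codes))
    )
  })
}

#' Write a complete synthetic benchmark to disk
#'
#' Generates the network and attributes for `spec` and writes the three
#' pipeline inputs (association TSV, fingerprint table, tree-number TSV)
#' plus a JSON manifest holding the spec, the seed and the ground-truth
#' block assignments. Rerunning with the same spec reproduces the files
#' byte-identically.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
make_benchmark <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  network <- simulate_network(spec)
  attrs <- simulate_attributes(spec, network)
  paths <- list(
    associations = file.path(dir, "associations.tsv"),
    fingerprints = file.path(dir, "fingerprints.tsv"),
    tree_numbers = file.path(dir, "tree_numbers.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  assoc <- network$associations
  writeLines(
    c("# drug_id\tdisease_id",
      paste(assoc$drug_id, assoc$disease_id, sep = "\t")),
    paths$associations
  )
  write_fingerprints(attrs$fingerprints, paths$fingerprints)
  per_disease <- split(attrs$tree_numbers$tree_number, attrs$tree_numbers$disease_id)
  writeLines(
    c("# disease_id\ttree_numbers",
      vapply(names(per_disease), function(id) {
        paste0(id, "\t", paste(per_disease[[id]], collapse = ";"))
      }, "")),
    paths$tree_numbers
  )
  jsonlite::write_json(
    list(spec = unclass(spec),
         n_positive_pairs = nrow(assoc),
         drug_blocks = as.list(network$drug_blocks),
         disease_blocks = as.list(network$disease_blocks)),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}
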