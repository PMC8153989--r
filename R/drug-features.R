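#' Morgan (circular) fingerprint of a molecule
#'
#' Hashes the circular atom neighbourhoods of a molecule up to the given
#' radius into a fixed-length binary vector. Neighbourhood enumeration and
#' hashing are delegated to the OpenBabel ECFP implementation (via
#' ChemmineOB); the native 4096-bit vector is then folded down to `n_bits`
#' by OR-ing positions modulo `n_bits`, the standard fingerprint folding
#' operation. The result is deterministic and invariant to the SMILES
#' writing order of the same molecule.
#'
#' @param smiles A single SMILES string.
#' @param radius Neighbourhood radius (bonds), 0 to 5. Default 2 (the ECFP4
#'   convention).
#' @param n_bits Folded fingerprint length, at least 8. Default 1024.
#' @param drug_id Optional identifier used in parse-error messages.
#' @return Integer 0/1 vector of length `n_bits`.
#' @examples
#' sum(morgan_fingerprint("C", radius = 0, n_bits = 64))  # one environment
#' @export
morgan_fingerprint <- function(smiles, radius = 2, n_bits = 1024, drug_id = NULL) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles))) {
    abort("`smiles` must be a single non-empty string.")
  }
  if (!radius %in% 0:5) abort("`radius` must be an integer between 0 and 5.")
  if (n_bits < 8) abort("`n_bits` must be at least 8.")
  who <- if (is.null(drug_id)) sprintf("SMILES '%s'", smiles) else sprintf("drug '%s'", drug_id)
  mol <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) abort(sprintf("Cannot parse %s: %s", who, conditionMessage(e)))
  )
  raw <- tryCatch(
    ChemmineOB::fingerprint_OB(mol, paste0("ECFP", 2L * radius)),
    error = function(e) abort(sprintf("Fingerprint failed for %s: %s", who, conditionMessage(e)))
  )
  raw <- as.numeric(raw)
  if (sum(raw) == 0) {
    abort(sprintf("No atom environments hashed for %s; refusing to emit an all-zero fingerprint.", who))
  }
  bits <- integer(n_bits)
  bits[(which(raw != 0) - 1L) %% n_bits + 1L] <- 1L
  bits
}

#' Fingerprint matrix for a drug structure table
#'
#' Applies [morgan_fingerprint()] to every drug and stacks the rows in
#' canonical (lexicographic) drug order, matching the node ordering of the
#' association network.
#'
#' @param smiles_tbl Tibble with columns `drug_id` and `smiles`
#'   (see [read_smiles_table()]).
#' @inheritParams morgan_fingerprint
#' @return Binary matrix `n_drugs x n_bits` with drug ids as row names and
#'   attributes `radius` and `n_bits`.
#' @export
fingerprint_matrix <- function(smiles_tbl, radius = 2, n_bits = 1024) {
  if (!is.data.frame(smiles_tbl) ||
      !all(c("drug_id", "smiles") %in% names(smiles_tbl))) {
    abort("`smiles_tbl` needs columns `drug_id` and `smiles`.")
  }
  ord <- order(smiles_tbl$drug_id)
  ids <- smiles_tbl$drug_id[ord]
  rows <- lapply(seq_along(ids), function(i) {
    morgan_fingerprint(smiles_tbl$smiles[ord[i]], radius = radius,
                       n_bits = n_bits, drug_id = ids[i])
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- ids
  structure(mat, radius = radius, n_bits = n_bits)
}

#' Assemble the unified node attribute matrix
#'
#' Drugs and diseases carry heterogeneous attributes (fingerprint bits vs.
#' disease-similarity profiles), but graph convolution needs a single
#' attribute dimension `k` for all `n` nodes. The two signals are merged by
#' zero-padded block concatenation: drug row `i` is
#' `[fingerprint_i | 0...0]`, disease row `j` is `[0...0 | similarity_j]`,
#' giving `k = n_bits + n_diseases`.
#'
#' @param fps Fingerprint matrix (drugs x bits, row names = drug ids).
#' @param sims Disease similarity matrix (diseases x diseases).
#' @param assoc Optional [as_association_table()] used to verify that both
#'   blocks cover the network's canonical node order.
#' @return Numeric matrix `n x k` with node ids as row names and an
#'   attribute `layout` recording the block boundary.
#' @export
build_attribute_matrix <- function(fps, sims, assoc = NULL) {
  if (!is.matrix(fps) || nrow(fps) == 0L) abort("Degenerate network: no drugs.")
  if (!is.matrix(sims) || nrow(sims) == 0L) abort("Degenerate network: no diseases.")
  if (is.null(rownames(fps))) {
    abort("`fps` must be a matrix with drug ids as row names.")
  }
  if (is.null(rownames(sims))) {
    abort("`sims` must be a matrix with disease ids as row names.")
  }
  if (!is.null(assoc)) {
    if (!identical(rownames(fps), drug_ids(assoc))) {
      abort("Fingerprint row order does not match the canonical drug order.")
    }
    if (!identical(rownames(sims), disease_ids(assoc))) {
      abort("Similarity row order does not match the canonical disease order.")
    }
  }
  n_bits <- ncol(fps)
  n_dis <- ncol(sims)
  X <- rbind(
    cbind(fps, matrix(0, nrow(fps), n_dis)),
    cbind(matrix(0, nrow(sims), n_bits), unclass(sims))
  )
  rownames(X) <- c(rownames(fps), rownames(sims))
  colnames(X) <- c(paste0("fp", seq_len(n_bits)), paste0("sim_", colnames(sims)))
  structure(X, layout = list(n_bits = n_bits, n_diseases = n_dis,
                             n_drugs = nrow(fps)))
}
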