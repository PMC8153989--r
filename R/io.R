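#' Build an association table from a data frame of drug-disease pairs
#'
#' The association table is the package's central input: a tibble of known
#' drug-disease association pairs together with the canonical node ordering
#' used by every downstream matrix. Drugs sorted lexicographically occupy
#' matrix indices `1..n_drugs`, diseases `n_drugs+1..n`, in every adjacency,
#' attribute and feature matrix derived from the table.
#'
#' @param pairs A data frame whose first two columns are drug and disease
#'   identifiers (character). Extra columns are dropped. Duplicate pairs are
#'   removed with a message reporting how many were dropped.
#' @return A tibble of class `assoc_tbl` with columns `drug_id` and
#'   `disease_id`, carrying the sorted unique id vectors as attributes
#'   `drug_ids` and `disease_ids`.
#' @examples
#' assoc <- as_association_table(
#'   data.frame(drug_id = c("d1", "d2", "d1"), disease_id = c("z1", "z1", "z2"))
#' )
#' n_drugs(assoc)
#' @export
as_association_table <- function(pairs) {
  if (!is.data.frame(pairs) || ncol(pairs) < 2L) {
    abort("`pairs` must be a data frame with at least two columns.")
  }
  tbl <- tibble::tibble(
    drug_id = as.character(pairs[[1L]]),
    disease_id = as.character(pairs[[2L]])
  )
  if (nrow(tbl) == 0L) abort("Association table is empty.")
  if (anyNA(tbl$drug_id) || anyNA(tbl$disease_id) ||
      any(tbl$drug_id == "") || any(tbl$disease_id == "")) {
    abort("Association pairs contain missing or empty identifiers.")
  }
  n_raw <- nrow(tbl)
  tbl <- dplyr::distinct(tbl, .data$drug_id, .data$disease_id)
  dropped <- n_raw - nrow(tbl)
  if (dropped > 0L) {
    message(sprintf("Dropped %d duplicate association pair(s).", dropped))
  }
  structure(
    tbl,
    drug_ids = sort(unique(tbl$drug_id)),
    disease_ids = sort(unique(tbl$disease_id)),
    class = c("assoc_tbl", class(tbl))
  )
}

#' @rdname as_association_table
#' @param x An `assoc_tbl`.
#' @export
drug_ids <- function(x) attr(x, "drug_ids")

#' @rdname as_association_table
#' @export
disease_ids <- function(x) attr(x, "disease_ids")

#' @rdname as_association_table
#' @export
n_drugs <- function(x) length(drug_ids(x))

#' @rdname as_association_table
#' @export
n_diseases <- function(x) length(disease_ids(x))

#' Node identifiers in canonical order (drugs first, then diseases)
#' @param x An `assoc_tbl`.
#' @return Character vector of length `n_drugs(x) + n_diseases(x)`.
#' @export
node_ids <- function(x) c(drug_ids(x), disease_ids(x))

#' Read a drug-disease association edge list
#'
#' Expects a TSV with one pair per line (`drug_id<TAB>disease_id`); lines
#' starting with `#` are comments. Duplicates are dropped and reported.
#'
#' @param path Path to the TSV file.
#' @return An [as_association_table()] tibble.
#' @export
read_associations <- function(path) {
  parsed <- read_tsv_fields(path, min_fields = 2L, what = "Association")
  as_association_table(data.frame(
    drug_id = vapply(parsed$fields, `[[`, "", 1L),
    disease_id = vapply(parsed$fields, `[[`, "", 2L)
  ))
}

#' Read a drug structure table (drug id, SMILES)
#'
#' @param path TSV with columns `drug_id<TAB>smiles`.
#' @return A tibble with columns `drug_id` and `smiles`, ordered as read.
#' @export
read_smiles_table <- function(path) {
  parsed <- read_tsv_fields(path, min_fields = 2L, what = "SMILES")
  tbl <- tibble::tibble(
    drug_id = vapply(parsed$fields, `[[`, "", 1L),
    smiles = vapply(parsed$fields, `[[`, "", 2L)
  )
  dup <- unique(tbl$drug_id[duplicated(tbl$drug_id)])
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate drug id(s) in SMILES table: %s",
                  paste(head(dup, 5L), collapse = ", ")))
  }
  empty <- tbl$drug_id[!nzchar(trimws(tbl$smiles))]
  if (length(empty) > 0L) {
    abort(sprintf("Empty SMILES for drug id(s): %s",
                  paste(head(empty, 5L), collapse = ", ")))
  }
  tbl
}

tree_number_regex <- "^[A-Z][0-9]+(\\.[0-9]+)*$"

#' Read a disease ontology table of MeSH-style tree numbers
#'
#' Each line maps one disease to its semicolon-separated tree numbers
#' (dot-separated hierarchy codes such as `C04.557.337`). Every code is
#' syntax-checked against `[A-Z][0-9]+(\.[0-9]+)*`.
#'
#' @param path TSV with columns `disease_id<TAB>code1;code2;...`.
#' @return A long tibble with columns `disease_id` and `tree_number`,
#'   one row per code.
#' @export
read_tree_numbers <- function(path) {
  parsed <- read_tsv_fields(path, min_fields = 2L, what = "Tree-number")
  ids <- vapply(parsed$fields, `[[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate disease id(s) in tree-number table: %s",
                  paste(head(dup, 5L), collapse = ", ")))
  }
  codes <- strsplit(vapply(parsed$fields, `[[`, "", 2L), ";", fixed = TRUE)
  codes <- lapply(codes, trimws)
  for (i in seq_along(ids)) {
    if (length(codes[[i]]) == 0L || all(!nzchar(codes[[i]]))) {
      abort(sprintf("Disease '%s' (line %d) has an empty tree-number field.",
                    ids[i], parsed$line_numbers[i]))
    }
    bad <- codes[[i]][!grepl(tree_number_regex, codes[[i]])]
    if (length(bad) > 0L) {
      abort(sprintf("Invalid tree number '%s' for disease '%s' (line %d).",
                    bad[1L], ids[i], parsed$line_numbers[i]))
    }
  }
  tibble::tibble(
    disease_id = rep(ids, lengths(codes)),
    tree_number = unlist(codes, use.names = FALSE)
  )
}

#' Write / read node embeddings in word2vec text format
#'
#' The format is the word2vec convention: a header line `n_nodes dim`
#' followed by one line per node, `id v1 ... vdim`, space-separated. The
#' round trip is lossless to at least 8 significant digits.
#'
#' @param mat Numeric matrix with node ids as row names.
#' @param path Output (or input) file path.
#' @return `write_embeddings()` returns `path` invisibly; `read_embeddings()`
#'   returns the matrix with ids as row names.
#' @export
write_embeddings <- function(mat, path) {
  if (!is.matrix(mat)) abort("`mat` must be a matrix.")
  if (nrow(mat) > 0L && is.null(rownames(mat))) {
    abort("`mat` must carry node ids as row names.")
  }
  lines <- c(
    paste(nrow(mat), ncol(mat)),
    if (nrow(mat) > 0L) {
      vapply(seq_len(nrow(mat)), function(i) {
        paste(c(rownames(mat)[i], fmt_num(mat[i, ])), collapse = " ")
      }, "")
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) abort(sprintf("Embedding file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(header) != 2L) abort("Malformed embedding header line.")
  n <- as.integer(header[1L]); d <- as.integer(header[2L])
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    abort(sprintf("Embedding header declares %d rows but file has %d.",
                  n, length(body)))
  }
  if (n == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = d))
  }
  toks <- strsplit(trimws(body), "\\s+")
  nf <- vapply(toks, length, 1L)
  if (any(nf != d + 1L)) {
    abort(sprintf(
      "Embedding row %d has %d values but header declares dimension %d.",
      which(nf != d + 1L)[1L], nf[which(nf != d + 1L)[1L]] - 1L, d
    ))
  }
  ids <- vapply(toks, `[[`, "", 1L)
  vals <- matrix(
    as.numeric(unlist(lapply(toks, `[`, -1L), use.names = FALSE)),
    nrow = n, byrow = TRUE
  )
  rownames(vals) <- ids
  vals
}

#' Write / read a labelled numeric matrix as TSV
#'
#' Used for similarity matrices, attribute matrices and graph-convolution
#' features: a header of column names, then one row per line with the row
#' id in the first field.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path File path.
#' @return The matrix (readers) or `path` invisibly (writers).
#' @export
write_matrix_tsv <- function(mat, path) {
  if (!is.matrix(mat)) abort("`mat` must be a matrix.")
  con <- file(path, "w")
  on.exit(close(con))
  cn <- colnames(mat)
  if (is.null(cn)) cn <- paste0("V", seq_len(ncol(mat)))
  writeLines(paste(c("id", cn), collapse = "\t"), con)
  rn <- rownames(mat)
  if (is.null(rn)) rn <- paste0("row", seq_len(nrow(mat)))
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(rn[i], fmt_num(mat[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  parsed <- read_tsv_fields(path, min_fields = 2L, what = "Matrix")
  header <- parsed$fields[[1L]]
  rows <- parsed$fields[-1L]
  nf <- vapply(rows, length, 1L)
  if (any(nf != length(header))) {
    abort(sprintf("Matrix TSV row at line %d has %d fields, header has %d.",
                  parsed$line_numbers[-1L][which(nf != length(header))[1L]],
                  nf[which(nf != length(header))[1L]], length(header)))
  }
  mat <- matrix(
    as.numeric(unlist(lapply(rows, `[`, -1L), use.names = FALSE)),
    nrow = length(rows), byrow = TRUE,
    dimnames = list(vapply(rows, `[[`, "", 1L), header[-1L])
  )
  mat
}

#' Write / read a binary fingerprint table
#'
#' Compact TSV: `drug_id<TAB>bitstring` where `bitstring` is a 0/1 string of
#' length `n_bits`.
#'
#' @param fps Binary matrix, drugs in rows (row names = drug ids).
#' @param path File path.
#' @return The fingerprint matrix (reader) or `path` invisibly (writer).
#' @export
write_fingerprints <- function(fps, path) {
  if (!is.matrix(fps) || is.null(rownames(fps))) {
    abort("`fps` must be a matrix with drug ids as row names.")
  }
  lines <- vapply(seq_len(nrow(fps)), function(i) {
    paste0(rownames(fps)[i], "\t", paste(as.integer(fps[i, ]), collapse = ""))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  parsed <- read_tsv_fields(path, min_fields = 2L, what = "Fingerprint")
  ids <- vapply(parsed$fields, `[[`, "", 1L)
  bits <- vapply(parsed$fields, `[[`, "", 2L)
  if (length(unique(nchar(bits))) != 1L) {
    abort("Fingerprint rows have inconsistent bit lengths.")
  }
  if (any(grepl("[^01]", bits))) {
    abort("Fingerprint bitstrings must contain only 0 and 1.")
  }
  mat <- matrix(
    as.integer(unlist(strsplit(bits, "", fixed = TRUE), use.names = FALSE)),
    nrow = length(ids), byrow = TRUE, dimnames = list(ids, NULL)
  )
  mat
}
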