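# Fixed-length binary substructure fingerprints and Tanimoto similarity.
#
# The fingerprint algorithm is a pluggable registry. The default, "hashed_ap",
# enumerates atom pairs (ChemmineR) from the molecular graph and hashes each
# pair descriptor into one of `nbits` slots, giving a deterministic 2048-bit
# hashed substructure scheme that is invariant under SMILES rewrites. Column
# names follow the `Avalon_FP_<i>` slot convention used by the packaged
# feature sets; the algorithm actually used is stamped into the matrix
# provenance.

.fp_registry <- new.env(parent = emptyenv())

#' Register a fingerprint algorithm
#'
#' @param name Algorithm name.
#' @param fun Function `(smiles, nbits) -> integer matrix` with one row per
#'   input and `nbits` 0/1 columns.
#' @export
register_fingerprint_algorithm <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .fp_registry)
  invisible(name)
}

fp_bit_names <- function(nbits) paste0("Avalon_FP_", seq_len(nbits) - 1L)

hashed_ap_fingerprint <- function(smiles, nbits) {
  names(smiles) <- sprintf("m%06d", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  apset <- suppressWarnings(ChemmineR::sdf2ap(sdf))
  pairs <- ChemmineR::ap(apset)
  m <- matrix(0L, nrow = length(smiles), ncol = nbits,
              dimnames = list(NULL, fp_bit_names(nbits)))
  for (i in seq_along(pairs)) {
    slots <- unique(as.integer(pairs[[i]] %% nbits)) + 1L
    m[i, slots] <- 1L
  }
  m
}

register_fingerprint_algorithm("hashed_ap", hashed_ap_fingerprint)

#' Compute a fingerprint matrix
#'
#' Computes one fixed-length binary fingerprint per molecule. Input may be a
#' vector of (already standardized) SMILES or a record data.frame from
#' [standardize_molecules()].
#'
#' @param x Character vector of SMILES, or a data.frame with columns
#'   `smiles` and `id`.
#' @param ids Row ids; defaults to `x$id` or names of the SMILES vector.
#' @param nbits Fingerprint length (default 2048).
#' @param algorithm Registered algorithm name (default `"hashed_ap"`).
#' @return An object of class `fp_matrix`: a list with the binary `matrix`
#'   (rownames = ids, colnames = bit slot names) and `provenance`.
#' @export
fingerprint_matrix <- function(x, ids = NULL, nbits = 2048L,
                               algorithm = "hashed_ap") {
  if (is.data.frame(x)) {
    ids <- ids %||% x$id
    smiles <- x$smiles
  } else {
    ids <- ids %||% names(x) %||% sprintf("mol_%d", seq_along(x))
    smiles <- unname(as.character(x))
  }
  if (anyDuplicated(ids)) ds_error("bad_config", "row ids must be unique")
  if (!exists(algorithm, envir = .fp_registry))
    ds_error("bad_config", sprintf("unknown fingerprint algorithm '%s'", algorithm))
  fun <- get(algorithm, envir = .fp_registry)
  m <- fun(smiles, as.integer(nbits))
  if (ncol(m) != nbits || nrow(m) != length(smiles) || !all(m %in% c(0L, 1L)))
    ds_error("bad_config", "fingerprint algorithm returned a malformed matrix")
  rownames(m) <- ids
  new_fp_matrix(m, algorithm = algorithm,
                parameters = list(nbits = as.integer(nbits)))
}

new_fp_matrix <- function(m, algorithm, parameters = list()) {
  structure(
    list(matrix = m, ids = rownames(m),
         provenance = list(algorithm = algorithm, parameters = parameters)),
    class = "fp_matrix"
  )
}

#' @export
print.fp_matrix <- function(x, ...) {
  cat(sprintf("Fingerprint matrix: %d x %d bits (%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$provenance$algorithm))
  invisible(x)
}

#' Fingerprint a single molecule
#'
#' @inheritParams fingerprint_matrix
#' @param smiles One SMILES string.
#' @return Named integer vector of length `nbits`.
#' @export
fingerprint <- function(smiles, nbits = 2048L, algorithm = "hashed_ap") {
  fp <- fingerprint_matrix(smiles, ids = "q", nbits = nbits,
                           algorithm = algorithm)
  fp$matrix[1L, ]
}

# Subset rows of an fp_matrix by id, preserving provenance.
fp_subset <- function(fp, ids) {
  stopifnot(inherits(fp, "fp_matrix"))
  missing <- setdiff(ids, fp$ids)
  if (length(missing) > 0L)
    ds_error("bad_config", sprintf("ids absent from fingerprint matrix (e.g. %s)",
                                   missing[1L]))
  new_fp_matrix(fp$matrix[ids, , drop = FALSE],
                algorithm = fp$provenance$algorithm,
                parameters = fp$provenance$parameters)
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|a AND b| / |a OR b|` on the on-bit sets. By documented convention two
#' all-zero vectors are maximally similar (1.0).
#'
#' @param a,b Binary vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    ds_error("length_mismatch", "fingerprints differ in length")
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) return(1.0)
  inter / uni
}

#' Maximum Tanimoto similarity of a query to a pool
#'
#' @param query Binary vector.
#' @param pool An `fp_matrix`.
#' @return List with `similarity` (the maximum) and `id` (the argmax row id).
#' @export
max_similarity_to_set <- function(query, pool) {
  stopifnot(inherits(pool, "fp_matrix"))
  if (nrow(pool$matrix) == 0L)
    ds_error("empty_pool", "similarity against an empty pool is undefined")
  sims <- tanimoto_to_pool_matrix(matrix(query, nrow = 1L), pool$matrix)[1L, ]
  i <- which.max(sims)
  list(similarity = unname(sims[i]), id = pool$ids[i])
}

# All pairwise Tanimoto similarities between rows of A (queries) and B (pool).
# Both all-zero => 1 by convention.
tanimoto_to_pool_matrix <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  inter <- A %*% t(B)
  ra <- rowSums(A); rb <- rowSums(B)
  uni <- outer(ra, rb, "+") - inter
  out <- ifelse(uni == 0, 1, inter / uni)
  out
}

# Row-wise maximum Tanimoto of each fingerprint in `fp` to any row of `pool`.
max_tanimoto_per_row <- function(fp, pool) {
  stopifnot(inherits(fp, "fp_matrix"), inherits(pool, "fp_matrix"))
  if (nrow(pool$matrix) == 0L) ds_error("empty_pool", "empty positive pool")
  sims <- tanimoto_to_pool_matrix(fp$matrix, pool$matrix)
  stats::setNames(apply(sims, 1L, max), fp$ids)
}

#' Read/write a fingerprint matrix as a delimited table
#'
#' Wide TSV with an `id` column followed by one 0/1 column per bit slot.
#' Round-trips bit-exactly.
#'
#' @param fp An `fp_matrix`.
#' @param path File path.
#' @return `read_fp_matrix()` returns an `fp_matrix`.
#' @export
write_fp_matrix <- function(fp, path) {
  stopifnot(inherits(fp, "fp_matrix"))
  df <- data.frame(id = fp$ids, fp$matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fp_matrix
#' @param algorithm Provenance label to stamp on the matrix read back.
#' @export
read_fp_matrix <- function(path, algorithm = "from_file") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$id
  new_fp_matrix(m, algorithm = algorithm)
}
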