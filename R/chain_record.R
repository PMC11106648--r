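#' Construct a chain record
#'
#' A `chain_record` holds the Calpha trace of one polypeptide chain, indexed
#' by reference-sequence residue number (1-based, UniProt-style). It is the
#' unit every downstream computation (distance matrices, GLOCON, clustering,
#' superposition) consumes; side chains and non-Calpha backbone atoms are
#' never represented.
#'
#' @param structure_id Structure label, e.g. a PDB-style 4-character code.
#' @param chain_id Chain identifier within the structure.
#' @param accession Reference sequence accession the residue numbers refer to.
#' @param resno Integer vector of reference residue numbers, strictly
#'   increasing. Unmodeled residues are simply absent.
#' @param xyz Numeric matrix, `length(resno)` rows by 3 columns, of Calpha
#'   coordinates in Angstrom.
#' @param source_model Model number the coordinates were taken from (1 for
#'   single-model structures).
#'
#' @return An object of class `chain_record`.
#' @export
chain_record <- function(structure_id, chain_id, accession, resno, xyz,
                         source_model = 1L) {
  resno <- as.integer(resno)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  rec <- structure(
    list(
      structure_id = as.character(structure_id),
      chain_id = as.character(chain_id),
      accession = as.character(accession),
      resno = resno,
      xyz = xyz,
      source_model = as.integer(source_model)
    ),
    class = "chain_record"
  )
  validate_chain_record(rec)
  rec
}

validate_chain_record <- function(rec) {
  stopifnot(inherits(rec, "chain_record"))
  n <- length(rec$resno)
  if (n < 3L) {
    stop("chain too short: chain '", chain_key(rec), "' has ", n,
         " Calpha residues; at least 3 are required", call. = FALSE)
  }
  if (nrow(rec$xyz) != n || ncol(rec$xyz) != 3L) {
    stop("coordinate matrix of chain '", chain_key(rec),
         "' must be length(resno) x 3", call. = FALSE)
  }
  if (any(diff(rec$resno) <= 0L)) {
    stop("residue numbers of chain '", chain_key(rec),
         "' must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(rec$xyz))) {
    stop("non-finite coordinates in chain '", chain_key(rec), "'",
         call. = FALSE)
  }
  invisible(rec)
}

#' Unique key for a chain
#'
#' Chains are identified throughout by `structure_id` and `chain_id` joined
#' with an underscore (e.g. `"1abc_A"`); these keys label GLOCON matrices,
#' dendrogram leaves and cluster assignments.
#'
#' @param rec A `chain_record`.
#' @return A single string.
#' @export
chain_key <- function(rec) {
  paste0(rec$structure_id, "_", rec$chain_id)
}

#' @export
print.chain_record <- function(x, ...) {
  cat(sprintf(
    "<chain_record> %s  accession=%s  model=%d  residues=%d (%d..%d)\n",
    chain_key(x), x$accession, x$source_model, length(x$resno),
    min(x$resno), max(x$resno)
  ))
  invisible(x)
}

#' @export
length.chain_record <- function(x) length(x$resno)

# coordinates of a subset of reference residues, in resno order
chain_coords <- function(rec, resno) {
  idx <- match(resno, rec$resno)
  if (anyNA(idx)) {
    stop("residues ", paste(resno[is.na(idx)], collapse = ", "),
         " not modeled in chain '", chain_key(rec), "'", call. = FALSE)
  }
  rec$xyz[idx, , drop = FALSE]
}

#' Apply a rigid-body transform to a chain
#'
#' Coordinates become `xyz %*% t(rotation) + translation`. Used to place
#' superposed chains in a common frame before writing them out.
#'
#' @param rec A `chain_record`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric vector (Angstrom).
#' @return The transformed `chain_record`.
#' @export
transform_chain <- function(rec, rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-6) {
    stop("rotation must be a proper rotation (det = +1)", call. = FALSE)
  }
  rec$xyz <- rec$xyz %*% t(rotation) +
    matrix(translation, nrow(rec$xyz), 3L, byrow = TRUE)
  rec
}
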