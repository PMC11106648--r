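#' Read a chain-to-reference mapping table
#'
#' The mapping table plays the role SIFTS plays for the PDB archive: it
#' declares, per chain, which reference (UniProt-style) accession the chain
#' belongs to, which closed interval `[ref_start, ref_end]` of that sequence
#' it covers, and the constant `offset` that converts author residue numbers
#' into reference numbers (`ref = author + offset`). The table is taken as
#' authoritative: sequences are not re-aligned or re-compared.
#'
#' @param path Path to a tab-separated file with header columns
#'   `structure_id`, `chain_id`, `accession`, `ref_start`, `ref_end`,
#'   `offset`.
#' @return A `data.frame` of class `mapping_table`.
#' @export
read_mapping_table <- function(path) {
  if (!file.exists(path)) stop("mapping table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  mapping_table(df)
}

#' Build a mapping table from a data frame
#'
#' @param df Data frame with columns `structure_id`, `chain_id`,
#'   `accession`, `ref_start`, `ref_end`, `offset`.
#' @return The validated `mapping_table`.
#' @export
mapping_table <- function(df) {
  needed <- c("structure_id", "chain_id", "accession",
              "ref_start", "ref_end", "offset")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("mapping table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[needed]
  df$structure_id <- as.character(df$structure_id)
  df$chain_id <- as.character(df$chain_id)
  df$accession <- as.character(df$accession)
  for (col in c("ref_start", "ref_end", "offset")) {
    df[[col]] <- as.integer(df[[col]])
    if (anyNA(df[[col]])) {
      stop("mapping table column '", col, "' contains non-integer values",
           call. = FALSE)
    }
  }
  if (any(df$ref_start > df$ref_end)) {
    stop("mapping table has rows with ref_start > ref_end", call. = FALSE)
  }
  key <- paste(df$structure_id, df$chain_id)
  if (anyDuplicated(key)) {
    stop("mapping table has duplicate (structure_id, chain_id) rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  class(df) <- c("mapping_table", "data.frame")
  df
}

#' Write a mapping table to TSV
#'
#' @param mapping A `mapping_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping_table <- function(mapping, path) {
  utils::write.table(as.data.frame(mapping), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# the single row of a mapping table matching a chain, or error
mapping_row <- function(mapping, structure_id, chain_id) {
  hit <- mapping$structure_id == structure_id & mapping$chain_id == chain_id
  if (sum(hit) != 1L) {
    stop("no mapping row for chain '", structure_id, "_", chain_id, "'",
         call. = FALSE)
  }
  mapping[hit, , drop = FALSE]
}
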