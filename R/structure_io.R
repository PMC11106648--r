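#' Read a macromolecular structure file
#'
#' Parses an mmCIF (PDBx `atom_site` category) or legacy PDB coordinate file
#' into a structure handle: a flat atom table carrying author numbering,
#' alternate-location identifiers, occupancies, insertion codes and model
#' numbers, from which chains are extracted with [extract_chain()]. Legacy
#' PDB files are parsed with \pkg{bio3d}; the mmCIF reader resolves
#' `atom_site` columns by tag name, so files with any column ordering and
#' models of unequal atom counts are handled.
#'
#' @param path Path to the coordinate file.
#' @param format `"auto"` (default; decided by file extension, falling back
#'   to content sniffing), `"mmcif"` or `"pdb"`.
#' @param structure_id Label for the structure; defaults to the file name
#'   without extension.
#' @return An object of class `structure_handle` with elements
#'   `structure_id`, `path`, `format`, and `atoms` (a data frame with one
#'   row per atom, columns `record`, `elety`, `alt`, `resid`, `chain`,
#'   `resno`, `insert`, `x`, `y`, `z`, `occ`, `model`).
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb"),
                           structure_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(structure_id)) {
    structure_id <- sub("\\.(cif|mmcif|pdb|ent)$", "",
                        basename(path), ignore.case = TRUE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
      "mmcif"
    } else if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE)) {
      "pdb"
    } else if (any(grepl("^(data_|loop_|_atom_site)",
                         readLines(path, n = 50L, warn = FALSE)))) {
      "mmcif"
    } else {
      "pdb"
    }
  }
  atoms <- switch(format,
    mmcif = read_mmcif_atoms(path),
    pdb = read_pdb_atoms(path)
  )
  if (nrow(atoms) == 0L) {
    stop("no atoms found in '", path, "'", call. = FALSE)
  }
  structure(
    list(structure_id = structure_id, path = path, format = format,
         atoms = atoms),
    class = "structure_handle"
  )
}

#' @export
print.structure_handle <- function(x, ...) {
  cat(sprintf("<structure_handle> %s  format=%s  models=%d  chains=%s  atoms=%d\n",
              x$structure_id, x$format, length(structure_models(x)),
              paste(sort(unique(x$atoms$chain)), collapse = ","),
              nrow(x$atoms)))
  invisible(x)
}

#' Model numbers of a structure handle, in file order
#'
#' @param handle A `structure_handle`.
#' @return Integer vector of model numbers as they first appear in the file.
#' @export
structure_models <- function(handle) {
  unique(handle$atoms$model)
}

#' Chain identifiers present in a structure handle
#'
#' @param handle A `structure_handle`.
#' @return Character vector of chain ids, sorted.
#' @export
structure_chains <- function(handle) {
  sort(unique(handle$atoms$chain))
}

#' Reduce a structure handle to a single model
#'
#' Multi-model files (NMR-style ensembles, but also any other file carrying
#' several models) are reduced by the first-model rule: the model that
#' appears first in the file is kept, regardless of its number. The retained
#' model's number is recorded on extracted chains as `source_model`.
#'
#' @param handle A `structure_handle`.
#' @param policy Model selection policy; only `"first"` is defined.
#' @return A `structure_handle` containing exactly one model.
#' @export
select_model <- function(handle, policy = "first") {
  policy <- match.arg(policy, "first")
  models <- structure_models(handle)
  if (length(models) == 0L) stop("structure has no models", call. = FALSE)
  handle$atoms <- handle$atoms[handle$atoms$model == models[1L], , drop = FALSE]
  handle
}

#' Extract one chain as a Calpha chain record
#'
#' Pulls a single chain out of a single-model structure handle, keeps only
#' residues with a Calpha atom, resolves alternate locations by the
#' highest-occupancy rule (ties broken by the lexicographically smallest
#' altloc id), renumbers author residue numbers into reference-sequence
#' coordinates via the mapping row's `offset`, and drops residues outside
#' the mapped interval `[ref_start, ref_end]`. Residues without a Calpha
#' are treated as unmodeled. Water and non-polymer entities are ignored.
#' Insertion-coded residues are an error: a constant offset cannot express
#' them, and failing loudly beats silent misnumbering.
#'
#' @param handle A single-model `structure_handle` (apply [select_model()]
#'   first for multi-model files).
#' @param chain_id Chain to extract.
#' @param mapping A `mapping_table` (the row matching this chain is used).
#' @return A [chain_record()].
#' @export
extract_chain <- function(handle, chain_id, mapping) {
  models <- structure_models(handle)
  if (length(models) > 1L) {
    stop("handle holds ", length(models),
         " models; apply select_model() before extract_chain()",
         call. = FALSE)
  }
  row <- mapping_row(mapping, handle$structure_id, chain_id)
  at <- handle$atoms
  at <- at[at$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("chain '", chain_id, "' not present in structure '",
         handle$structure_id, "'", call. = FALSE)
  }
  # Calpha of amino-acid residues only; calcium ions share the atom name
  # but carry it as their residue name, waters are never polymer
  at <- at[at$elety == "CA" &
             !(at$resid %in% c("HOH", "WAT", "DOD", "CA")), , drop = FALSE]
  if (any(!is.na(at$insert) & nzchar(at$insert))) {
    bad <- unique(at$resno[!is.na(at$insert) & nzchar(at$insert)])
    stop("chain '", chain_id, "' of '", handle$structure_id,
         "' has insertion-coded residues (author numbers ",
         paste(bad, collapse = ", "),
         "); a constant-offset mapping cannot renumber them", call. = FALSE)
  }
  if (nrow(at) > 0L) {
    # highest occupancy wins within a residue; tie -> smallest altloc id
    occ <- ifelse(is.na(at$occ), 1, at$occ)
    alt <- ifelse(is.na(at$alt), "", at$alt)
    at <- at[order(at$resno, -occ, alt), , drop = FALSE]
    at <- at[!duplicated(at$resno), , drop = FALSE]
  }
  ref <- at$resno + row$offset
  keep <- ref >= row$ref_start & ref <= row$ref_end
  at <- at[keep, , drop = FALSE]
  ref <- ref[keep]
  if (nrow(at) < 3L) {
    stop("chain too short: '", handle$structure_id, "_", chain_id,
         "' has ", nrow(at),
         " mapped Calpha residues after filtering; at least 3 required",
         call. = FALSE)
  }
  chain_record(
    structure_id = handle$structure_id,
    chain_id = chain_id,
    accession = row$accession,
    resno = ref,
    xyz = cbind(at$x, at$y, at$z),
    source_model = at$model[1L]
  )
}

#' Write chain records to an mmCIF file
#'
#' Writes one model per chain so that superposed ensembles can be viewed
#' together in any mmCIF-aware viewer. Only Calpha atoms are represented
#' (the package never carries more); residue identities are not retained by
#' chain records and are written as alanine. `auth_seq_id` carries the
#' reference-sequence residue number. Coordinates are written at the
#' format's conventional 3-decimal precision.
#'
#' @param records List of [chain_record()] objects.
#' @param path Output path.
#' @param transforms Optional list, parallel to `records`, of
#'   `list(rotation =, translation =)` rigid motions applied before writing
#'   (see [transform_chain()]); `NULL` entries mean identity.
#' @return `path`, invisibly.
#' @export
write_superposed <- function(records, path, transforms = NULL) {
  stopifnot(is.list(records), length(records) >= 1L)
  if (!is.null(transforms)) {
    stopifnot(length(transforms) == length(records))
    for (i in seq_along(records)) {
      tr <- transforms[[i]]
      if (!is.null(tr)) {
        records[[i]] <- transform_chain(records[[i]], tr$rotation,
                                        tr$translation)
      }
    }
  }
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) {
    stop("cannot open '", path, "' for writing", call. = FALSE)
  }
  on.exit(close(con))
  writeLines(c(
    "data_superposed",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_asym_id",
    "_atom_site.pdbx_PDB_model_num"
  ), con)
  serial <- 0L
  for (i in seq_along(records)) {
    rec <- records[[i]]
    for (k in seq_along(rec$resno)) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM %d C CA . ALA %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %d",
        serial, rec$chain_id, rec$resno[k],
        rec$xyz[k, 1L], rec$xyz[k, 2L], rec$xyz[k, 3L],
        rec$resno[k], rec$chain_id, i
      ), con)
    }
  }
  writeLines("#", con)
  invisible(path)
}

# ---- mmCIF parsing ---------------------------------------------------------

# Name-based parser for the atom_site loop of a PDBx/mmCIF file.
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tag_idx <- grep("^_atom_site\\.", lines)
  if (length(tag_idx) == 0L) {
    stop("mmCIF parse error in '", path,
         "': no _atom_site category found", call. = FALSE)
  }
  if (any(diff(tag_idx) != 1L)) {
    stop("mmCIF parse error in '", path,
         "': _atom_site tags are not contiguous (line ",
         tag_idx[which(diff(tag_idx) != 1L)[1L] + 1L], ")", call. = FALSE)
  }
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  i <- max(tag_idx) + 1L
  rows <- character(0)
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_") || startsWith(ln, "data_")) break
    rows <- c(rows, ln)
    i <- i + 1L
  }
  if (length(rows) == 0L) {
    stop("mmCIF parse error in '", path,
         "': _atom_site loop has no data rows", call. = FALSE)
  }
  toks <- strsplit(rows, "[ \t]+")
  nt <- lengths(toks)
  if (any(nt != length(tags))) {
    bad <- which(nt != length(tags))[1L]
    stop("mmCIF parse error in '", path, "' at line ",
         max(tag_idx) + bad, ": expected ", length(tags),
         " fields, found ", nt[bad], call. = FALSE)
  }
  m <- matrix(unlist(toks), nrow = length(rows), byrow = TRUE,
              dimnames = list(NULL, tags))
  col <- function(name, default = NA_character_) {
    if (name %in% tags) m[, name] else rep(default, nrow(m))
  }
  blank_na <- function(v) {
    v[v %in% c(".", "?")] <- NA_character_
    v
  }
  num <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    if (anyNA(out)) {
      stop("mmCIF parse error in '", path, "': non-numeric ", what,
           " value '", v[which(is.na(out))[1L]], "'", call. = FALSE)
    }
    out
  }
  chain <- blank_na(col("auth_asym_id"))
  if (all(is.na(chain))) chain <- blank_na(col("label_asym_id"))
  resno <- blank_na(col("auth_seq_id"))
  if (all(is.na(resno))) resno <- blank_na(col("label_seq_id"))
  model <- blank_na(col("pdbx_PDB_model_num"))
  model <- ifelse(is.na(model), 1L, suppressWarnings(as.integer(model)))
  occ <- suppressWarnings(as.numeric(col("occupancy")))
  data.frame(
    record = col("group_PDB", "ATOM"),
    elety = blank_na(col("label_atom_id")),
    alt = blank_na(col("label_alt_id")),
    resid = blank_na(col("label_comp_id")),
    chain = chain,
    resno = as.integer(num(resno, "auth_seq_id")),
    insert = blank_na(col("pdbx_PDB_ins_code")),
    x = num(col("Cartn_x"), "Cartn_x"),
    y = num(col("Cartn_y"), "Cartn_y"),
    z = num(col("Cartn_z"), "Cartn_z"),
    occ = occ,
    model = model,
    stringsAsFactors = FALSE
  )
}

# ---- legacy PDB parsing (via bio3d) ----------------------------------------

read_pdb_atoms <- function(path) {
  pdb <- try(suppressWarnings(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  ), silent = TRUE)
  if (inherits(pdb, "try-error")) {
    stop("PDB parse error in '", path, "': ",
         attr(pdb, "condition")$message, call. = FALSE)
  }
  at <- pdb$atom
  nmodels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  # bio3d does not expose MODEL serial numbers; recover them from the file
  model_no <- grep("^MODEL", readLines(path, warn = FALSE), value = TRUE)
  model_no <- suppressWarnings(as.integer(substr(model_no, 11L, 14L)))
  if (length(model_no) != nmodels || anyNA(model_no)) {
    model_no <- seq_len(nmodels)
  }
  one <- data.frame(
    record = at$type,
    elety = at$elety,
    alt = at$alt,
    resid = at$resid,
    chain = at$chain,
    resno = as.integer(at$resno),
    insert = at$insert,
    x = at$x, y = at$y, z = at$z,
    occ = at$o,
    model = model_no[1L],
    stringsAsFactors = FALSE
  )
  if (nmodels == 1L) return(one)
  out <- vector("list", nmodels)
  for (m in seq_len(nmodels)) {
    mi <- one
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    mi$x <- xyz[, 1L]; mi$y <- xyz[, 2L]; mi$z <- xyz[, 3L]
    mi$model <- model_no[m]
    out[[m]] <- mi
  }
  do.call(rbind, out)
}
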