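#' Generate an ideal helical Calpha backbone
#'
#' A deterministic alpha-helical Calpha trace with a rise of 1.5 Angstrom
#' per residue, 100 degrees of twist per residue and a helix radius of
#' 2.3 Angstrom, giving consecutive Calpha-Calpha distances of about
#' 3.8 Angstrom. Any self-avoiding curve would do for testing purposes;
#' determinism matters more than physical realism, so the geometry
#' constants are fixed.
#'
#' @param n Number of residues (>= 3).
#' @param structure_id,chain_id,accession Identifiers for the resulting
#'   chain record.
#' @return A [chain_record()] with residues numbered 1..n.
#' @export
generate_backbone <- function(n, structure_id = "synt", chain_id = "A",
                              accession = "SYNTH") {
  if (n < 3L) stop("backbone needs at least 3 residues", call. = FALSE)
  i <- seq_len(n)
  theta <- (i - 1L) * 100 * pi / 180
  xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1L))
  chain_record(structure_id, chain_id, accession, resno = i, xyz = xyz)
}

#' Rotate the C-terminal part of a chain about a hinge
#'
#' Residues strictly after the hinge residue are rotated rigidly about an
#' axis through the hinge Calpha; residues up to and including the hinge
#' are untouched. This emulates inter-domain motions such as open/closed
#' transitions: intra-domain distances are preserved exactly, only
#' inter-domain distances change.
#'
#' @param chain A [chain_record()].
#' @param hinge_residue Reference residue number of the hinge; must be
#'   strictly inside the chain.
#' @param angle_deg Rotation angle in degrees.
#' @param axis Rotation axis direction (length-3, need not be normalised);
#'   default the x axis, perpendicular to the generated helix axis.
#' @return The hinged [chain_record()].
#' @export
apply_hinge <- function(chain, hinge_residue, angle_deg, axis = c(1, 0, 0)) {
  rn <- chain$resno
  if (!(hinge_residue %in% rn)) {
    stop("hinge residue ", hinge_residue, " is not modeled in chain '",
         chain_key(chain), "'", call. = FALSE)
  }
  if (hinge_residue <= min(rn) || hinge_residue >= max(rn)) {
    stop("hinge residue must be strictly inside the chain", call. = FALSE)
  }
  R <- rotation_about_axis(axis, angle_deg * pi / 180)
  pivot <- chain$xyz[match(hinge_residue, rn), ]
  moving <- rn > hinge_residue
  shifted <- sweep(chain$xyz[moving, , drop = FALSE], 2L, pivot)
  chain$xyz[moving, ] <- shifted %*% t(R) +
    matrix(pivot, sum(moving), 3L, byrow = TRUE)
  chain
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; exported because tests and callers building rigid
#' motions need it.
#'
#' @param axis Length-3 direction vector (normalised internally).
#' @param angle Angle in radians.
#' @return A 3x3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3L, 3L, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Add Gaussian coordinate noise to a chain
#'
#' Independent normal displacement of every coordinate, emulating the
#' sub-Angstrom variation between independently solved copies of the same
#' conformation.
#'
#' @param chain A [chain_record()].
#' @param sigma Per-coordinate standard deviation in Angstrom (>= 0).
#' @param seed Optional integer seed for reproducibility.
#' @return The perturbed [chain_record()].
#' @export
perturb_chain <- function(chain, sigma, seed = NULL) {
  if (!(sigma >= 0)) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(chain)
  if (!is.null(seed)) set.seed(seed)
  chain$xyz <- chain$xyz + matrix(stats::rnorm(3L * nrow(chain$xyz),
                                               sd = sigma),
                                  nrow(chain$xyz), 3L)
  chain
}

#' Shift a loop region of a chain
#'
#' Translates the Calpha of residues `start..end` by `displacement`
#' Angstrom along `direction`, emulating a local loop movement while the
#' rest of the chain is unchanged.
#'
#' @param chain A [chain_record()].
#' @param start,end Closed reference-residue interval of the loop.
#' @param displacement Shift magnitude in Angstrom.
#' @param direction Length-3 shift direction (normalised internally).
#' @return The shifted [chain_record()].
#' @export
shift_loop <- function(chain, start, end, displacement,
                       direction = c(1, 0, 0)) {
  u <- direction / sqrt(sum(direction^2))
  sel <- chain$resno >= start & chain$resno <= end
  if (!any(sel)) {
    stop("loop interval ", start, "..", end, " has no modeled residues",
         call. = FALSE)
  }
  chain$xyz[sel, ] <- chain$xyz[sel, , drop = FALSE] +
    matrix(u * displacement, sum(sel), 3L, byrow = TRUE)
  chain
}

#' Specification of a synthetic multi-state ensemble
#'
#' Describes a ground-truth ensemble: one helical backbone bent into one
#' or more planted conformational states (hinge rotations and/or loop
#' shifts), several independently jittered chains per state, optional
#' per-chain unmodeled gaps, and optional author renumbering to exercise
#' the mapping step.
#'
#' @param n_residues Chain length; the default of 150 is a typical
#'   single-domain protein size and gives a mid-chain hinge enough lever
#'   arm for moderate hinge angles to change inter-domain Calpha distances
#'   well beyond the 3 Angstrom placement-noise filter.
#' @param states List of states, each a list with `name`, and optionally
#'   `hinge_angle_deg` + `hinge_residue` and/or
#'   `loop_shift = c(start, end, displacement)`.
#' @param chains_per_state Number of chains generated per state.
#' @param jitter_sigma Per-coordinate Gaussian noise, Angstrom.
#' @param gap_spec Optional list of `list(chain = ordinal, start =, end =)`
#'   unmodeled intervals (reference numbering; chain ordinals count across
#'   states in generation order).
#' @param author_start Author number of reference residue 1 in the emitted
#'   files (default 1; other values exercise the offset machinery).
#' @param nmr_models If > 0, the first chain is written as a multi-model
#'   NMR-style file: model 1 holds the chain's coordinates, the extra
#'   models are further perturbed copies that the first-model rule must
#'   discard.
#' @param accession Reference accession for all chains.
#' @param seed Integer seed; every random draw in the ensemble derives
#'   from it.
#' @return A list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_residues = 150L,
                          states = list(
                            list(name = "open", hinge_angle_deg = 0,
                                 hinge_residue = 75L),
                            list(name = "closed", hinge_angle_deg = 30,
                                 hinge_residue = 75L)
                          ),
                          chains_per_state = 5L,
                          jitter_sigma = 0.2,
                          gap_spec = list(),
                          author_start = 1L,
                          nmr_models = 0L,
                          accession = "SYNTH",
                          seed = 1L) {
  stopifnot(n_residues >= 3L, chains_per_state >= 1L, jitter_sigma >= 0)
  for (st in states) {
    if (!is.null(st$hinge_residue)) {
      if (st$hinge_residue <= 1L || st$hinge_residue >= n_residues) {
        stop("hinge residue must be strictly inside the chain",
             call. = FALSE)
      }
    }
  }
  structure(
    list(n_residues = as.integer(n_residues), states = states,
         chains_per_state = as.integer(chains_per_state),
         jitter_sigma = jitter_sigma, gap_spec = gap_spec,
         author_start = as.integer(author_start),
         nmr_models = as.integer(nmr_models),
         accession = accession, seed = as.integer(seed)),
    class = "ensemble_spec"
  )
}

#' Generate a ground-truth ensemble on disk
#'
#' Materialises an [ensemble_spec()]: one mmCIF file per chain (author
#' numbering shifted by `author_start`), a mapping table TSV relating each
#' chain to the reference accession, and the planted state labels for
#' evaluating clustering results.
#'
#' @param spec An [ensemble_spec()].
#' @param dir Output directory (created if needed).
#' @return A list with `files` (character vector of mmCIF paths),
#'   `mapping_path`, `mapping` (the `mapping_table`), `labels` (named
#'   character vector, chain key -> planted state name) and `records`
#'   (the in-memory chain records as written).
#' @export
generate_ensemble <- function(spec, dir) {
  stopifnot(inherits(spec, "ensemble_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- spec$n_residues
  base <- generate_backbone(n, accession = spec$accession)

  state_chains <- list()
  labels <- character(0)
  ordinal <- 0L
  for (si in seq_along(spec$states)) {
    st <- spec$states[[si]]
    proto <- base
    if (!is.null(st$hinge_angle_deg) && st$hinge_angle_deg != 0) {
      proto <- apply_hinge(proto, st$hinge_residue, st$hinge_angle_deg)
    }
    if (!is.null(st$loop_shift)) {
      ls <- st$loop_shift
      proto <- shift_loop(proto, ls[1L], ls[2L], ls[3L])
    }
    for (ci in seq_len(spec$chains_per_state)) {
      ordinal <- ordinal + 1L
      rec <- proto
      rec$structure_id <- sprintf("st%02d", ordinal)
      rec$chain_id <- "A"
      rec <- perturb_chain(rec, spec$jitter_sigma,
                           seed = spec$seed + 7919L * ordinal)
      state_chains[[ordinal]] <- rec
      labels[chain_key(rec)] <- st$name
    }
  }

  # carve the requested unmodeled gaps
  for (g in spec$gap_spec) {
    idx <- g$chain
    if (idx < 1L || idx > length(state_chains)) {
      stop("gap_spec refers to chain ordinal ", idx,
           " but only ", length(state_chains), " chains exist",
           call. = FALSE)
    }
    rec <- state_chains[[idx]]
    keep <- !(rec$resno >= g$start & rec$resno <= g$end)
    if (sum(keep) < 3L) {
      stop("gap ", g$start, "..", g$end, " leaves chain ", idx,
           " with fewer than 3 residues", call. = FALSE)
    }
    st <- spec$states[[ceiling(idx / spec$chains_per_state)]]
    if (!is.null(st$hinge_residue) &&
        !is.null(st$hinge_angle_deg) && st$hinge_angle_deg != 0) {
      if (!any(rec$resno[keep] <= st$hinge_residue) ||
          !any(rec$resno[keep] > st$hinge_residue)) {
        stop("gap ", g$start, "..", g$end,
             " removes an entire hinge flank of chain ", idx,
             "; the planted state would be unobservable", call. = FALSE)
      }
    }
    rec$resno <- rec$resno[keep]
    rec$xyz <- rec$xyz[keep, , drop = FALSE]
    state_chains[[idx]] <- rec
  }

  offset <- 1L - spec$author_start  # ref = author + offset
  files <- character(length(state_chains))
  for (i in seq_along(state_chains)) {
    rec <- state_chains[[i]]
    path <- file.path(dir, paste0(rec$structure_id, ".cif"))
    extra <- NULL
    if (i == 1L && spec$nmr_models > 0L) {
      extra <- lapply(seq_len(spec$nmr_models), function(m)
        perturb_chain(rec, max(spec$jitter_sigma, 0.1),
                      seed = spec$seed + 104729L * m))
    }
    write_chain_cif(rec, path, author_offset = -offset, extra_models = extra)
    files[i] <- path
  }

  mapping <- mapping_table(data.frame(
    structure_id = vapply(state_chains, function(r) r$structure_id,
                          character(1)),
    chain_id = vapply(state_chains, function(r) r$chain_id, character(1)),
    accession = spec$accession,
    ref_start = 1L, ref_end = n, offset = offset,
    stringsAsFactors = FALSE
  ))
  mapping_path <- file.path(dir, "mapping.tsv")
  write_mapping_table(mapping, mapping_path)

  list(files = files, mapping_path = mapping_path, mapping = mapping,
       labels = labels, records = state_chains)
}

# write one chain (optionally with extra models) as mmCIF, shifting
# reference numbers back into author numbering by author_offset
write_chain_cif <- function(rec, path, author_offset = 0L,
                            extra_models = NULL) {
  models <- c(list(rec), extra_models %||% list())
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("data_", rec$structure_id),
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
  for (m in seq_along(models)) {
    rm <- models[[m]]
    auth <- rm$resno + author_offset
    for (k in seq_along(rm$resno)) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM %d C CA . ALA %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %d",
        serial, rm$chain_id, rm$resno[k],
        rm$xyz[k, 1L], rm$xyz[k, 2L], rm$xyz[k, 3L],
        auth[k], rm$chain_id, m
      ), con)
    }
  }
  writeLines("#", con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
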