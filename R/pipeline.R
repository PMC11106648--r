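#' Pipeline configuration
#'
#' Validates and freezes everything a single pipeline run needs. All
#' thresholds of the method are surfaced here with their defaults: the 3
#' Angstrom noise filter, the 70% dendrogram cut, and the 0.8 segment
#' overlap fraction (the cut in particular can be tuned per run, as
#' separation quality varies between segments).
#'
#' @param input Directory containing mmCIF/PDB files, or an explicit
#'   character vector of file paths.
#' @param mapping Path to a mapping TSV (see [read_mapping_table()]) or a
#'   `mapping_table` object.
#' @param output_dir Directory for all outputs (created if needed).
#' @param params A [glocon_params()] object.
#' @param min_overlap_fraction Segment merging threshold, see
#'   [assign_segments()].
#' @param model_paths Optional named character vector / list mapping a
#'   reference accession to a predicted-model coordinate file; each
#'   segment of that accession is compared against the model.
#' @param log_level `"info"` (progress messages) or `"quiet"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, mapping, output_dir,
                            params = glocon_params(),
                            min_overlap_fraction = 0.8,
                            model_paths = list(),
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(inherits(params, "glocon_params"))
  if (length(input) == 1L && dir.exists(input)) {
    files <- list.files(input, pattern = "\\.(cif|mmcif|pdb|ent)$",
                        full.names = TRUE, ignore.case = TRUE)
  } else {
    files <- as.character(input)
  }
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(files) == 0L) {
    stop("no structure files found in input", call. = FALSE)
  }
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- read_mapping_table(mapping)
  }
  if (!inherits(mapping, "mapping_table")) {
    stop("mapping must be a mapping_table or a path to one", call. = FALSE)
  }
  if (!(min_overlap_fraction > 0 && min_overlap_fraction <= 1)) {
    stop("min_overlap_fraction must be in (0, 1]", call. = FALSE)
  }
  model_paths <- as.list(model_paths)
  mp <- as.character(unlist(model_paths))
  bad_models <- mp[!file.exists(mp)]
  if (length(bad_models)) {
    stop("predicted-model file(s) not found: ",
         paste(bad_models, collapse = ", "), call. = FALSE)
  }
  structure(
    list(files = sort(files), mapping = mapping, output_dir = output_dir,
         params = params, min_overlap_fraction = min_overlap_fraction,
         model_paths = model_paths, log_level = log_level),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognised keys: `input`, `mapping`, `output_dir`, `noise_threshold`,
#' `normalization_mode`, `cut_fraction`, `min_overlap_fraction`,
#' `model_paths` (mapping accession -> file), `log_level`. Relative paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @param overrides Named list of values that win over the file's.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(startsWith(p, "/"), p, file.path(base, p))
  pipeline_config(
    input = rel(cfg$input),
    mapping = rel(cfg$mapping),
    output_dir = rel(cfg$output_dir),
    params = glocon_params(
      noise_threshold = cfg$noise_threshold %||% 3,
      normalization_mode = cfg$normalization_mode %||% "literal_product",
      cut_fraction = cfg$cut_fraction %||% 0.7
    ),
    min_overlap_fraction = cfg$min_overlap_fraction %||% 0.8,
    model_paths = lapply(cfg$model_paths %||% list(), rel),
    log_level = cfg$log_level %||% "info"
  )
}

#' Run the conformational-state pipeline
#'
#' Reads every input structure, applies the first-model rule, extracts
#' mapped chains, groups them into segments, computes each segment's
#' GLOCON matrix, clusters it by UPGMA with a cut at `cut_fraction` of the
#' maximum score, selects medoid representatives, superposes all members
#' onto the representative of the largest cluster, and (when a predicted
#' model is supplied for the accession) reports the model's RMSD against
#' every cluster representative. Per segment it writes a GLOCON CSV and
#' PHYLIP matrix, a Newick dendrogram, a cluster CSV and a superposed
#' mmCIF; failures are isolated per structure and per segment. A JSON run
#' summary records counts, parameters and an order-independent content
#' hash of all outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the run summary list. The summary's `n_failed`
#'   counts structures or segments that errored.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) {
    if (config$log_level == "info") message(sprintf(...))
  }

  failures <- list()
  records <- list()
  for (path in config$files) {
    res <- tryCatch({
      handle <- select_model(read_structure(path))
      wanted <- config$mapping[
        config$mapping$structure_id == handle$structure_id, , drop = FALSE]
      if (nrow(wanted) == 0L) {
        stop("no mapping rows for structure '", handle$structure_id, "'",
             call. = FALSE)
      }
      lapply(wanted$chain_id, function(ch)
        extract_chain(handle, ch, config$mapping))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[basename(path)]] <- conditionMessage(res)
      say("FAILED %s: %s", basename(path), conditionMessage(res))
    } else {
      records <- c(records, res)
    }
  }
  if (length(records) == 0L) {
    stop("no chains could be extracted from the input", call. = FALSE)
  }
  say("extracted %d chains from %d files", length(records),
      length(config$files))

  segments <- assign_segments(records, config$mapping,
                              config$min_overlap_fraction)
  say("%d segment(s)", length(segments))

  seg_summaries <- list()
  for (seg in segments) {
    out <- tryCatch(
      run_segment(seg, config),
      error = function(e) e
    )
    if (inherits(out, "error")) {
      failures[[seg$segment_id]] <- conditionMessage(out)
      say("FAILED segment %s: %s", seg$segment_id, conditionMessage(out))
    } else {
      seg_summaries[[seg$segment_id]] <- out
      say("segment %s: %d chains, %d cluster(s)", seg$segment_id,
          length(seg$members), out$n_clusters)
    }
  }

  outputs <- sort(setdiff(
    list.files(config$output_dir, full.names = TRUE),
    file.path(config$output_dir, "run_summary.json")
  ))
  hash <- content_hash(outputs)

  summary <- list(
    n_files = length(config$files),
    n_chains = length(records),
    n_segments = length(segments),
    n_failed = length(failures),
    failures = failures,
    parameters = list(
      noise_threshold = config$params$noise_threshold,
      normalization_mode = config$params$normalization_mode,
      cut_fraction = config$params$cut_fraction,
      min_overlap_fraction = config$min_overlap_fraction
    ),
    segments = seg_summaries,
    package_version = as.character(utils::packageVersion("glocon")),
    output_hash = hash
  )
  jsonlite::write_json(summary, file.path(config$output_dir,
                                          "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}

run_segment <- function(seg, config) {
  od <- config$output_dir
  if (length(seg$members) < 2L) {
    write_segments_report(list(seg),
                          file.path(od, paste0(seg$segment_id,
                                               "_segment.csv")))
    return(list(segment_id = seg$segment_id, n_chains = 1L,
                n_clusters = 1L, skipped = "single member"))
  }
  g <- pairwise_glocon(seg, config$params)
  d <- upgma(g)
  assignment <- cut_dendrogram(d, g, config$params$cut_fraction)

  write_glocon_csv(g, file.path(od, paste0(seg$segment_id, "_glocon.csv")))
  write_glocon_phylip(g, file.path(od, paste0(seg$segment_id,
                                              "_glocon.phylip")))
  dendrogram_newick(d, file.path(od, paste0(seg$segment_id, ".nwk")))
  write_cluster_csv(assignment, seg,
                    file.path(od, paste0(seg$segment_id, "_clusters.csv")))

  # common display frame: everything onto the largest cluster's medoid
  ref_key <- assignment$representatives[["1"]]
  sups <- superpose_segment(seg, ref_key)
  keys <- segment_keys(seg)
  transforms <- lapply(keys, function(k) {
    if (k == ref_key) NULL else
      list(rotation = sups[[k]]$rotation, translation = sups[[k]]$translation)
  })
  write_superposed(seg$members,
                   file.path(od, paste0(seg$segment_id, "_superposed.cif")),
                   transforms = transforms)

  model_summary <- NULL
  model_path <- config$model_paths[[seg$accession]]
  if (!is.null(model_path)) {
    model <- read_model_chain(model_path, seg$accession)
    cmp <- model_vs_representatives(model, assignment, seg)
    write_model_rmsd_csv(cmp, assignment, seg,
                         file.path(od, paste0(seg$segment_id,
                                              "_model_rmsd.csv")))
    model_summary <- list(closest_cluster = cmp$closest,
                          rmsd = as.list(round(cmp$rmsd, 6)))
  }

  list(segment_id = seg$segment_id,
       n_chains = length(seg$members),
       n_clusters = assignment$n_clusters,
       cut_height = assignment$cut_height,
       max_glocon = max(g$G),
       representatives = as.list(assignment$representatives),
       model = model_summary)
}

#' Read a predicted-model file as a chain record
#'
#' Predicted models (e.g. from AlphaFold-style pipelines) are numbered
#' directly in reference-sequence coordinates, so no mapping offset is
#' applied: the first chain of the first model is taken as-is.
#'
#' @param path Coordinate file (mmCIF or PDB).
#' @param accession Accession to stamp on the record.
#' @return A [chain_record()].
#' @export
read_model_chain <- function(path, accession) {
  handle <- select_model(read_structure(path))
  ch <- structure_chains(handle)[1L]
  at <- handle$atoms
  at <- at[at$chain == ch & at$elety == "CA" &
             !(at$resid %in% c("HOH", "WAT", "DOD", "CA")), , drop = FALSE]
  at <- at[order(at$resno), , drop = FALSE]
  at <- at[!duplicated(at$resno), , drop = FALSE]
  if (nrow(at) < 3L) {
    stop("model '", path, "' has fewer than 3 Calpha residues",
         call. = FALSE)
  }
  chain_record(handle$structure_id, ch, accession,
               resno = at$resno, xyz = cbind(at$x, at$y, at$z),
               source_model = at$model[1L])
}

# order-independent md5 digest over a set of text files
content_hash <- function(paths) {
  if (length(paths) == 0L) return(NA_character_)
  sums <- sort(paste(basename(paths), unname(tools::md5sum(paths))))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(sums, tmp)
  unname(tools::md5sum(tmp))
}
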