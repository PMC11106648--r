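#' GLOCON scoring parameters
#'
#' Bundles the tunable constants of the GLObal CONformation (GLOCON)
#' dissimilarity and its downstream cut.
#'
#' @param noise_threshold Noise filter threshold in Angstrom: entries of the
#'   absolute distance-matrix difference strictly below it are zeroed,
#'   removing small discrepancies in Calpha placement. Default 3.
#' @param normalization_mode `"literal_product"` (default): the filtered
#'   upper-triangle sum is multiplied by the fraction of modeled residues.
#'   `"mean_then_fraction"`: the sum is first divided by the number of
#'   residue pairs, then multiplied by the fraction — an alternative that
#'   keeps scores comparable across pairs with different coverage.
#' @param cut_fraction Dendrogram cut height as a fraction of the maximum
#'   pairwise GLOCON score in the segment. Default 0.7.
#' @return A list of class `glocon_params`.
#' @export
glocon_params <- function(noise_threshold = 3,
                          normalization_mode = c("literal_product",
                                                 "mean_then_fraction"),
                          cut_fraction = 0.7) {
  normalization_mode <- match.arg(normalization_mode)
  if (!(noise_threshold >= 0)) {
    stop("noise_threshold must be >= 0", call. = FALSE)
  }
  if (!(cut_fraction > 0 && cut_fraction <= 1)) {
    stop("cut_fraction must be in (0, 1]", call. = FALSE)
  }
  structure(list(noise_threshold = noise_threshold,
                 normalization_mode = normalization_mode,
                 cut_fraction = cut_fraction),
            class = "glocon_params")
}

#' Calpha distance matrix of a chain
#'
#' All pairwise Euclidean distances between the chain's Calpha atoms. The
#' matrix depends only on internal geometry, so it is invariant to any
#' rigid motion of the chain (reflections included: they change chirality
#' but not distances).
#'
#' @param chain A [chain_record()].
#' @return Symmetric numeric matrix with zero diagonal; row and column
#'   names are the reference residue numbers.
#' @export
ca_distance_matrix <- function(chain) {
  validate_chain_record(chain)
  D <- as.matrix(stats::dist(chain$xyz))
  if (any(D > 1e4)) {
    stop("absurd Calpha distance (> 1e4 Angstrom) in chain '",
         chain_key(chain), "'; input is likely corrupt", call. = FALSE)
  }
  dimnames(D) <- list(chain$resno, chain$resno)
  D
}

#' Absolute difference of two Calpha distance matrices
#'
#' Restricts both matrices to the residues modeled in both chains and takes
#' the element-wise absolute difference. This captures chain-to-chain
#' differences in Calpha geometry independent of either chain's original
#' Cartesian frame.
#'
#' @param a,b Calpha distance matrices from [ca_distance_matrix()] (row
#'   names are reference residue numbers).
#' @param ids Optional length-2 character vector naming the pair for error
#'   messages.
#' @return List with `diff` (matrix over the common residues, increasing
#'   order) and `common` (integer vector of common residue numbers).
#' @export
difference_matrix <- function(a, b, ids = c("a", "b")) {
  ra <- as.integer(rownames(a))
  rb <- as.integer(rownames(b))
  common <- sort(intersect(ra, rb))
  if (length(common) < 3L) {
    stop("insufficient overlap between chains '", ids[1L], "' and '",
         ids[2L], "': ", length(common),
         " common residues (>= 3 required)", call. = FALSE)
  }
  key <- as.character(common)
  list(diff = abs(a[key, key] - b[key, key]), common = common)
}

#' Zero sub-threshold entries of a difference matrix
#'
#' Entries strictly below the threshold are set to zero; entries equal to
#' or above it pass unchanged. With `tau = 0` the filter is the identity.
#'
#' @param diff Numeric matrix of absolute distance differences.
#' @param tau Threshold in Angstrom (default 3).
#' @return The filtered matrix.
#' @export
apply_noise_filter <- function(diff, tau = 3) {
  if (!(tau >= 0)) stop("tau must be >= 0", call. = FALSE)
  diff[diff < tau] <- 0
  diff
}

#' Fraction of the segment modeled in both chains of a pair
#'
#' The number of residues with a Calpha in both chains, divided by the
#' segment interval length. Using the segment interval (not either chain's
#' own length) as denominator makes the fraction symmetric in the pair and
#' comparable across all pairs of one segment; any gap in either chain
#' lowers it.
#'
#' @param a,b [chain_record()] objects.
#' @param segment The `segment` both chains belong to.
#' @return A number in (0, 1].
#' @export
fraction_modeled <- function(a, b, segment) {
  common <- intersect(a$resno, b$resno)
  if (length(common) == 0L) {
    stop("insufficient overlap between chains '", chain_key(a), "' and '",
         chain_key(b), "': no common residues", call. = FALSE)
  }
  length(common) / segment_length(segment)
}

#' Condense a filtered difference matrix into a GLOCON score
#'
#' In `"literal_product"` mode the upper-triangle entries are summed and
#' the sum multiplied by the fraction of modeled residues, penalising gaps.
#' In `"mean_then_fraction"` mode the sum is divided by the number of
#' upper-triangle pairs before the multiplication.
#'
#' @param filtered Square symmetric matrix after [apply_noise_filter()].
#' @param fraction Fraction of modeled residues from [fraction_modeled()].
#' @param mode Normalisation mode, see [glocon_params()].
#' @return A non-negative number; zero iff all filtered entries are zero.
#' @export
glocon_score <- function(filtered, fraction,
                         mode = c("literal_product", "mean_then_fraction")) {
  mode <- match.arg(mode)
  if (!(fraction > 0 && fraction <= 1)) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  s <- sum(filtered[upper.tri(filtered)])
  if (mode == "mean_then_fraction") {
    n_pairs <- sum(upper.tri(filtered))
    s <- s / n_pairs
  }
  s * fraction
}

#' Pairwise GLOCON matrix of a segment
#'
#' Computes the GLOCON dissimilarity for every unordered pair of chains in
#' a segment: per pair, the Calpha distance matrices are restricted to the
#' residues modeled in both chains, differenced, noise-filtered, summed
#' over the upper triangle and gap-normalised. Pairs with fewer than 3
#' common residues make the whole segment fail (with all offending pairs
#' listed) rather than being silently imputed.
#'
#' @param segment A `segment` with at least 2 members.
#' @param params A [glocon_params()] object.
#' @return An object of class `glocon_matrix`: list with `chain_ids`, the
#'   symmetric score matrix `G` (zero diagonal), the per-pair
#'   modeled-fraction matrix `f`, and the `params` used.
#' @export
pairwise_glocon <- function(segment, params = glocon_params()) {
  members <- segment$members
  n <- length(members)
  if (n < 2L) {
    stop("segment '", segment$segment_id,
         "' has fewer than 2 members; nothing to compare", call. = FALSE)
  }
  keys <- segment_keys(segment)
  D <- lapply(members, ca_distance_matrix)
  G <- matrix(0, n, n, dimnames = list(keys, keys))
  f <- matrix(1, n, n, dimnames = list(keys, keys))
  bad <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      res <- try(difference_matrix(D[[i]], D[[j]], ids = keys[c(i, j)]),
                 silent = TRUE)
      if (inherits(res, "try-error")) {
        bad <- c(bad, paste0(keys[i], " vs ", keys[j]))
        next
      }
      fij <- length(res$common) / segment_length(segment)
      filt <- apply_noise_filter(res$diff, params$noise_threshold)
      sij <- glocon_score(filt, fij, params$normalization_mode)
      G[i, j] <- G[j, i] <- sij
      f[i, j] <- f[j, i] <- fij
    }
  }
  if (length(bad)) {
    stop("segment '", segment$segment_id,
         "' has pairs with insufficient residue overlap: ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  structure(list(chain_ids = keys, G = G, f = f, params = params),
            class = "glocon_matrix")
}

#' @export
print.glocon_matrix <- function(x, ...) {
  cat(sprintf("<glocon_matrix> %d chains  max score %.3f  (tau=%g, %s)\n",
              length(x$chain_ids), max(x$G), x$params$noise_threshold,
              x$params$normalization_mode))
  invisible(x)
}

#' Export a GLOCON matrix as CSV
#'
#' Square matrix with chain keys as header row and first column.
#'
#' @param g A `glocon_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_glocon_csv <- function(g, path) {
  df <- as.data.frame(g$G)
  df <- cbind(chain = g$chain_ids, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a GLOCON matrix in PHYLIP square distance format
#'
#' Plain-text square matrix understood by common tree-building tools:
#' first line the number of taxa, then one row per chain with the chain
#' key followed by its distances.
#'
#' @param g A `glocon_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_glocon_phylip <- function(g, path) {
  n <- length(g$chain_ids)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste(c(sprintf("%-12s", g$chain_ids[i]),
                       sprintf("%.6f", g$G[i, ])), collapse = "  ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
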