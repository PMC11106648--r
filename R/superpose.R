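#' Kabsch least-squares superposition of two chains
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' the Calpha positions of the residues modeled in both chains, by SVD of
#' the cross-covariance matrix with the reflection branch corrected to a
#' proper rotation (det = +1). Superposition uses ALL common residues:
#' unlike structurally-conserved-core methods, RMSDs between hinge-bending
#' or fold-switching chains reflect the full conformational change, not a
#' rigid core.
#'
#' @param mobile,target [chain_record()] objects sharing reference
#'   numbering.
#' @return An object of class `superposition_result`: `rotation` (3x3,
#'   det +1), `translation` (length 3), `rmsd` (Angstrom), `n_aligned`
#'   (residue pairs used), and the ids of both chains. Applying
#'   `rotation`/`translation` to `mobile` (see [transform_chain()])
#'   superposes it onto `target`.
#' @export
kabsch_superpose <- function(mobile, target) {
  common <- sort(intersect(mobile$resno, target$resno))
  if (length(common) < 3L) {
    stop("insufficient overlap between chains '", chain_key(mobile),
         "' and '", chain_key(target), "': ", length(common),
         " common residues (>= 3 required)", call. = FALSE)
  }
  P <- chain_coords(mobile, common)  # mobile
  Q <- chain_coords(target, common)  # target
  pc <- colMeans(P)
  qc <- colMeans(Q)
  P0 <- sweep(P, 2L, pc)
  Q0 <- sweep(Q, 2L, qc)
  # collinear (or coincident) point sets leave the rotation underdetermined
  sp <- svd(P0)$d
  if (sp[2L] < 1e-8 * max(sp[1L], 1)) {
    stop("degenerate configuration: common Calpha of '", chain_key(mobile),
         "' are (nearly) collinear; rotation is underdetermined",
         call. = FALSE)
  }
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- qc - as.vector(R %*% pc)
  moved <- P %*% t(R) + matrix(t, nrow(P), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(
    list(rotation = R, translation = t, rmsd = rmsd,
         n_aligned = length(common),
         mobile = chain_key(mobile), target = chain_key(target)),
    class = "superposition_result"
  )
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition> %s -> %s  rmsd=%.3f A over %d residues\n",
              x$mobile, x$target, x$rmsd, x$n_aligned))
  invisible(x)
}

#' Superpose all chains of a segment onto a reference chain
#'
#' One Kabsch superposition per non-reference member, giving the transforms
#' needed to display the whole segment in the reference's frame (the
#' pairwise dissimilarity structure is already covered by the GLOCON
#' matrix, so a common frame is all that display requires).
#'
#' @param segment A `segment`.
#' @param reference Chain key of the reference member (typically a cluster
#'   representative).
#' @return Named list of `superposition_result` objects, one per
#'   non-reference member, keyed by chain key.
#' @export
superpose_segment <- function(segment, reference) {
  keys <- segment_keys(segment)
  if (!reference %in% keys) {
    stop("reference chain '", reference, "' is not a member of segment '",
         segment$segment_id, "'", call. = FALSE)
  }
  target <- segment$members[[match(reference, keys)]]
  out <- list()
  for (i in seq_along(keys)) {
    if (keys[i] == reference) next
    res <- tryCatch(
      kabsch_superpose(segment$members[[i]], target),
      error = function(e) {
        stop("superposition of '", keys[i], "' onto '", reference,
             "' failed: ", conditionMessage(e), call. = FALSE)
      }
    )
    out[[keys[i]]] <- res
  }
  out
}

#' RMSD of a predicted model against each cluster representative
#'
#' Superposes the model onto every cluster's representative chain and
#' reports the per-cluster RMSD, identifying the conformational state the
#' model most resembles. A cluster whose representative shares no residues
#' with the model gets an `NA` RMSD (reported, never silently dropped) and
#' is excluded from the arg-min.
#'
#' @param model A [chain_record()] numbered in the segment's reference
#'   coordinates.
#' @param assignment A `cluster_assignment` for the segment.
#' @param segment The `segment` the assignment belongs to.
#' @return A list with `rmsd` (named numeric vector, cluster label ->
#'   RMSD), `n_aligned` (named integer vector) and `closest` (label of the
#'   minimum-RMSD cluster, `NA` if none defined).
#' @export
model_vs_representatives <- function(model, assignment, segment) {
  keys <- segment_keys(segment)
  labs <- names(assignment$representatives)
  rmsd <- stats::setNames(rep(NA_real_, length(labs)), labs)
  n_aligned <- stats::setNames(rep(NA_integer_, length(labs)), labs)
  for (k in seq_along(labs)) {
    rep_key <- assignment$representatives[[k]]
    rep_chain <- segment$members[[match(rep_key, keys)]]
    res <- tryCatch(kabsch_superpose(model, rep_chain),
                    error = function(e) NULL)
    if (!is.null(res)) {
      rmsd[k] <- res$rmsd
      n_aligned[k] <- res$n_aligned
    }
  }
  closest <- if (all(is.na(rmsd))) NA_character_ else
    labs[which.min(rmsd)]
  list(rmsd = rmsd, n_aligned = n_aligned, closest = closest)
}

#' Write a per-cluster model RMSD report
#'
#' @param comparison Result of [model_vs_representatives()].
#' @param assignment The `cluster_assignment` used.
#' @param segment The segment.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_model_rmsd_csv <- function(comparison, assignment, segment, path) {
  df <- data.frame(
    segment_id = segment$segment_id,
    cluster = as.integer(names(comparison$rmsd)),
    representative = as.character(assignment$representatives),
    model_rmsd = round(comparison$rmsd, 6),
    n_aligned = comparison$n_aligned,
    is_closest = names(comparison$rmsd) == comparison$closest,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
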