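#' UPGMA clustering of a GLOCON matrix
#'
#' Unweighted pair-group average linkage: at every step the two clusters
#' with the smallest average pairwise dissimilarity (mean of the original
#' matrix entries across all member pairs) are merged, at a height equal to
#' that average. Ties are broken by the lexicographically smallest pair of
#' cluster member-id minima, so results are reproducible across platforms
#' and input orderings. Merge heights are non-decreasing, as average
#' linkage guarantees.
#'
#' @param g A `glocon_matrix` from [pairwise_glocon()], or any symmetric
#'   zero-diagonal dissimilarity matrix with row/column names.
#' @return An object of class `glocon_dendrogram`: `leaves` (chain ids in
#'   input order), `merge` (hclust-style matrix: negative entries index
#'   leaves, positive entries earlier merges), `height` (merge heights),
#'   and `merge_members` (list of leaf-id sets per merge).
#' @export
upgma <- function(g) {
  G <- if (inherits(g, "glocon_matrix")) g$G else as.matrix(g)
  n <- nrow(G)
  if (n < 2L) stop("need at least 2 chains to cluster", call. = FALSE)
  if (is.null(rownames(G))) {
    dimnames(G) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  }
  if (!isTRUE(all.equal(G, t(G), tolerance = 1e-12)) ||
      any(diag(G) != 0) || any(G < 0)) {
    stop("dissimilarity matrix must be symmetric, non-negative, ",
         "with zero diagonal", call. = FALSE)
  }
  leaves <- rownames(G)

  # active clusters: members = leaf indices; node = hclust code
  clusters <- lapply(seq_len(n), function(i) {
    list(members = i, node = -i, min_id = leaves[i])
  })
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  merge_members <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- mean(G[clusters[[i]]$members, clusters[[j]]$members])
        key <- sort(c(clusters[[i]]$min_id, clusters[[j]]$min_id))
        better <- is.null(best) || h < best$h ||
          (h == best$h && (key[1L] < best$key[1L] ||
                             (key[1L] == best$key[1L] && key[2L] < best$key[2L])))
        if (better) best <- list(i = i, j = j, h = h, key = key)
      }
    }
    ci <- clusters[[best$i]]; cj <- clusters[[best$j]]
    merge[step, ] <- sort(c(ci$node, cj$node))
    height[step] <- best$h
    merged <- list(members = c(ci$members, cj$members), node = step,
                   min_id = min(ci$min_id, cj$min_id))
    merge_members[[step]] <- sort(leaves[merged$members])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  structure(list(leaves = leaves, merge = merge, height = height,
                 merge_members = merge_members),
            class = "glocon_dendrogram")
}

#' @export
print.glocon_dendrogram <- function(x, ...) {
  cat(sprintf("<glocon_dendrogram> %d leaves, root height %.3f\n",
              length(x$leaves), max(x$height)))
  invisible(x)
}

#' Convert a UPGMA dendrogram to an hclust object
#'
#' Useful for plotting with base graphics or converting further with
#' [stats::as.dendrogram()].
#'
#' @param x A `glocon_dendrogram`.
#' @param ... Unused.
#' @return A `stats::hclust` object.
#' @export
as.hclust.glocon_dendrogram <- function(x, ...) {
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0L) {
      ord <<- c(ord, -node)
    } else {
      walk(x$merge[node, 1L])
      walk(x$merge[node, 2L])
    }
  }
  walk(nrow(x$merge))
  structure(
    list(merge = x$merge, height = x$height, order = ord,
         labels = x$leaves, method = "average",
         call = match.call(), dist.method = "glocon"),
    class = "hclust"
  )
}

#' Export a dendrogram in Newick format
#'
#' Leaves sit at depth `root_height / 2` (the UPGMA ultrametric
#' convention): each branch length is half the difference between the
#' parent's and the child's merge height.
#'
#' @param d A `glocon_dendrogram`.
#' @param path Optional output path; if `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly if written to `path`).
#' @export
dendrogram_newick <- function(d, path = NULL) {
  node_str <- function(node, parent_h) {
    if (node < 0L) {
      sprintf("%s:%.6f", d$leaves[-node], parent_h / 2)
    } else {
      h <- d$height[node]
      sprintf("(%s,%s):%.6f",
              node_str(d$merge[node, 1L], h),
              node_str(d$merge[node, 2L], h),
              (parent_h - h) / 2)
    }
  }
  root <- nrow(d$merge)
  h <- d$height[root]
  nwk <- sprintf("(%s,%s);",
                 node_str(d$merge[root, 1L], h),
                 node_str(d$merge[root, 2L], h))
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Cut a dendrogram at a fraction of the maximum GLOCON score
#'
#' The cut height is `cut_fraction` times the largest off-diagonal entry of
#' the GLOCON matrix. Merges with height up to and including the cut height
#' are kept; discarding the higher merges leaves the clusters, which
#' approximate the segment's conformational states. Cluster labels are
#' 1-based, ordered by decreasing size with ties broken by the smallest
#' member chain id; each cluster's representative is its medoid under
#' GLOCON.
#'
#' @param d A `glocon_dendrogram`.
#' @param g The `glocon_matrix` the dendrogram was built from.
#' @param cut_fraction Fraction in (0, 1] of the maximum score; default 0.7.
#' @return An object of class `cluster_assignment`: `labels` (named integer
#'   vector, chain key -> cluster), `cut_height`, `representatives` (named
#'   character vector, cluster -> chain key), and `n_clusters`.
#' @export
cut_dendrogram <- function(d, g, cut_fraction = 0.7) {
  if (!(cut_fraction > 0 && cut_fraction <= 1)) {
    stop("cut_fraction must be in (0, 1]", call. = FALSE)
  }
  G <- if (inherits(g, "glocon_matrix")) g$G else as.matrix(g)
  cut_height <- cut_fraction * max(G[row(G) != col(G)])

  # union-find over leaves, applying merges at or below the cut
  parent <- seq_along(d$leaves)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  leaf_sets <- lapply(seq_along(d$leaves), function(i) i)
  node_rep <- integer(nrow(d$merge))  # leaf representative per kept merge
  for (m in seq_len(nrow(d$merge))) {
    if (d$height[m] > cut_height) break
    pick <- function(code) {
      if (code < 0L) -code else node_rep[code]
    }
    a <- find(pick(d$merge[m, 1L]))
    b <- find(pick(d$merge[m, 2L]))
    parent[max(a, b)] <- min(a, b)
    node_rep[m] <- min(a, b)
  }
  root <- vapply(seq_along(d$leaves), find, integer(1))
  comps <- split(seq_along(d$leaves), root)

  size <- lengths(comps)
  min_id <- vapply(comps, function(idx) min(d$leaves[idx]), character(1))
  ord <- order(-size, min_id)
  comps <- comps[ord]

  labels <- stats::setNames(integer(length(d$leaves)), d$leaves)
  reps <- character(length(comps))
  for (k in seq_along(comps)) {
    keys <- d$leaves[comps[[k]]]
    labels[keys] <- k
    reps[k] <- select_representative(keys, g)
  }
  structure(
    list(labels = labels, cut_height = cut_height,
         representatives = stats::setNames(reps, seq_along(comps)),
         n_clusters = length(comps)),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d clusters at cut height %.3f\n",
              x$n_clusters, x$cut_height))
  for (k in seq_len(x$n_clusters)) {
    cat(sprintf("  cluster %d (n=%d, representative %s)\n",
                k, sum(x$labels == k), x$representatives[[k]]))
  }
  invisible(x)
}

#' Medoid representative of a cluster
#'
#' The member minimising the summed GLOCON dissimilarity to all other
#' members; ties broken by the lexicographically smallest chain key. A
#' singleton cluster's representative is its only member.
#'
#' @param member_keys Character vector of chain keys in the cluster.
#' @param g The `glocon_matrix` (or named dissimilarity matrix) covering
#'   them.
#' @return A single chain key.
#' @export
select_representative <- function(member_keys, g) {
  stopifnot(length(member_keys) >= 1L)
  if (length(member_keys) == 1L) return(member_keys)
  G <- if (inherits(g, "glocon_matrix")) g$G else as.matrix(g)
  sums <- vapply(member_keys, function(k)
    sum(G[k, setdiff(member_keys, k)]), numeric(1))
  cand <- member_keys[sums == min(sums)]
  sort(cand)[1L]
}

#' Write a cluster assignment as CSV
#'
#' One row per chain: segment id, structure and chain id, cluster label
#' and whether the chain is its cluster's representative.
#'
#' @param assignment A `cluster_assignment`.
#' @param segment The segment it belongs to.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_csv <- function(assignment, segment, path) {
  keys <- names(assignment$labels)
  split_keys <- strsplit(keys, "_(?=[^_]+$)", perl = TRUE)
  df <- data.frame(
    segment_id = segment$segment_id,
    structure_id = vapply(split_keys, `[`, character(1), 1L),
    chain_id = vapply(split_keys, `[`, character(1), 2L),
    cluster = as.integer(assignment$labels),
    is_representative = keys %in% assignment$representatives,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$cluster, df$structure_id, df$chain_id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
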