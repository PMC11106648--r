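# Independent reference implementations used as oracles. These are written
# against the definitions, not against the package internals, and stay
# deliberately naive.

`%||%` <- function(a, b) if (is.null(a)) b else a

# random proper rotation (QR of a Gaussian matrix, sign-fixed)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rigidly_move <- function(rec, R = random_rotation(),
                         t = rnorm(3, sd = 20)) {
  rec$xyz <- rec$xyz %*% t(R) + matrix(t, nrow(rec$xyz), 3, byrow = TRUE)
  rec
}

# brute-force GLOCON for one pair of chain records
oracle_glocon_pair <- function(a, b, seg_len, tau = 3,
                               mode = "literal_product") {
  common <- sort(intersect(a$resno, b$resno))
  da <- as.matrix(dist(a$xyz[match(common, a$resno), , drop = FALSE]))
  db <- as.matrix(dist(b$xyz[match(common, b$resno), , drop = FALSE]))
  n <- length(common)
  s <- 0
  np <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- abs(da[i, j] - db[i, j])
      if (d < tau) d <- 0
      s <- s + d
      np <- np + 1L
    }
  }
  f <- n / seg_len
  if (mode == "mean_then_fraction") s <- s / np
  s * f
}

# Naive UPGMA via Lance-Williams dissimilarity updates (the package
# recomputes averages from the original matrix instead). Same tie-break:
# lexicographically smallest pair of cluster member-id minima.
oracle_upgma <- function(G) {
  n <- nrow(G)
  labels <- rownames(G)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D <- G
  active <- seq_len(n)
  sizes <- rep(1L, n)
  node <- -seq_len(n)
  minid <- labels
  merges <- list()
  for (step in seq_len(n - 1)) {
    best <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1):length(active)) {
        i <- active[ii]; j <- active[jj]
        h <- D[i, j]
        key <- sort(c(minid[i], minid[j]))
        take <- is.null(best) || h < best$h ||
          (h == best$h && (key[1] < best$key[1] ||
                             (key[1] == best$key[1] && key[2] < best$key[2])))
        if (take) best <- list(i = i, j = j, h = h, key = key)
      }
    }
    i <- best$i; j <- best$j
    merges[[step]] <- list(nodes = sort(c(node[i], node[j])), height = best$h)
    for (k in active) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        (sizes[i] * D[i, k] + sizes[j] * D[j, k]) / (sizes[i] + sizes[j])
    }
    sizes[i] <- sizes[i] + sizes[j]
    node[i] <- step
    minid[i] <- min(minid[i], minid[j])
    active <- setdiff(active, j)
  }
  merges
}

# Horn's closed-form quaternion superposition (independent of the SVD path)
oracle_quaternion_superpose <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  A <- sweep(P, 2, pc); B <- sweep(Q, 2, qc)
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
  t <- qc - as.vector(R %*% pc)
  moved <- P %*% t(R) + matrix(t, nrow(P), 3, byrow = TRUE)
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums((moved - Q)^2))))
}

# adjusted Rand index between two labelings (contingency-table formula)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# compact two-state hinge spec for small fixtures (hinge mid-chain)
two_state_spec <- function(n, seed, angle = 40, sigma = 0.2, chains = 5) {
  ensemble_spec(
    n_residues = n,
    states = list(
      list(name = "open", hinge_angle_deg = 0,
           hinge_residue = as.integer(n / 2)),
      list(name = "closed", hinge_angle_deg = angle,
           hinge_residue = as.integer(n / 2))
    ),
    chains_per_state = chains, jitter_sigma = sigma, seed = seed)
}

# small helper: build a chain record from a coordinate matrix
make_chain <- function(xyz, resno = seq_len(nrow(xyz)), id = "chn",
                       chain_id = "A", accession = "ACC") {
  chain_record(id, chain_id, accession, resno = resno, xyz = xyz)
}

# legacy PDB ATOM/MODEL writer for fixtures (fixed-column format)
write_pdb_fixture <- function(path, atoms, models = NULL) {
  # atoms: data.frame with chain, resno, x, y, z and optional alt, occ, insert
  fmt_atom <- function(serial, a) {
    sprintf("ATOM  %5d  CA %s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            serial,
            if (is.null(a$alt) || is.na(a$alt)) " " else a$alt,
            "ALA", a$chain, a$resno,
            if (is.null(a$insert) || is.na(a$insert)) " " else a$insert,
            a$x, a$y, a$z,
            if (is.null(a$occ) || is.na(a$occ)) 1 else a$occ, 0)
  }
  lines <- character(0)
  if (is.null(models)) {
    for (i in seq_len(nrow(atoms))) {
      lines <- c(lines, fmt_atom(i, as.list(atoms[i, ])))
    }
  } else {
    serial <- 0
    for (m in seq_along(models)) {
      lines <- c(lines, sprintf("MODEL     %4d", models[[m]]$number))
      at <- models[[m]]$atoms
      for (i in seq_len(nrow(at))) {
        serial <- serial + 1
        lines <- c(lines, fmt_atom(serial, as.list(at[i, ])))
      }
      lines <- c(lines, "ENDMDL")
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
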