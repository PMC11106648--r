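two_chain_segment <- function(a, b, interval = NULL) {
  if (is.null(interval)) {
    interval <- range(c(a$resno, b$resno))
  }
  structure(list(segment_id = "TEST_1", accession = a$accession,
                 interval = interval, members = list(a, b)),
            class = "segment")
}

test_that("distance matrix of collinear points is plain arithmetic", {
  ch <- make_chain(cbind(c(0, 3.8, 7.6), 0, 0))
  D <- ca_distance_matrix(ch)
  expect_equal(sort(D[upper.tri(D)]), c(3.8, 3.8, 7.6))
  expect_equal(unname(diag(D)), c(0, 0, 0))
})

test_that("distance matrix is invariant to rigid motion", {
  set.seed(5)
  ch <- generate_backbone(25)
  moved <- rigidly_move(ch, rotation_about_axis(c(1, 2, 3), 37 * pi / 180),
                        t = c(4, -2, 9))
  expect_lt(max(abs(ca_distance_matrix(ch) - ca_distance_matrix(moved))),
            1e-9)
})

test_that("distance matrix equals the brute-force pairwise norms", {
  set.seed(6)
  ch <- make_chain(matrix(rnorm(30, sd = 5), 10, 3))
  D <- ca_distance_matrix(ch)
  for (i in 1:10) for (j in 1:10) {
    expect_equal(D[i, j], sqrt(sum((ch$xyz[i, ] - ch$xyz[j, ])^2)))
  }
})

test_that("difference matrix works on the residue intersection", {
  a <- generate_backbone(100)
  b <- generate_backbone(90)
  res <- difference_matrix(ca_distance_matrix(a), ca_distance_matrix(b))
  expect_equal(dim(res$diff), c(90, 90))
  expect_equal(res$common, 1:90)
  expect_true(all(res$diff == 0))

  same <- difference_matrix(ca_distance_matrix(a), ca_distance_matrix(a))
  expect_true(all(same$diff == 0))
})

test_that("a single displaced residue marks exactly its row and column", {
  a <- generate_backbone(30)
  b <- a
  b$xyz[10, ] <- b$xyz[10, ] + c(5, 0, 0)
  res <- difference_matrix(ca_distance_matrix(a), ca_distance_matrix(b))
  nz <- which(res$diff > 1e-9, arr.ind = TRUE)
  expect_true(all(nz[, 1] == 10 | nz[, 2] == 10))
  expect_gt(sum(res$diff > 1e-9), 0)
})

test_that("too little residue overlap is a named error", {
  a <- generate_backbone(10)
  b <- generate_backbone(10)
  b$resno <- b$resno + 8L  # only residues 9,10 shared
  expect_error(
    difference_matrix(ca_distance_matrix(a), ca_distance_matrix(b),
                      ids = c("x_A", "y_B")),
    "insufficient overlap.*x_A.*y_B")
})

test_that("noise filter zeroes strictly-below-threshold entries only", {
  m <- matrix(c(0, 2.9, 3.0, 2.9, 0, 5, 3.0, 5, 0), 3, 3)
  f <- apply_noise_filter(m, 3)
  expect_equal(f[1, 2], 0)     # 2.9 is below 3 and vanishes
  expect_equal(f[1, 3], 3.0)   # 3.0 is not "below 3" and survives
  expect_equal(f[2, 3], 5)
  expect_equal(apply_noise_filter(m, 0), m)
})

test_that("the score is the filtered upper-triangle sum times the fraction", {
  filt <- matrix(0, 3, 3)
  filt[1, 2] <- filt[2, 1] <- 4
  filt[1, 3] <- filt[3, 1] <- 5
  expect_equal(glocon_score(filt, 0.5), 4.5)
  expect_equal(glocon_score(filt, 0.5, mode = "mean_then_fraction"),
               (9 / 3) * 0.5)
  expect_equal(glocon_score(matrix(0, 4, 4), 0.7), 0)
  expect_error(glocon_score(filt, 0), "fraction")
  expect_error(glocon_score(filt, 1.2), "fraction")
})

test_that("random matrices match an independent two-loop summation", {
  set.seed(8)
  for (rep in 1:5) {
    m <- matrix(runif(400, 0, 10), 20, 20)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    s <- 0
    for (i in 1:19) for (j in (i + 1):20) s <- s + m[i, j]
    expect_equal(glocon_score(m, 0.8), s * 0.8)
  }
})

test_that("fraction_modeled is common coverage over segment length", {
  a <- generate_backbone(100)
  b <- generate_backbone(100)
  seg <- two_chain_segment(a, b)
  expect_equal(fraction_modeled(a, b, seg), 1.0)

  b10 <- b
  keep <- !(b10$resno %in% 41:50)
  b10$resno <- b10$resno[keep]; b10$xyz <- b10$xyz[keep, ]
  expect_equal(fraction_modeled(a, b10, two_chain_segment(a, b10,
                                                          c(1, 100))), 0.9)

  a5 <- a
  keep_a <- !(a5$resno %in% 1:10)
  a5$resno <- a5$resno[keep_a]; a5$xyz <- a5$xyz[keep_a, ]
  b5 <- b
  keep_b <- !(b5$resno %in% 6:15)
  b5$resno <- b5$resno[keep_b]; b5$xyz <- b5$xyz[keep_b, ]
  expect_equal(fraction_modeled(a5, b5, two_chain_segment(a5, b5,
                                                          c(1, 100))), 0.85)
})

test_that("random gap patterns agree with a set-arithmetic oracle", {
  set.seed(9)
  base <- generate_backbone(80)
  for (rep in 1:50) {
    a <- base; b <- base
    ga <- sort(sample(1:80, sample(0:30, 1)))
    gb <- sort(sample(1:80, sample(0:30, 1)))
    keep_a <- !(a$resno %in% ga); keep_b <- !(b$resno %in% gb)
    a$resno <- a$resno[keep_a]; a$xyz <- a$xyz[keep_a, ]
    b$resno <- b$resno[keep_b]; b$xyz <- b$xyz[keep_b, ]
    seg <- two_chain_segment(a, b, c(1, 80))
    expected <- length(intersect(setdiff(1:80, ga), setdiff(1:80, gb))) / 80
    if (expected == 0) {
      expect_error(fraction_modeled(a, b, seg), "overlap")
    } else {
      expect_equal(fraction_modeled(a, b, seg), expected)
    }
  }
})

test_that("pairwise GLOCON equals the single-pair path and is symmetric", {
  spec <- two_state_spec(60, seed = 21, angle = 40, sigma = 0.3)
  ens <- generate_ensemble(spec, tempfile("pair"))
  seg <- assign_segments(ens$records, ens$mapping)[[1]]
  g <- pairwise_glocon(seg)
  expect_identical(g$G, t(g$G))
  expect_equal(unname(diag(g$G)), rep(0, 10))
  keys <- segment_keys(seg)
  for (i in c(1, 4)) {
    for (j in c(6, 9)) {
      expect_equal(
        g$G[i, j],
        oracle_glocon_pair(seg$members[[i]], seg$members[[j]],
                           segment_length(seg)))
    }
  }
})

test_that("two identical chains score zero", {
  a <- generate_backbone(30, structure_id = "ida")
  b <- generate_backbone(30, structure_id = "idb")
  seg <- two_chain_segment(a, b)
  g <- pairwise_glocon(seg)
  expect_equal(max(abs(g$G)), 0)
})

test_that("GLOCON is blind to sub-threshold jitter", {
  a <- generate_backbone(50, structure_id = "ja")
  b <- perturb_chain(generate_backbone(50, structure_id = "jb"), 0.2,
                     seed = 3)
  g <- pairwise_glocon(two_chain_segment(a, b))
  expect_equal(max(g$G), 0)
})

test_that("GLOCON grows monotonically with hinge opening", {
  base <- generate_backbone(60, structure_id = "h0")
  scores <- vapply(seq(0, 90, by = 10), function(ang) {
    moved <- if (ang == 0) base else apply_hinge(base, 30, ang)
    moved$structure_id <- "h1"
    g <- pairwise_glocon(two_chain_segment(base, moved))
    g$G[1, 2]
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
  expect_gt(scores[10], 0)
})

test_that("a gappier pair never out-scores the complete pair", {
  base <- generate_backbone(60, structure_id = "ga")
  open <- apply_hinge(generate_backbone(60, structure_id = "gb"), 30, 45)
  full <- pairwise_glocon(two_chain_segment(base, open))$G[1, 2]
  gappy <- open
  keep <- !(gappy$resno %in% 40:49)
  gappy$resno <- gappy$resno[keep]; gappy$xyz <- gappy$xyz[keep, ]
  g2 <- pairwise_glocon(two_chain_segment(base, gappy, c(1, 60)))$G[1, 2]
  expect_lte(g2, full)
})

test_that("rigid motions of either chain leave the matrix unchanged", {
  set.seed(10)
  spec <- two_state_spec(40, seed = 31, angle = 60, sigma = 0.3, chains = 2)
  ens <- generate_ensemble(spec, tempfile("rig"))
  seg <- assign_segments(ens$records, ens$mapping)[[1]]
  g0 <- pairwise_glocon(seg)$G
  for (rep in 1:10) {
    seg2 <- seg
    seg2$members <- lapply(seg$members, rigidly_move)
    expect_lt(max(abs(pairwise_glocon(seg2)$G - g0)), 1e-9)
  }
})

test_that("matrix exports round-trip", {
  spec <- two_state_spec(30, seed = 41, angle = 90, sigma = 0.2, chains = 2)
  ens <- generate_ensemble(spec, tempfile("exp"))
  seg <- assign_segments(ens$records, ens$mapping)[[1]]
  g <- pairwise_glocon(seg)
  csv <- tempfile(fileext = ".csv")
  write_glocon_csv(g, csv)
  back <- read.csv(csv)
  expect_equal(back$chain, g$chain_ids)
  expect_equal(as.matrix(back[, -1]),
               unname(g$G), ignore_attr = TRUE, tolerance = 1e-6)
  phy <- tempfile(fileext = ".phylip")
  write_glocon_phylip(g, phy)
  first <- scan(phy, n = 1, quiet = TRUE)
  expect_equal(first, length(g$chain_ids))
})
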