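# Fragment extraction, superposition RMSD, cutoff scan, representatives.

test_that("fragment extraction yields 55 coarse-grained points and rejects gaps", {
  h <- make_helix("GCGAUCUA")
  fr <- extract_fragment(h, "A", 3, "B", 4)
  expect_identical(dim(fr$coords), c(55L, 3L))
  # identity oracle: rows equal direct per-residue extraction
  cr <- dualamine:::chain_residues(h, "A")
  direct <- dualamine:::coarse_grain_residue(cr$sub, cr$rows_of[[1]])
  expect_equal(fr$coords[1:5, ], direct)
  expect_error(extract_fragment(h, "A", 2, "B", 4),
               class = "FragmentIncomplete")   # needs 2 upstream
  expect_error(extract_fragment(h, "A", 7, "B", 4),
               class = "FragmentIncomplete")   # needs 3 downstream
  # missing coarse-grain atom
  broken <- h[!(h$chain == "A" & h$resno == 4 & h$elety == "C4'"), ]
  broken <- dualamine:::new_structure(broken, "BRK")
  expect_error(extract_fragment(broken, "A", 3, "B", 4),
               class = "FragmentIncomplete")
})

test_that("superposition RMSD is zero on rigid copies and symmetric", {
  set.seed(5)
  fs <- make_fragment_set(k = 2, n_per = 3, sigma = 0.2, seed = 2)
  f1 <- fs$fragments[[1]]
  moved <- sweep(f1 %*% random_rotation(), 2, c(5, -3, 9), "+")
  expect_lt(superpose_rmsd(f1, moved), 1e-9)
  m <- rmsd_matrix(fs$fragments)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  # rigid motion of one member leaves the matrix unchanged
  fs2 <- fs$fragments
  fs2[[2]] <- sweep(fs2[[2]] %*% random_rotation(), 2, c(-4, 2, 1), "+")
  expect_equal(rmsd_matrix(fs2), m, tolerance = 1e-9)
  expect_error(rmsd_matrix(list(f1, f1[1:10, ])), class = "ContractViolation")
})

test_that("superposition matches a brute-force rotation-grid oracle", {
  # small point clouds; oracle scans a dense grid of rotations
  set.seed(8)
  p <- matrix(rnorm(12), 4, 3)
  q <- matrix(rnorm(12), 4, 3)
  got <- superpose_rmsd(p, q)
  pc <- sweep(p, 2, colMeans(p)); qc <- sweep(q, 2, colMeans(q))
  best <- Inf
  for (a in seq(0, 350, by = 10)) for (b in seq(0, 170, by = 10))
    for (c in seq(0, 350, by = 10)) {
      r <- dualamine:::rot_z(a) %*% dualamine:::rot_x(b) %*% dualamine:::rot_z(c)
      best <- min(best, sqrt(sum((pc %*% r - qc)^2) / nrow(p)))
    }
  expect_lte(got, best + 1e-9)        # optimal beats every grid rotation
  expect_lt(abs(got - best), 0.05)    # and the grid gets close to it
})

test_that("no-reflection guard: mirror images keep a nonzero RMSD", {
  set.seed(10)
  p <- matrix(rnorm(30), 10, 3)
  q <- p
  q[, 3] <- -q[, 3]
  expect_gt(superpose_rmsd(p, q), 0.1)
})

test_that("planted partitions are recovered at the Silhouette-optimal cutoff", {
  for (k in 2:3) {
    fs <- make_fragment_set(k = k, n_per = 8, sigma = 0.3, seed = 40 + k)
    m <- rmsd_matrix(fs$fragments)
    cl <- scan_and_cluster(m, fragments = fs$fragments)
    expect_identical(length(unique(cl$labels)), k)
    tab <- table(cl$labels, fs$labels)
    expect_true(all(tab %in% c(0L, 8L)))   # perfect membership
    expect_gt(max(cl$metrics$silhouette, na.rm = TRUE), 0.8)
    # dominant cluster is the (joint) max-membership one
    expect_identical(unname(max(table(cl$labels))),
                     sum(cl$labels == cl$dominant))
  }
})

test_that("identical fragments collapse into one cluster at any cutoff", {
  f <- make_fragment_set(k = 1, n_per = 6, sigma = 0, seed = 3)
  m <- rmsd_matrix(f$fragments)
  expect_lt(max(m), 1e-9)
  err <- tryCatch(scan_and_cluster(m), error = function(e) e)
  # an all-identical set has no scan range above the zero cutoff: either a
  # single cluster or a NoValidCutoff signal is acceptable, never a split
  if (!inherits(err, "error")) {
    expect_identical(length(unique(err$labels)), 1L)
  } else {
    expect_s3_class(err, "NoValidCutoff")
  }
})

test_that("validation metrics are invariant to label permutation", {
  fs <- make_fragment_set(k = 2, n_per = 5, sigma = 0.3, seed = 6)
  m <- rmsd_matrix(fs$fragments)
  lab <- fs$labels
  relab <- ifelse(lab == 1, 2L, 1L)
  expect_equal(dualamine:::calinski_harabasz_d(m, lab),
               dualamine:::calinski_harabasz_d(m, relab))
  expect_equal(dualamine:::davies_bouldin_d(m, lab),
               dualamine:::davies_bouldin_d(m, relab))
  expect_equal(dualamine:::mean_silhouette(m, lab),
               dualamine:::mean_silhouette(m, relab))
})

test_that("distance-form validation metrics equal their coordinate forms", {
  # embed points in 3D, compare against textbook coordinate formulas
  set.seed(12)
  pts <- rbind(matrix(rnorm(30, 0), 10, 3), matrix(rnorm(30, 6), 10, 3))
  lab <- rep(1:2, each = 10)
  dmat <- as.matrix(dist(pts))
  ch_coord <- {
    n <- nrow(pts); k <- 2
    cent <- apply(pts, 2, function(col) tapply(col, lab, mean))
    gmean <- colMeans(pts)
    wss <- sum((pts - cent[lab, ])^2)
    bss <- sum(10 * rowSums(sweep(cent, 2, gmean)^2))
    (bss / (k - 1)) / (wss / (n - k))
  }
  expect_equal(dualamine:::calinski_harabasz_d(dmat, lab), ch_coord,
               tolerance = 1e-9)
  db_coord <- {
    cent <- apply(pts, 2, function(col) tapply(col, lab, mean))
    s <- sqrt(tapply(rowSums((pts - cent[lab, ])^2), lab, mean))
    m12 <- sqrt(sum((cent[1, ] - cent[2, ])^2))
    mean(rep((s[1] + s[2]) / m12, 2))
  }
  expect_equal(dualamine:::davies_bouldin_d(dmat, lab), unname(db_coord),
               tolerance = 1e-9)
})

test_that("the representative of a symmetric cluster is its central member", {
  fs <- make_fragment_set(k = 1, n_per = 1, sigma = 0, seed = 9)
  center <- fs$fragments[[1]]
  delta <- matrix(0, nrow(center), 3)
  delta[1:10, 1] <- 1.5
  members <- list(center + delta, center, center - delta)
  m <- rmsd_matrix(members)
  expect_identical(cluster_representative(members, m, 1:3), 2L)
  # singleton cluster returns the fragment itself
  expect_identical(cluster_representative(members, m, 3L), 3L)
  # invariance to member ordering
  perm <- c(2L, 3L, 1L)
  m2 <- rmsd_matrix(members[perm])
  expect_identical(perm[cluster_representative(members[perm], m2, 1:3)], 2L)
})
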