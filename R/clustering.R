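# Coarse-grained fragment extraction and superposition-RMSD clustering for
# motif discovery. Each nucleotide is reduced to five atoms (purines: P,
# C4', N9, C2, C6; pyrimidines: P, C4', N1, C2, C4) so fragments of
# different sequence are comparable; a 6 x 5 nucleotide window (strand of
# interest x pairing-partner strand) gives 55 points per fragment.

COARSE_GRAIN <- list(purine = c("P", "C4'", "N9", "C2", "C6"),
                     pyrimidine = c("P", "C4'", "N1", "C2", "C4"))

coarse_grain_residue <- function(structure, rows) {
  resid <- sub("^D", "", structure$resid[rows[1]])
  atoms <- if (resid %in% c("A", "G")) COARSE_GRAIN$purine else COARSE_GRAIN$pyrimidine
  out <- matrix(NA_real_, length(atoms), 3)
  for (j in seq_along(atoms)) {
    p <- residue_atom(structure, rows, atoms[j])
    if (is.null(p)) return(NULL)
    out[j, ] <- p
  }
  out
}

#' Extract a coarse-grained 6 x 5 nucleotide fragment
#'
#' Strand 1 holds the residue of interest at position 3 of 6 (two residues
#' upstream, three downstream); strand 2 holds its base-pairing partner
#' with two flanking residues on each side. Fragments with any missing
#' residue or coarse-grain atom are rejected, never padded.
#'
#' @param structure structure data frame.
#' @param chain,resno residue of interest.
#' @param partner_chain,partner_resno its base-pairing partner.
#' @param insert,partner_insert insertion codes.
#' @param strand1_window offsets relative to the residue of interest.
#' @param strand2_window offsets relative to the partner.
#' @return A `dualamine_fragment`: list with `coords` (55 x 3) and `meta`.
#' @export
extract_fragment <- function(structure, chain, resno,
                             partner_chain, partner_resno,
                             insert = "", partner_insert = "",
                             strand1_window = -2:3, strand2_window = -2:2) {
  grab_strand <- function(ch, rn, window) {
    cr <- chain_residues(structure, ch)
    resnos <- vapply(cr$keys, function(k)
      as.integer(cr$sub$resno[match(k, residue_key(cr$sub))]), 1L)
    at <- match(rn, resnos)
    if (is.na(at)) abort_class("FragmentIncomplete", "residue not in chain")
    want <- at + window
    if (any(want < 1 | want > length(cr$keys))) {
      abort_class("FragmentIncomplete", "insufficient flanking residues")
    }
    blocks <- lapply(want, function(i) coarse_grain_residue(cr$sub, cr$rows_of[[i]]))
    if (any(vapply(blocks, is.null, TRUE))) {
      abort_class("FragmentIncomplete", "missing coarse-grain atom")
    }
    do.call(rbind, blocks)
  }
  s1 <- grab_strand(chain, resno, strand1_window)
  s2 <- grab_strand(partner_chain, partner_resno, strand2_window)
  structure(list(coords = rbind(s1, s2),
                 meta = list(entry_id = attr(structure, "entry_id"),
                             chain = chain, resno = resno,
                             partner_chain = partner_chain,
                             partner_resno = partner_resno)),
            class = "dualamine_fragment")
}

#' Pairwise superposition RMSD matrix
#'
#' Minimal least-squares RMSD (optimal proper rotation and translation, no
#' reflection) between every pair of fragments.
#'
#' @param fragments list of fragments (or bare coordinate matrices) with
#'   identical point counts.
#' @return Symmetric matrix with zero diagonal.
#' @export
rmsd_matrix <- function(fragments) {
  coords <- lapply(fragments, function(f) {
    if (inherits(f, "dualamine_fragment")) f$coords else as.matrix(f)
  })
  npts <- vapply(coords, nrow, 1L)
  if (length(unique(npts)) > 1) {
    abort_class("ContractViolation", "fragments differ in point count")
  }
  n <- length(coords)
  m <- matrix(0, n, n)
  if (n < 2) return(m)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- superpose_rmsd(coords[[i]], coords[[j]])
  }
  m
}

# Distance-only cluster validation metrics. Within-cluster dispersions use
# the Euclidean identities WSS_k = sum_{i<j in k} d_ij^2 / n_k and
# ||c_i - c_j||^2 = mean d^2(between) - WSS_i/n_i - WSS_j/n_j, which are
# exact when the distances embed in Euclidean space.
wss_of <- function(d2, members) {
  if (length(members) < 2) return(0)
  sum(d2[members, members]) / (2 * length(members))
}

calinski_harabasz_d <- function(dmat, labels) {
  d2 <- dmat^2
  n <- length(labels)
  k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  groups <- split(seq_len(n), labels)
  wss <- sum(vapply(groups, function(g) wss_of(d2, g), 0))
  tss <- sum(d2) / (2 * n)
  ((tss - wss) / (k - 1)) / (wss / (n - k))
}

davies_bouldin_d <- function(dmat, labels) {
  d2 <- dmat^2
  groups <- split(seq_along(labels), labels)
  k <- length(groups)
  if (k < 2) return(NA_real_)
  s <- vapply(groups, function(g) sqrt(wss_of(d2, g) / length(g)), 0)
  ratios <- matrix(0, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    gi <- groups[[i]]; gj <- groups[[j]]
    m2 <- mean(d2[gi, gj]) - wss_of(d2, gi) / length(gi) -
      wss_of(d2, gj) / length(gj)
    m <- sqrt(max(m2, 1e-12))
    ratios[i, j] <- ratios[j, i] <- (s[i] + s[j]) / m
  }
  mean(apply(ratios, 1, max))
}

mean_silhouette <- function(dmat, labels) {
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- cluster::silhouette(labels, dmatrix = dmat)
  mean(sil[, "sil_width"])
}

#' Cutoff scan and agglomerative clustering of an RMSD matrix
#'
#' Hierarchical clustering on the precomputed distance matrix. Cutoffs are
#' scanned from the smallest value at which a cluster of at least four
#' members forms, up to the integer below the maximum pairwise distance;
#' the Silhouette score, Calinski-Harabasz index, and Davies-Bouldin index
#' are computed at each cutoff, and the Silhouette-optimal cutoff is
#' chosen.
#'
#' @param dmat symmetric distance matrix.
#' @param linkage hclust linkage method (default "average").
#' @param grid_step cutoff grid step in Angstrom.
#' @param min_cluster_size cluster size that opens the scan range.
#' @return List: `cutoff`, `labels`, `metrics` (per scanned cutoff),
#'   `dominant` (label of the most populated cluster), `representatives`
#'   (per cluster, see [cluster_representative()]), `hclust`.
#' @export
scan_and_cluster <- function(dmat, linkage = "average", grid_step = 0.05,
                             min_cluster_size = 4, fragments = NULL) {
  dmat <- as.matrix(dmat)
  if (max(abs(dmat - t(dmat))) > 1e-9 || any(diag(dmat) != 0)) {
    abort_class("ContractViolation", "not a distance matrix")
  }
  hc <- stats::hclust(stats::as.dist(dmat), method = linkage)
  heights <- sort(unique(hc$height))
  lo <- NA_real_
  for (h in heights) {
    sizes <- table(stats::cutree(hc, h = h))
    if (any(sizes >= min_cluster_size)) { lo <- h; break }
  }
  hi <- floor(max(dmat))
  if (is.na(lo) || lo > hi + grid_step) {
    abort_class("NoValidCutoff", "no cutoff forms a cluster of minimum size")
  }
  from <- ceiling(lo / grid_step) * grid_step
  grid <- seq(from, max(hi, from), by = grid_step)
  metrics <- data.frame(cutoff = grid, n_clusters = NA_integer_,
                        silhouette = NA_real_, calinski_harabasz = NA_real_,
                        davies_bouldin = NA_real_)
  labels_at <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    lab <- stats::cutree(hc, h = grid[i])
    labels_at[[i]] <- lab
    metrics$n_clusters[i] <- length(unique(lab))
    metrics$silhouette[i] <- mean_silhouette(dmat, lab)
    metrics$calinski_harabasz[i] <- calinski_harabasz_d(dmat, lab)
    metrics$davies_bouldin[i] <- davies_bouldin_d(dmat, lab)
  }
  ok <- which(!is.na(metrics$silhouette))
  if (length(ok) == 0) abort_class("NoValidCutoff", "all scanned cutoffs are degenerate")
  best <- ok[which.max(metrics$silhouette[ok])]
  labels <- labels_at[[best]]
  dominant <- as.integer(names(which.max(table(labels))))
  reps <- NULL
  if (!is.null(fragments)) {
    reps <- vapply(sort(unique(labels)), function(cl) {
      cluster_representative(fragments, dmat, which(labels == cl))
    }, 1L)
    names(reps) <- sort(unique(labels))
  }
  list(cutoff = grid[best], labels = labels, metrics = metrics,
       dominant = dominant, representatives = reps, hclust = hc)
}

#' Representative member of a cluster
#'
#' Superposes every member onto the cluster medoid, averages the
#' coarse-grained coordinates, and returns the member with the smallest
#' RMSD to that average structure.
#'
#' @param fragments list of fragments or coordinate matrices.
#' @param dmat full distance matrix over the fragments.
#' @param members indices of the cluster members.
#' @return Index (into `fragments`) of the representative.
#' @export
cluster_representative <- function(fragments, dmat, members) {
  if (length(members) == 0) abort_class("ContractViolation", "empty cluster")
  if (length(members) == 1) return(members)
  coords <- lapply(fragments, function(f) {
    if (inherits(f, "dualamine_fragment")) f$coords else as.matrix(f)
  })
  medoid <- members[which.min(rowSums(dmat[members, members, drop = FALSE]))]
  aligned <- lapply(members, function(i) superpose_onto(coords[[i]], coords[[medoid]]))
  avg <- Reduce(`+`, aligned) / length(aligned)
  rms <- vapply(members, function(i) superpose_rmsd(coords[[i]], avg), 0)
  members[which.min(rms)]
}
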