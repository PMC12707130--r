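# Idealized exocyclic amine protonation. Structures deposited without
# hydrogens get two amine H's per A/C/G placed analytically: in the base
# plane, at the configured N-H bond length, symmetric about the C-N bond at
# half the H-N-H angle on either side (sp2 geometry). Placement is fully
# deterministic: identical coordinates give bit-identical hydrogens.

#' Place idealized amine hydrogens
#'
#' For every A, C, or G residue in the target chains with a complete set of
#' anchor atoms (A: N6 on C6 with N1/C5 as plane references; C: N4 on C4
#' with N3/C5; G: N2 on C2 with N1/N3), two hydrogens are placed in the
#' base plane at `nh_bond` from the nitrogen, at half of `hnh_angle` on
#' each side of the extended C-N direction. Residues where placement is
#' impossible (missing nitrogen or anchors, or a covalent modification at
#' the amine nitrogen, detected as a non-hydrogen atom within 1.2 A) are
#' excluded with a logged reason.
#'
#' @param structure a hydrogen-free structure data frame.
#' @param target_chains chains whose amines are donors (default all chains).
#' @param nh_bond N-H bond length in Angstrom.
#' @param hnh_angle H-N-H angle in degrees.
#' @return A list with `sites` (one row per amine: identity, nitrogen atom
#'   row index and coordinates of N, H1, H2) and `excluded` (residue
#'   identity plus reason).
#' @export
protonate_amines <- function(structure, target_chains = NULL,
                             nh_bond = 1.01, hnh_angle = 120) {
  if (any(structure$elesy == "H")) {
    abort_class("ContractViolation", "strip hydrogens before protonation")
  }
  if (is.null(target_chains)) target_chains <- unique(structure$chain)
  idx <- which(structure$resid %in% c("A", "C", "G") &
                 structure$chain %in% target_chains & structure$is_polymer)
  keys <- unique(residue_key(structure)[idx])
  sites <- list()
  excluded <- list()
  all_keys <- residue_key(structure)
  xyz <- structure_xyz(structure)
  for (k in keys) {
    rows <- which(all_keys == k & structure$is_polymer)
    resid <- structure$resid[rows[1]]
    chem <- get_chemistry(resid)
    am <- chem$amine
    ident <- data.frame(chain = structure$chain[rows[1]],
                        resno = structure$resno[rows[1]],
                        insert = structure$insert[rows[1]],
                        resid = resid, stringsAsFactors = FALSE)
    need <- c(am$n, am$anchor, am$ref1, am$ref2)
    have <- structure$elety[rows]
    if (!all(need %in% have)) {
      excluded[[length(excluded) + 1]] <-
        cbind(ident, reason = sprintf("missing anchor (%s)",
                                      paste(setdiff(need, have), collapse = ",")))
      next
    }
    n_row <- rows[match(am$n, have)]
    n <- xyz[n_row, ]
    anchor <- xyz[rows[match(am$anchor, have)], ]
    ref1 <- xyz[rows[match(am$ref1, have)], ]
    ref2 <- xyz[rows[match(am$ref2, have)], ]
    # covalent modification guard: any foreign heavy atom bonded to the N
    d_all <- sqrt(rowSums(sweep(xyz, 2, n)^2))
    close_idx <- which(d_all < 1.2 & seq_len(nrow(xyz)) != n_row)
    close_idx <- setdiff(close_idx, rows[match(am$anchor, have)])
    if (length(close_idx) > 0) {
      excluded[[length(excluded) + 1]] <-
        cbind(ident, reason = "modified amine nitrogen")
      next
    }
    hs <- place_sp2_hydrogens(n, anchor, ref1, ref2, nh_bond, hnh_angle)
    sites[[length(sites) + 1]] <-
      cbind(ident,
            data.frame(n_row = n_row,
                       nx = n[1], ny = n[2], nz = n[3],
                       h1x = hs[1, 1], h1y = hs[1, 2], h1z = hs[1, 3],
                       h2x = hs[2, 1], h2y = hs[2, 2], h2z = hs[2, 3]))
  }
  empty_id <- data.frame(chain = character(), resno = integer(),
                         insert = character(), resid = character(),
                         stringsAsFactors = FALSE)
  list(sites = if (length(sites)) do.call(rbind, sites) else
         cbind(empty_id, data.frame(n_row = integer(), nx = numeric(),
                                    ny = numeric(), nz = numeric(),
                                    h1x = numeric(), h1y = numeric(),
                                    h1z = numeric(), h2x = numeric(),
                                    h2y = numeric(), h2z = numeric())),
       excluded = if (length(excluded)) do.call(rbind, excluded) else
         cbind(empty_id, data.frame(reason = character())))
}

# Two in-plane hydrogens on an sp2 amine nitrogen. The plane is defined by
# the anchor carbon and its two ring references; H's sit at half the H-N-H
# angle on either side of the extended anchor->N direction, so one is cis
# and one trans to ref1. H1 is always the hydrogen on the ref1 side.
place_sp2_hydrogens <- function(n, anchor, ref1, ref2, nh_bond, hnh_angle) {
  u <- unitv(n - anchor)
  nrm <- unitv(vcross(ref1 - anchor, ref2 - anchor))
  perp <- unitv(vcross(nrm, u))
  # orient perp toward ref1 so H1/H2 labels are reproducible
  if (sum(perp * (ref1 - anchor)) > 0) perp <- -perp
  half <- hnh_angle / 2 * pi / 180
  h1 <- n + nh_bond * (cos(half) * u - sin(half) * perp)
  h2 <- n + nh_bond * (cos(half) * u + sin(half) * perp)
  rbind(h1, h2)
}

#' Amine site coordinates as matrices
#' @param sites the `sites` data frame from [protonate_amines()].
#' @param i row index.
#' @return List with `n`, `h1`, `h2` 3-vectors.
#' @export
amine_coords <- function(sites, i) {
  list(n = c(sites$nx[i], sites$ny[i], sites$nz[i]),
       h1 = c(sites$h1x[i], sites$h1y[i], sites$h1z[i]),
       h2 = c(sites$h2x[i], sites$h2y[i], sites$h2z[i]))
}
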