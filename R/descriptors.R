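# Per-amine burial and conformation descriptors: Shrake-Rupley solvent
# accessible surface area, heavy-atom shell densities around the amine
# nitrogen, the glycosidic chi dihedral, and the eta/theta backbone
# pseudotorsions.

# van der Waals radii (Angstrom) used by the surface sampler; a compact
# standard set covering the elements present in nucleic-acid/protein
# structures. Unlisted elements fall back to 1.70.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Samples a quasi-uniform spherical point set on the solvent-accessible
#' sphere of each target atom (vdW radius + probe radius) and counts the
#' points not occluded by any neighbor's accessible sphere. Deterministic
#' for a fixed point count.
#'
#' @param structure a hydrogen-free structure data frame.
#' @param atom_rows rows of the atoms to evaluate (default: all atoms).
#' @param probe probe radius in Angstrom.
#' @param n_points sphere sample points per atom.
#' @return Numeric vector of SASA values (Angstrom^2), one per target atom.
#' @export
sasa_atoms <- function(structure, atom_rows = seq_len(nrow(structure)),
                       probe = 1.40, n_points = 100) {
  if (nrow(structure) == 0) abort_class("EmptyStructure", "no atoms")
  xyz <- structure_xyz(structure)
  radii <- vdw_radius(structure$elesy)
  sphere <- fibonacci_sphere(n_points)
  rmax <- max(radii) + probe
  index <- build_cell_index(xyz, cell = max(2 * rmax, 4))
  vapply(atom_rows, function(i) {
    ri <- radii[i] + probe
    center <- xyz[i, ]
    nb <- query_cell_index(index, center, ri + rmax)
    nb <- nb[nb != i]
    pts <- sweep(sphere * ri, 2, center, "+")
    if (length(nb) > 0) {
      acc_r2 <- (radii[nb] + probe)^2
      free <- rep(TRUE, n_points)
      for (j in seq_along(nb)) {
        d2 <- rowSums(sweep(pts, 2, xyz[nb[j], ])^2)
        free <- free & d2 > acc_r2[j]
        if (!any(free)) break
      }
      n_free <- sum(free)
    } else n_free <- n_points
    4 * pi * ri^2 * n_free / n_points
  }, numeric(1))
}

#' SASA of the amine nitrogens
#'
#' @param structure a structure data frame; hydrogens are stripped first.
#' @param sites amine sites from [protonate_amines()] (defaults to all
#'   amines of the structure).
#' @param probe,n_points see [sasa_atoms()].
#' @return `sites` with an added `sasa` column.
#' @export
sasa_of_amine_nitrogens <- function(structure, sites = NULL, probe = 1.40,
                                    n_points = 100) {
  structure <- strip_hydrogens(structure)
  if (is.null(sites)) sites <- protonate_amines(structure)$sites
  sites$sasa <- if (nrow(sites) > 0) {
    sasa_atoms(structure, sites$n_row, probe = probe, n_points = n_points)
  } else numeric(0)
  sites
}

#' Heavy-atom shell densities around a point
#'
#' Counts polymer heavy atoms within the inner region of interest
#' (r <= r1) and the outer shell (r1 < r <= r2) around a center, and
#' divides by the region volumes in nm^3. The central atom itself counts in
#' the inner region. Waters, ions, and ligands (non-polymer atoms) are
#' excluded.
#'
#' @param structure hydrogen-free structure data frame.
#' @param center 3-vector (typically the amine nitrogen position).
#' @param r1,r2 region radii in Angstrom.
#' @return Named vector: `n1`, `n2` (counts), `rho1`, `rho2` (atoms/nm^3).
#' @export
shell_density <- function(structure, center, r1 = 7.5, r2 = 12.5) {
  poly <- structure[structure$is_polymer &
                      !(structure$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(poly) == 0) {
    n1 <- 0L; n2 <- 0L
  } else {
    d <- sqrt(rowSums(sweep(structure_xyz(poly), 2, center)^2))
    n1 <- sum(d <= r1)
    n2 <- sum(d > r1 & d <= r2)
  }
  v1 <- 4 / 3 * pi * (r1 / 10)^3
  v2 <- 4 / 3 * pi * ((r2 / 10)^3 - (r1 / 10)^3)
  c(n1 = n1, n2 = n2, rho1 = n1 / v1, rho2 = n2 / v2)
}

residue_atom <- function(structure, rows, atom) {
  i <- rows[match(atom, structure$elety[rows])]
  if (is.na(i)) return(NULL)
  c(structure$x[i], structure$y[i], structure$z[i])
}

#' Glycosidic chi dihedral of a nucleotide
#'
#' O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for pyrimidines, reported in
#' (-180, 180]. The syn window is (-90, 90); the minor-population window
#' used for display is (-20, 130).
#'
#' @param structure structure data frame.
#' @param chain,resno,insert residue identity.
#' @return List: `chi` (degrees or NA), `syn`, `minor`, `reason`.
#' @export
chi_dihedral <- function(structure, chain, resno, insert = "") {
  rows <- which(residue_key(structure) == paste(chain, resno, insert, sep = "|"))
  if (length(rows) == 0) return(list(chi = NA_real_, syn = NA, minor = NA,
                                     reason = "residue not found"))
  resid <- structure$resid[rows[1]]
  purine <- sub("^D", "", resid) %in% c("A", "G")
  atoms <- if (purine) c("O4'", "C1'", "N9", "C4") else c("O4'", "C1'", "N1", "C2")
  pos <- lapply(atoms, function(a) residue_atom(structure, rows, a))
  if (any(vapply(pos, is.null, TRUE))) {
    return(list(chi = NA_real_, syn = NA, minor = NA, reason = "missing atom"))
  }
  chi <- dihedral4(pos[[1]], pos[[2]], pos[[3]], pos[[4]])
  list(chi = chi, syn = chi > -90 & chi < 90, minor = chi > -20 & chi < 130,
       reason = NA_character_)
}

# ordered residue table of one chain, with chain-break flags from the
# O3'(i)-P(i+1) covalent linkage distance
chain_residues <- function(structure, chain, break_dist = 2.5) {
  sub <- structure[structure$chain == chain & structure$is_polymer, ,
                   drop = FALSE]
  keys <- unique(residue_key(sub))
  ord <- order(vapply(keys, function(k) {
    as.numeric(sub$resno[match(k, residue_key(sub))])
  }, numeric(1)))
  keys <- keys[ord]
  rows_of <- lapply(keys, function(k) which(residue_key(sub) == k))
  linked <- rep(NA, length(keys) - 1)
  for (i in seq_along(linked)) {
    o3 <- residue_atom(sub, rows_of[[i]], "O3'")
    p <- residue_atom(sub, rows_of[[i + 1]], "P")
    linked[i] <- !is.null(o3) && !is.null(p) && vnorm(o3 - p) <= break_dist
  }
  list(sub = sub, keys = keys, rows_of = rows_of, linked = linked)
}

#' Backbone pseudotorsions eta and theta
#'
#' eta = C4'(i-1)-P(i)-C4'(i)-P(i+1); theta = P(i)-C4'(i)-P(i+1)-C4'(i+1),
#' mapped to [0, 360). Chain termini and chain breaks (consecutive-residue
#' O3'-P distance above `break_dist`) are undefined, reported as NA with a
#' reason rather than 0.
#'
#' @param structure structure data frame.
#' @param chain chain id.
#' @param break_dist covalent-linkage threshold in Angstrom.
#' @return Data frame per residue: identity, `eta`, `theta`, `reason`.
#' @export
eta_theta <- function(structure, chain, break_dist = 2.5) {
  cr <- chain_residues(structure, chain, break_dist)
  n <- length(cr$keys)
  out <- data.frame(chain = chain,
                    resno = vapply(cr$keys, function(k)
                      as.integer(cr$sub$resno[match(k, residue_key(cr$sub))]), 1L),
                    insert = vapply(cr$keys, function(k)
                      cr$sub$insert[match(k, residue_key(cr$sub))], ""),
                    eta = NA_real_, theta = NA_real_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  for (i in seq_len(n)) {
    if (i == 1 || i == n) { out$reason[i] <- "chain terminus"; next }
    if (!isTRUE(cr$linked[i - 1]) || !isTRUE(cr$linked[i])) {
      out$reason[i] <- "chain break"; next
    }
    c4_prev <- residue_atom(cr$sub, cr$rows_of[[i - 1]], "C4'")
    p_i <- residue_atom(cr$sub, cr$rows_of[[i]], "P")
    c4_i <- residue_atom(cr$sub, cr$rows_of[[i]], "C4'")
    p_next <- residue_atom(cr$sub, cr$rows_of[[i + 1]], "P")
    c4_next <- residue_atom(cr$sub, cr$rows_of[[i + 1]], "C4'")
    if (any(vapply(list(c4_prev, p_i, c4_i, p_next, c4_next), is.null, TRUE))) {
      out$reason[i] <- "missing atom"; next
    }
    out$eta[i] <- dihedral4(c4_prev, p_i, c4_i, p_next) %% 360
    out$theta[i] <- dihedral4(p_i, c4_i, p_next, c4_next) %% 360
  }
  out
}

#' Pseudotorsion region boxes
#'
#' The two dual-donor-enriched locations and the A-form reference region in
#' the (eta, theta) plane. Ranges are inclusive.
#'
#' @return Named list of boxes with `eta` and `theta` ranges (degrees).
#' @export
region_boxes <- function() {
  list(location1 = list(eta = c(43, 72), theta = c(151, 180)),
       location2 = list(eta = c(295, 324), theta = c(14, 43)),
       aform = list(eta = c(145, 190), theta = c(190, 245)))
}

#' Region membership of a pseudotorsion pair
#'
#' @param eta,theta pseudotorsions in degrees ([0, 360) or NA).
#' @param box one element of [region_boxes()].
#' @return TRUE/FALSE; undefined torsions give FALSE.
#' @export
in_region <- function(eta, theta, box) {
  !is.na(eta) & !is.na(theta) &
    eta >= box$eta[1] & eta <= box$eta[2] &
    theta >= box$theta[1] & theta <= box$theta[2]
}

#' Full descriptor set for the amines of a structure
#'
#' Joins SASA, shell densities, chi, and eta/theta onto the per-amine
#' records of a survey.
#'
#' @param structure structure data frame.
#' @param survey result of [survey_structure()].
#' @param probe,n_points surface sampler settings.
#' @return The survey `records` with descriptor columns appended.
#' @export
amine_descriptors <- function(structure, survey, probe = 1.40, n_points = 100) {
  structure <- strip_hydrogens(structure)
  recs <- survey$records
  sites <- survey$sites
  if (is.null(recs) || nrow(recs) == 0) return(recs)
  sites <- sasa_of_amine_nitrogens(structure, sites, probe, n_points)
  recs$sasa <- sites$sasa
  dens <- t(vapply(seq_len(nrow(sites)), function(i) {
    shell_density(structure, c(sites$nx[i], sites$ny[i], sites$nz[i]))
  }, c(n1 = 0, n2 = 0, rho1 = 0, rho2 = 0)))
  recs$rho1 <- dens[, "rho1"]
  recs$rho2 <- dens[, "rho2"]
  recs$chi <- NA_real_; recs$syn <- NA; recs$minor <- NA
  recs$eta <- NA_real_; recs$theta <- NA_real_
  for (ch in unique(recs$chain)) {
    et <- eta_theta(structure, ch)
    sel <- which(recs$chain == ch)
    m <- match(paste(recs$resno[sel], recs$insert[sel]),
               paste(et$resno, et$insert))
    recs$eta[sel] <- et$eta[m]
    recs$theta[sel] <- et$theta[m]
  }
  for (i in seq_len(nrow(recs))) {
    cd <- chi_dihedral(structure, recs$chain[i], recs$resno[i], recs$insert[i])
    recs$chi[i] <- cd$chi; recs$syn[i] <- cd$syn; recs$minor[i] <- cd$minor
  }
  recs
}
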