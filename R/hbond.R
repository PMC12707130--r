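# Geometric hydrogen-bond detection and donor classification.
#
# An amine-acceptor contact is an H-bond when the H-to-acceptor distance is
# at most `max_h_acceptor_distance` and the N-H-acceptor angle (vertex at
# the hydrogen) is at least `min_nha_angle`. Candidate acceptors are polymer
# atoms from the acceptor dictionary within `prescreen_radius` of the amine
# nitrogen, excluding the parent nucleobase.
#
# Donation classes:
#   non    - no passing bond;
#   single - passing bonds, but either one hydrogen carries them all
#            (bi/trifurcation) or all bonds share one acceptor;
#   dual   - both hydrogens carry passing bonds to at least two distinct
#            acceptor atoms.

#' Hydrogen-bond criteria
#'
#' @param prescreen_radius neighbor search radius around the amine nitrogen
#'   (Angstrom).
#' @param max_h_acceptor_distance maximum H-to-acceptor distance (Angstrom).
#' @param min_nha_angle minimum N-H-acceptor angle (degrees).
#' @return A criteria list.
#' @export
hbond_criteria <- function(prescreen_radius = 4.1,
                           max_h_acceptor_distance = 2.5,
                           min_nha_angle = 140) {
  if (prescreen_radius < max_h_acceptor_distance + 1.01) {
    abort_class("ContractViolation",
                "prescreen radius must cover max distance plus the N-H bond")
  }
  if (min(prescreen_radius, max_h_acceptor_distance, min_nha_angle) <= 0) {
    abort_class("ContractViolation", "criteria must be positive")
  }
  list(prescreen_radius = prescreen_radius,
       max_h_acceptor_distance = max_h_acceptor_distance,
       min_nha_angle = min_nha_angle)
}

# Uniform-grid spatial index over atom coordinates; query returns candidate
# row indices within `radius` of a point (superset pruned exactly).
build_cell_index <- function(xyz, cell = 4.2) {
  key <- paste(floor(xyz[, 1] / cell), floor(xyz[, 2] / cell),
               floor(xyz[, 3] / cell))
  list(cells = split(seq_len(nrow(xyz)), key), cell = cell, xyz = xyz)
}

query_cell_index <- function(index, point, radius) {
  cell <- index$cell
  lo <- floor((point - radius) / cell)
  hi <- floor((point + radius) / cell)
  keys <- as.vector(outer(
    as.vector(outer(lo[1]:hi[1], lo[2]:hi[2], paste)),
    lo[3]:hi[3], paste))
  cand <- unlist(index$cells[keys], use.names = FALSE)
  if (length(cand) == 0) return(integer())
  d2 <- rowSums(sweep(index$xyz[cand, , drop = FALSE], 2, point)^2)
  cand[d2 <= radius^2]
}

#' Candidate acceptors around an amine
#'
#' Polymer atoms within the prescreen radius of the amine nitrogen that
#' appear in the acceptor dictionary. Atoms of the parent nucleobase are
#' excluded; by default the parent residue's own sugar/phosphate atoms stay
#' eligible (set `exclude_parent_residue` to drop the whole residue).
#'
#' @param structure structure data frame.
#' @param site one row of the amine `sites` table.
#' @param criteria from [hbond_criteria()].
#' @param options from [chem_options()].
#' @param exclude_parent_residue drop all parent-residue atoms, not just the
#'   base moiety.
#' @param index optional prebuilt spatial index; exhaustive scan when NULL.
#' @return Integer vector of candidate atom row indices.
#' @export
find_candidates <- function(structure, site, criteria = hbond_criteria(),
                            options = chem_options(),
                            exclude_parent_residue = FALSE,
                            index = NULL) {
  xyz <- structure_xyz(structure)
  n <- c(site$nx, site$ny, site$nz)
  if (is.null(index)) {
    d2 <- rowSums(sweep(xyz, 2, n)^2)
    cand <- which(d2 <= criteria$prescreen_radius^2)
  } else {
    cand <- query_cell_index(index, n, criteria$prescreen_radius)
  }
  cand <- cand[structure$is_polymer[cand]]
  lp <- acceptor_lone_pairs(structure$resid[cand], structure$elety[cand], options)
  cand <- cand[!is.na(lp)]
  parent <- residue_key(structure)[cand] ==
    paste(site$chain, site$resno, site$insert, sep = "|")
  if (exclude_parent_residue) {
    cand <- cand[!parent]
  } else {
    base_atom <- structure$elety[cand] %in% BASE_MOIETY_ATOMS
    cand <- cand[!(parent & base_atom)]
  }
  sort(cand)
}

#' Measure amine-acceptor geometry
#'
#' For one acceptor position, returns the H-to-acceptor distance and the
#' N-H-acceptor angle for each of the two amine hydrogens. Both numbers are
#' invariant under rigid-body motion of the structure.
#'
#' @param site one row of the amine `sites` table.
#' @param acc acceptor position (3-vector).
#' @return Data frame with columns `h` (1/2), `d`, `alpha`.
#' @export
measure_amine_acceptor <- function(site, acc) {
  co <- amine_coords(site, 1)
  d1 <- vnorm(acc - co$h1); d2 <- vnorm(acc - co$h2)
  a1 <- angle3(co$n, co$h1, acc)
  a2 <- angle3(co$n, co$h2, acc)
  data.frame(h = c(1L, 2L), d = c(d1, d2), alpha = c(a1, a2))
}

#' Measure all candidates for one amine
#'
#' @param structure structure data frame.
#' @param site one amine site row.
#' @param cand candidate atom row indices from [find_candidates()].
#' @param criteria from [hbond_criteria()].
#' @return Observation data frame: acceptor identity and label, `h`, `d`,
#'   `alpha`, and the pass flag.
#' @export
measure_candidates <- function(structure, site, cand,
                               criteria = hbond_criteria()) {
  if (length(cand) == 0) {
    return(data.frame(acc_row = integer(), acc_chain = character(),
                      acc_resno = integer(), acc_insert = character(),
                      acc_resid = character(), acc_atom = character(),
                      acc_label = character(), h = integer(),
                      d = numeric(), alpha = numeric(), passes = logical(),
                      stringsAsFactors = FALSE))
  }
  xyz <- structure_xyz(structure)
  out <- lapply(cand, function(j) {
    m <- measure_amine_acceptor(site, xyz[j, ])
    lab <- generalize_acceptor(structure$resid[j], structure$elety[j])
    data.frame(acc_row = j, acc_chain = structure$chain[j],
               acc_resno = structure$resno[j],
               acc_insert = structure$insert[j],
               acc_resid = structure$resid[j],
               acc_atom = structure$elety[j], acc_label = lab,
               h = m$h, d = m$d, alpha = m$alpha,
               passes = m$d <= criteria$max_h_acceptor_distance &
                 m$alpha >= criteria$min_nha_angle,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify an amine from its observations
#'
#' Applies the donation-class definition and assigns the donation scenario:
#' 1 one bond; 2 both hydrogens to one shared acceptor (geometrically
#' unreachable under the default criteria); 3/4 one hydrogen bi-/trifurcated;
#' 5 one bond per hydrogen to two acceptors; 6 dual with an acceptor shared
#' between the hydrogens (also unreachable); 7 dual with a bifurcated
#' hydrogen.
#'
#' @param observations data frame from [measure_candidates()].
#' @return List: `klass` ("non"/"single"/"dual"), `scenario` (integer or NA),
#'   `n_bonds`.
#' @export
classify_amine <- function(observations) {
  p <- observations[observations$passes, , drop = FALSE]
  if (nrow(p) == 0) return(list(klass = "non", scenario = NA_integer_, n_bonds = 0L))
  hs <- unique(p$h)
  accs <- unique(p$acc_row)
  dual <- length(hs) == 2 && length(accs) >= 2
  if (!dual) {
    if (length(hs) == 1) {
      scenario <- if (nrow(p) == 1) 1L else if (length(accs) == 2) 3L else 4L
    } else {
      scenario <- 2L  # both H's, single shared acceptor
    }
    return(list(klass = "single", scenario = scenario, n_bonds = nrow(p)))
  }
  shared <- any(table(unique(p[, c("h", "acc_row")])$acc_row) == 2)
  scenario <- if (shared) 6L else if (any(table(p$h) >= 2)) 7L else 5L
  list(klass = "dual", scenario = scenario, n_bonds = nrow(p))
}

#' Acceptor pair of a dual-donating amine
#'
#' Per hydrogen, the passing acceptor with the greatest N-H-acceptor angle
#' is taken. If both hydrogens elect the same atom, the hydrogen with the
#' larger best angle keeps it and the other falls back to its best distinct
#' acceptor (preserving the two-acceptor definition of dual donation). The
#' pair is ordered canonically by label, then residue identity.
#'
#' @param observations data frame from [measure_candidates()].
#' @return List: `labels` (ordered pair), `same_residue` flag, `rows`
#'   (acceptor atom row indices in pair order).
#' @export
acceptor_pair <- function(observations) {
  p <- observations[observations$passes, , drop = FALSE]
  cls <- classify_amine(observations)
  if (cls$klass != "dual") {
    abort_class("ContractViolation", "acceptor_pair requires a dual amine")
  }
  best_for <- function(h, exclude_row = NULL) {
    q <- p[p$h == h, , drop = FALSE]
    if (!is.null(exclude_row)) q <- q[q$acc_row != exclude_row, , drop = FALSE]
    if (nrow(q) == 0) return(NULL)
    q <- q[order(-q$alpha, q$acc_label, q$acc_row), , drop = FALSE]
    q[1, , drop = FALSE]
  }
  b1 <- best_for(1L)
  b2 <- best_for(2L)
  if (b1$acc_row == b2$acc_row) {
    if (b1$alpha >= b2$alpha) {
      alt <- best_for(2L, exclude_row = b1$acc_row)
      if (is.null(alt)) { b1 <- best_for(1L, exclude_row = b2$acc_row) } else b2 <- alt
    } else {
      alt <- best_for(1L, exclude_row = b2$acc_row)
      if (is.null(alt)) { b2 <- best_for(2L, exclude_row = b1$acc_row) } else b1 <- alt
    }
  }
  pair <- rbind(b1, b2)
  ord <- order(pair$acc_label, pair$acc_chain, pair$acc_resno, pair$acc_atom)
  pair <- pair[ord, , drop = FALSE]
  same_res <- length(unique(paste(pair$acc_chain, pair$acc_resno,
                                  pair$acc_insert, sep = "|"))) == 1
  list(labels = pair$acc_label, same_residue = same_res, rows = pair$acc_row)
}

#' Survey every amine of a structure
#'
#' Runs candidate search, measurement, classification, and acceptor-pair
#' extraction for all amines in the target chains. The complete per-amine
#' record mirrors the per-instance CSV interchange format.
#'
#' @param structure a structure data frame (hydrogens are stripped first).
#' @param target_chains donor chains (default all).
#' @param criteria from [hbond_criteria()].
#' @param options from [chem_options()].
#' @param exclude_parent_residue see [find_candidates()].
#' @param use_index use the spatial index (set FALSE for the exhaustive
#'   reference scan).
#' @return List: `records` (one row per amine with class, scenario, pair
#'   labels, same-residue flag), `observations` (all measured pairs),
#'   `excluded` (residues skipped at protonation).
#' @export
survey_structure <- function(structure, target_chains = NULL,
                             criteria = hbond_criteria(),
                             options = chem_options(),
                             exclude_parent_residue = FALSE,
                             use_index = TRUE) {
  structure <- strip_hydrogens(structure)
  pro <- protonate_amines(structure, target_chains)
  sites <- pro$sites
  xyz <- structure_xyz(structure)
  index <- if (use_index && nrow(structure) > 0)
    build_cell_index(xyz, cell = criteria$prescreen_radius) else NULL
  recs <- vector("list", nrow(sites))
  obs_all <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, , drop = FALSE]
    cand <- find_candidates(structure, site, criteria, options,
                            exclude_parent_residue, index)
    obs <- measure_candidates(structure, site, cand, criteria)
    cls <- classify_amine(obs)
    pair_labels <- c(NA_character_, NA_character_)
    same_res <- NA
    if (cls$klass == "dual") {
      ap <- acceptor_pair(obs)
      pair_labels <- ap$labels
      same_res <- ap$same_residue
    }
    recs[[i]] <- data.frame(
      entry_id = attr(structure, "entry_id") %||% "XXXX",
      chain = site$chain, resno = site$resno, insert = site$insert,
      base = site$resid, klass = cls$klass, scenario = cls$scenario,
      n_bonds = cls$n_bonds,
      acc1 = pair_labels[1], acc2 = pair_labels[2], same_residue = same_res,
      stringsAsFactors = FALSE)
    if (nrow(obs) > 0) {
      obs$donor_chain <- site$chain
      obs$donor_resno <- site$resno
      obs$donor_insert <- site$insert
      obs$donor_base <- site$resid
      obs_all[[i]] <- obs
    }
  }
  list(records = if (length(recs)) do.call(rbind, recs) else NULL,
       observations = do.call(rbind, obs_all),
       excluded = pro$excluded,
       sites = sites)
}

#' Detect canonical GC base pairs
#'
#' A GC pair is canonical when both of its defining bonds pass the
#' criteria: G(N2) donating to the C's O2 and that C's N4 donating to the
#' G's O6.
#'
#' @param survey result of [survey_structure()].
#' @return Data frame of detected pairs (G and C identities), possibly empty.
#' @export
detect_canonical_gc <- function(survey) {
  obs <- survey$observations
  empty <- data.frame(g_chain = character(), g_resno = integer(),
                      c_chain = character(), c_resno = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(obs) || nrow(obs) == 0) return(empty)
  p <- obs[obs$passes, , drop = FALSE]
  g2c <- p[p$donor_base == "G" & p$acc_resid == "C" & p$acc_atom == "O2", ,
           drop = FALSE]
  c2g <- p[p$donor_base == "C" & p$acc_resid == "G" & p$acc_atom == "O6", ,
           drop = FALSE]
  if (nrow(g2c) == 0 || nrow(c2g) == 0) return(empty)
  key_gc <- paste(g2c$donor_chain, g2c$donor_resno, g2c$donor_insert,
                  g2c$acc_chain, g2c$acc_resno, g2c$acc_insert)
  key_cg <- paste(c2g$acc_chain, c2g$acc_resno, c2g$acc_insert,
                  c2g$donor_chain, c2g$donor_resno, c2g$donor_insert)
  hit <- unique(key_gc[key_gc %in% key_cg])
  if (length(hit) == 0) return(empty)
  parts <- do.call(rbind, strsplit(hit, " "))
  data.frame(g_chain = parts[, 1], g_resno = as.integer(parts[, 2]),
             c_chain = parts[, 4], c_resno = as.integer(parts[, 5]),
             stringsAsFactors = FALSE)
}

#' Geometry histogram of amine-acceptor measurements
#'
#' Bins (distance, angle) over all measured amine-acceptor pairs, keeping
#' per pair only the measurement set with the greater N-H-acceptor angle.
#' The four canonical-pairing combinations A(N6)-U(O4), C(N4)-G(O6),
#' G(N2)-C(O2) and G(N2)-C(N3) are excluded here (and only here).
#'
#' @param observations observation data frame from [survey_structure()].
#' @param exclude_canonical apply the canonical-pair exclusion.
#' @param d_breaks,a_breaks bin edges (defaults: 0.05 Angstrom and 2 degree
#'   bins over the prescreen window).
#' @return Count matrix (distance bins x angle bins) with break attributes.
#' @export
geometry_histogram <- function(observations, exclude_canonical = TRUE,
                               d_breaks = seq(0, 5.2, by = 0.05),
                               a_breaks = seq(0, 180, by = 2)) {
  if (is.null(observations) || nrow(observations) == 0) {
    m <- matrix(0L, length(d_breaks) - 1, length(a_breaks) - 1)
    attr(m, "d_breaks") <- d_breaks; attr(m, "a_breaks") <- a_breaks
    return(m)
  }
  obs <- observations
  pair_id <- paste(obs$donor_chain, obs$donor_resno, obs$donor_insert,
                   obs$acc_row)
  keep <- unlist(lapply(split(seq_len(nrow(obs)), pair_id), function(ii) {
    ii[which.max(obs$alpha[ii])]
  }), use.names = FALSE)
  obs <- obs[keep, , drop = FALSE]
  if (exclude_canonical) {
    combo <- paste(obs$donor_base, obs$acc_resid, obs$acc_atom)
    obs <- obs[!(combo %in% c("A U O4", "C G O6", "G C O2", "G C N3")), ,
               drop = FALSE]
  }
  di <- cut(obs$d, d_breaks, include.lowest = TRUE, labels = FALSE)
  ai <- cut(obs$alpha, a_breaks, include.lowest = TRUE, labels = FALSE)
  ok <- !is.na(di) & !is.na(ai)
  m <- matrix(0L, length(d_breaks) - 1, length(a_breaks) - 1)
  for (i in which(ok)) m[di[i], ai[i]] <- m[di[i], ai[i]] + 1L
  attr(m, "d_breaks") <- d_breaks
  attr(m, "a_breaks") <- a_breaks
  m
}
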