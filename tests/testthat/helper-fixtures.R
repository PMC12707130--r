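# Shared fixtures, built once per test run, plus small independent oracles.

.fix <- new.env()

fix_helix <- function() {
  if (is.null(.fix$helix)) .fix$helix <- make_helix("GCGAUCGC")
  .fix$helix
}

fix_pair <- function(kind) {
  key <- paste0("pair_", kind)
  if (is.null(.fix[[key]])) .fix[[key]] <- make_pair(kind)
  .fix[[key]]
}

# independent dihedral oracle (bio3d's implementation)
oracle_dihedral <- function(p1, p2, p3, p4) {
  bio3d::torsion.xyz(c(p1, p2, p3, p4), atm.inc = 4)
}

# deterministic random rotation matrix
random_rotation <- function() {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, 360)
  u <- ax; t <- ang * pi / 180
  ct <- cos(t); st <- sin(t)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(ct + ux^2 * (1 - ct), ux * uy * (1 - ct) + uz * st,
           ux * uz * (1 - ct) - uy * st,
           ux * uy * (1 - ct) - uz * st, ct + uy^2 * (1 - ct),
           uy * uz * (1 - ct) + ux * st,
           ux * uz * (1 - ct) + uy * st, uy * uz * (1 - ct) - ux * st,
           ct + uz^2 * (1 - ct)), 3, 3)
}

# apply a rigid transform to a structure data frame
transform_structure <- function(s, rot, shift) {
  xyz <- structure_xyz(s) %*% rot
  s$x <- xyz[, 1] + shift[1]
  s$y <- xyz[, 2] + shift[2]
  s$z <- xyz[, 3] + shift[3]
  s
}

# bare single-atom structure (for closed-form descriptor checks)
atom_structure <- function(xyz, elety = "N", elesy = "N", resid = "G",
                           polymer = TRUE, entry_id = "TOY") {
  xyz <- matrix(xyz, ncol = 3)
  df <- data.frame(eleno = seq_len(nrow(xyz)),
                   elety = rep_len(elety, nrow(xyz)), alt = "",
                   resid = rep_len(resid, nrow(xyz)), chain = "A",
                   resno = seq_len(nrow(xyz)), insert = "",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1,
                   elesy = rep_len(elesy, nrow(xyz)),
                   is_polymer = rep_len(polymer, nrow(xyz)), model = 1L,
                   stringsAsFactors = FALSE)
  dualamine:::new_structure(df, entry_id)
}

# random synthetic structure: a few rigidly placed donor bases plus
# scattered single-atom acceptors; used for index-vs-exhaustive equivalence
random_structure <- function(n_donors = 4, n_acceptors = 60, box = 18) {
  tmpl <- list(G = dualamine:::template_residue("G"),
               A = dualamine:::template_residue("A"),
               C = dualamine:::template_residue("C"))
  blocks <- list()
  for (i in seq_len(n_donors)) {
    base <- sample(names(tmpl), 1)
    at <- tmpl[[base]] %*% random_rotation()
    at <- sweep(at, 2, stats::runif(3, 0, box), "+")
    rownames(at) <- rownames(tmpl[[base]])
    blocks[[length(blocks) + 1]] <-
      list(atoms = at, chain = "A", resno = i, resid = base)
  }
  for (j in seq_len(n_acceptors)) {
    pos <- matrix(stats::runif(3, -3, box + 3), 1, 3,
                  dimnames = list("O4", NULL))
    blocks[[length(blocks) + 1]] <-
      list(atoms = pos, chain = "B", resno = j, resid = "U")
  }
  dualamine:::residues_to_structure(blocks, "RND")
}
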