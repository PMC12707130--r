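# Burial and conformation descriptors.

test_that("lone-atom SASA matches the closed form and burial drives it to zero", {
  iso <- atom_structure(c(0, 0, 0))
  expect_equal(sasa_atoms(iso, 1), 4 * pi * (1.55 + 1.40)^2, tolerance = 0.01)
  # nitrogen enclosed by a tight shell of contact-distance atoms
  shell <- dualamine:::fibonacci_sphere(80) * 2.9
  s <- atom_structure(rbind(c(0, 0, 0), shell),
                      elety = c("N2", rep("O2", 80)),
                      elesy = c("N", rep("O", 80)))
  expect_identical(sasa_atoms(s, 1), 0)
  expect_error(sasa_atoms(atom_structure(c(0, 0, 0))[0, ]),
               class = "EmptyStructure")
})

test_that("occlusion never increases SASA beyond the lone-atom bound", {
  set.seed(9)
  for (rep in 1:5) {
    pts <- matrix(runif(30, -4, 4), 10, 3)
    s <- atom_structure(pts)
    v <- sasa_atoms(s)
    expect_true(all(v <= 4 * pi * (1.55 + 1.40)^2 + 1e-9))
  }
  # adding an atom cannot increase another atom's SASA
  s1 <- atom_structure(rbind(c(0, 0, 0), c(3, 0, 0)))
  s2 <- atom_structure(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)))
  expect_lte(sasa_atoms(s2, 1), sasa_atoms(s1, 1))
})

test_that("shell densities match hand-computed sphere volumes and brute force", {
  iso <- atom_structure(c(0, 0, 0))
  d <- shell_density(iso, c(0, 0, 0))
  expect_equal(unname(d["rho1"]), 1 / 1.7671, tolerance = 1e-4)
  expect_identical(unname(d["rho2"]), 0)
  # 100 atoms on a 5 A sphere around the center atom
  shell <- dualamine:::fibonacci_sphere(100) * 5
  s <- atom_structure(rbind(c(0, 0, 0), shell))
  d2 <- shell_density(s, c(0, 0, 0))
  expect_equal(unname(d2["n1"]), 101)
  expect_equal(unname(d2["rho1"]), 101 / 1.7671, tolerance = 1e-3)
  # boundary closed at exactly 7.5 A
  s3 <- atom_structure(rbind(c(0, 0, 0), c(7.5, 0, 0), c(7.5 + 1e-9, 0, 1e-4)))
  d3 <- shell_density(s3, c(0, 0, 0))
  expect_equal(unname(d3["n1"]), 2)
  expect_equal(unname(d3["n2"]), 1)
  # brute-force count agreement on a random cloud
  set.seed(17)
  cloud <- matrix(runif(300, -14, 14), 100, 3)
  s4 <- atom_structure(cloud)
  d4 <- shell_density(s4, c(0, 0, 0))
  r <- sqrt(rowSums(cloud^2))
  expect_equal(unname(d4["n1"]), sum(r <= 7.5))
  expect_equal(unname(d4["n2"]), sum(r > 7.5 & r <= 12.5))
  # non-polymer atoms are excluded
  s5 <- atom_structure(rbind(c(0, 0, 0), c(2, 0, 0)), polymer = c(TRUE, FALSE))
  expect_equal(unname(shell_density(s5, c(0, 0, 0))["n1"]), 1)
})

test_that("chi matches an analytic four-point construction and flips under reflection", {
  # planar zigzag with a known 60 degree torsion
  p1 <- c(1, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 1)
  # build p4 at torsion 60 about the p2->p3 axis
  p4 <- dualamine:::nerf_place(p1, p2, p3, 1.5, 109.5, 60)
  expect_equal(dualamine:::dihedral4(p1, p2, p3, p4), 60, tolerance = 1e-9)
  mir <- function(p) c(p[1], p[2], -p[3])
  expect_equal(dualamine:::dihedral4(mir(p1), mir(p2), mir(p3), mir(p4)), -60,
               tolerance = 1e-9)
  # A-form helix residues are anti
  h <- fix_helix()
  for (rn in 2:5) {
    cd <- chi_dihedral(h, "A", rn)
    expect_false(cd$syn)
    expect_lt(cd$chi, -90)
  }
  expect_true(chi_dihedral(atom_structure(c(0, 0, 0)), "A", 1)$reason ==
                "missing atom")
})

test_that("syn and minor-population windows follow their definitions", {
  cases <- data.frame(chi = c(-100, -89, 0, 89, 100, -21, -19, 129, 131),
                      syn = c(F, T, T, T, F, T, T, F, F),
                      minor = c(F, F, T, T, T, F, T, T, F))
  for (i in seq_len(nrow(cases))) {
    # synthetic four points at the target torsion on a purine-like residue
    g <- dualamine:::template_residue("G")
    o4 <- dualamine:::nerf_place(g["C4", ], g["N9", ], g["C1'", ],
                                 1.414, 108.2, cases$chi[i])
    g["O4'", ] <- o4
    s <- atom_structure(g, elety = rownames(g),
                        elesy = dualamine:::guess_element(rownames(g)))
    s$resno <- rep(1L, nrow(s))
    cd <- chi_dihedral(s, "A", 1)
    expect_equal(cd$chi, cases$chi[i], tolerance = 1e-6)
    expect_identical(cd$syn, cases$syn[i], info = cases$chi[i])
    expect_identical(cd$minor, cases$minor[i], info = cases$chi[i])
  }
})

test_that("pseudotorsions agree with the independent dihedral oracle", {
  h <- fix_helix()
  et <- eta_theta(h, "A")
  cr <- dualamine:::chain_residues(h, "A")
  for (i in 2:(length(cr$keys) - 1)) {
    c4p <- dualamine:::residue_atom(cr$sub, cr$rows_of[[i - 1]], "C4'")
    pi_ <- dualamine:::residue_atom(cr$sub, cr$rows_of[[i]], "P")
    c4i <- dualamine:::residue_atom(cr$sub, cr$rows_of[[i]], "C4'")
    pn <- dualamine:::residue_atom(cr$sub, cr$rows_of[[i + 1]], "P")
    c4n <- dualamine:::residue_atom(cr$sub, cr$rows_of[[i + 1]], "C4'")
    expect_equal(et$eta[i], oracle_dihedral(c4p, pi_, c4i, pn) %% 360,
                 tolerance = 1e-9)
    expect_equal(et$theta[i], oracle_dihedral(pi_, c4i, pn, c4n) %% 360,
                 tolerance = 1e-9)
  }
  # random-coordinate agreement of the torsion core
  set.seed(3)
  for (rep in 1:20) {
    pts <- matrix(rnorm(12), 4, 3)
    expect_equal(dualamine:::dihedral4(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("A-form interiors fall in the A-form box; termini are undefined", {
  h <- fix_helix()
  box <- region_boxes()$aform
  for (ch in c("A", "B")) {
    et <- eta_theta(h, ch)
    n <- nrow(et)
    expect_true(all(is.na(et$eta[c(1, n)])))
    expect_identical(et$reason[1], "chain terminus")
    expect_true(all(in_region(et$eta[2:(n - 1)], et$theta[2:(n - 1)], box)))
  }
})

test_that("chain breaks make pseudotorsions undefined rather than wrong", {
  h <- fix_helix()
  keep <- !(h$chain == "A" & h$resno == 4)   # delete residue 4 of strand A
  broken <- dualamine:::new_structure(h[keep, ], "GAP")
  et <- eta_theta(broken, "A")
  expect_true(is.na(et$eta[et$resno == 3]))
  expect_identical(et$reason[et$resno == 3], "chain break")
  expect_false(is.na(et$eta[et$resno == 7]))
})

test_that("region boxes contain their reference points", {
  boxes <- region_boxes()
  expect_true(in_region(50, 160, boxes$location1))
  expect_true(in_region(300, 20, boxes$location2))
  expect_true(in_region(170, 220, boxes$aform))
  expect_false(in_region(50, 160, boxes$location2))
  expect_false(in_region(NA, 160, boxes$location1))
})

test_that("descriptor medians reproduce the burial ordering on a planted cohort", {
  # cohort with burial planted by construction: isolated base (non donor),
  # canonical pair (single), sheared GA contact (dual); density must order
  # non < single < dual and SASA the other way around
  iso_g <- dualamine:::template_residue("G")
  s_non <- atom_structure(iso_g, elety = rownames(iso_g),
                          elesy = dualamine:::guess_element(rownames(iso_g)))
  s_non$resno <- rep(1L, nrow(s_non))
  d_non <- amine_descriptors(s_non, survey_structure(s_non))
  wc <- fix_pair("wc_gc")
  d_wc <- amine_descriptors(wc, survey_structure(wc))
  ga <- fix_pair("sheared_ga")
  d_ga <- amine_descriptors(ga, survey_structure(ga))
  expect_identical(d_non$klass, "non")
  rho_non <- d_non$rho1
  rho_single <- median(d_wc$rho1[d_wc$klass == "single"])
  rho_dual <- median(d_ga$rho1[d_ga$klass == "dual"])
  expect_lt(rho_non, rho_single)
  expect_lt(rho_single, rho_dual)
  sasa_non <- d_non$sasa
  sasa_single <- median(d_wc$sasa[d_wc$klass == "single"])
  sasa_dual <- median(d_ga$sasa[d_ga$klass == "dual"])
  expect_gt(sasa_non, sasa_single)
  expect_gt(sasa_single, sasa_dual)
})
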