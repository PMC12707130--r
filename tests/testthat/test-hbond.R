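# H-bond engine: candidate search, measurement, classification, pairs.

probe_site <- function(structure) {
  pro <- protonate_amines(structure)
  pro$sites[1, , drop = FALSE]
}

test_that("candidate search honors the prescreen radius and polymer filter", {
  g <- dualamine:::template_residue("G")
  n2 <- g["N2", ]
  dir <- c(-1, -0.3, 0); dir <- dir / sqrt(sum(dir^2))
  extra <- rbind(n2 + 4.0 * dir, n2 + 4.2 * dir, n2 + 3.0 * c(0, 0, 1))
  blocks <- list(list(atoms = `rownames<-`(g, rownames(g)), chain = "A",
                      resno = 1, resid = "G"),
                 list(atoms = matrix(extra[1, ], 1, 3, dimnames = list("O4", NULL)),
                      chain = "B", resno = 1, resid = "U"),
                 list(atoms = matrix(extra[2, ], 1, 3, dimnames = list("O4", NULL)),
                      chain = "B", resno = 2, resid = "U"),
                 list(atoms = matrix(extra[3, ], 1, 3, dimnames = list("O", NULL)),
                      chain = "W", resno = 1, resid = "HOH", het = TRUE))
  s <- dualamine:::residues_to_structure(blocks, "CND")
  site <- probe_site(s)
  cand <- find_candidates(s, site)
  labs <- paste(s$resid[cand], s$elety[cand])
  expect_true("U O4" %in% labs)                       # 4.0 A in
  expect_identical(sum(labs == "U O4"), 1L)           # 4.2 A out
  expect_false(any(s$resid[cand] == "HOH"))           # water excluded
  # parent nucleobase excluded, parent sugar/phosphate retained
  expect_false(any(cand %in% which(s$resno == 1 & s$chain == "A" &
                                     s$elety %in% c("O6", "N3", "N7"))))
  own_sugar <- which(s$resno == 1 & s$chain == "A" & s$elety == "O2'")
  d_sugar <- sqrt(sum((c(s$x[own_sugar], s$y[own_sugar], s$z[own_sugar]) - n2)^2))
  if (d_sugar <= 4.1) expect_true(own_sugar %in% cand)
  expect_false(own_sugar %in%
                 find_candidates(s, site, exclude_parent_residue = TRUE))
})

test_that("measurement returns exact collinear geometry and gates on angle", {
  g <- dualamine:::template_residue("G")
  s <- atom_structure(g, elety = rownames(g),
                      elesy = dualamine:::guess_element(rownames(g)))
  s$resno <- rep(1L, nrow(s))
  site <- probe_site(s)
  co <- amine_coords(site, 1)
  acc_collinear <- co$h1 + 2.0 * (co$h1 - co$n) / sqrt(sum((co$h1 - co$n)^2))
  m <- measure_amine_acceptor(site, acc_collinear)
  expect_lt(abs(m$d[1] - 2.0), 1e-9)
  expect_lt(abs(m$alpha[1] - 180), 1e-9)
  # acceptor back along the N direction: tiny angle, never passes
  acc_back <- co$n + 0.4 * (co$n - co$h1)
  m2 <- measure_amine_acceptor(site, acc_back)
  expect_lt(m2$alpha[1], 40)
})

test_that("measured geometry is invariant under rigid-body motion", {
  set.seed(7)
  p <- make_geometry_probe(5)
  sv1 <- survey_structure(p)
  rot <- random_rotation()
  p2 <- transform_structure(p, rot, c(11.3, -4.2, 7.7))
  sv2 <- survey_structure(p2)
  expect_equal(sv1$observations$d, sv2$observations$d, tolerance = 1e-9)
  expect_equal(sv1$observations$alpha, sv2$observations$alpha, tolerance = 1e-9)
  expect_identical(sv1$records$klass, sv2$records$klass)
})

test_that("donation scenarios classify as single or dual per the definitions", {
  expected <- c("1" = "single", "3" = "single", "4" = "single",
                "5" = "dual", "7" = "dual")
  for (sc in names(expected)) {
    sv <- survey_structure(make_geometry_probe(as.integer(sc)))
    expect_identical(sv$records$klass, unname(expected[sc]), info = sc)
    expect_identical(sv$records$scenario, as.integer(sc), info = sc)
  }
})

test_that("loosening criteria never demotes a donation class", {
  rank <- c(non = 0, single = 1, dual = 2)
  base <- hbond_criteria()
  loose <- hbond_criteria(prescreen_radius = 4.5,
                          max_h_acceptor_distance = 2.9, min_nha_angle = 120)
  set.seed(21)
  for (rep in 1:6) {
    s <- random_structure()
    k1 <- survey_structure(s, criteria = base)$records
    k2 <- survey_structure(s, criteria = loose)$records
    expect_true(all(rank[k2$klass] >= rank[k1$klass]))
  }
})

test_that("classification is invariant to atom order permutation", {
  set.seed(33)
  s <- random_structure()
  r1 <- survey_structure(s)$records
  perm <- sample(nrow(s))
  s2 <- dualamine:::new_structure(s[perm, ], attr(s, "entry_id"))
  r2 <- survey_structure(s2)$records
  key <- function(r) {
    out <- r[order(r$chain, r$resno), c("klass", "scenario")]
    rownames(out) <- NULL
    out
  }
  expect_identical(key(r1), key(r2))
})

test_that("spatially indexed search equals the exhaustive all-pairs scan", {
  set.seed(55)
  for (rep in 1:10) {
    s <- random_structure(n_donors = 3, n_acceptors = 50)
    a <- survey_structure(s, use_index = TRUE)
    b <- survey_structure(s, use_index = FALSE)
    expect_identical(a$records$klass, b$records$klass)
    expect_identical(a$records$scenario, b$records$scenario)
    expect_equal(a$observations$d, b$observations$d)
  }
})

test_that("the acceptor-pair rule picks the max-angle acceptor per hydrogen", {
  sv <- survey_structure(make_geometry_probe(7))
  rec <- sv$records
  expect_identical(rec$klass, "dual")
  # brute-force oracle over the passing bonds: per H the max-alpha acceptor
  p <- sv$observations[sv$observations$passes, ]
  best <- vapply(split(p, p$h), function(q) q$acc_label[which.max(q$alpha)], "")
  expect_setequal(c(rec$acc1, rec$acc2), unname(best))
})

test_that("a duplicated best acceptor falls back to the best distinct one", {
  obs <- data.frame(
    acc_row = c(10L, 10L, 11L), acc_chain = "B", acc_resno = c(1L, 1L, 2L),
    acc_insert = "", acc_resid = "U", acc_atom = "O4",
    acc_label = c("U(O4)", "U(O4)", "A(N7)"),
    h = c(1L, 2L, 2L), d = c(2.0, 2.1, 2.2), alpha = c(160, 150, 145),
    passes = TRUE, stringsAsFactors = FALSE)
  ap <- acceptor_pair(obs)
  # 2x2 enumeration: H1 keeps row 10 (alpha 160 > 150), H2 takes row 11
  expect_setequal(ap$rows, c(10L, 11L))
  expect_false(ap$same_residue)
  expect_error(acceptor_pair(obs[1, , drop = FALSE]),
               class = "ContractViolation")
})

test_that("canonical GC detection needs both defining bonds", {
  sv <- survey_structure(fix_helix())
  gc <- detect_canonical_gc(sv)
  expect_identical(nrow(gc), 6L)   # GCGAUCGC has six GC pairs
  # displace every C O2 far away: detection must vanish
  h <- fix_helix()
  o2 <- which(h$resid == "C" & h$elety == "O2")
  h$x[o2] <- h$x[o2] + 50
  sv2 <- survey_structure(dualamine:::new_structure(h, "BRK"))
  expect_identical(nrow(detect_canonical_gc(sv2)), 0L)
  # AU-only duplex never reports GC pairs
  au <- survey_structure(make_helix("AUAU"))
  expect_identical(nrow(detect_canonical_gc(au)), 0L)
})

test_that("the geometry histogram conserves counts and honors exclusions", {
  sv <- survey_structure(fix_helix())
  m_all <- geometry_histogram(sv$observations, exclude_canonical = FALSE)
  obs <- sv$observations
  n_pairs <- length(unique(paste(obs$donor_chain, obs$donor_resno,
                                 obs$donor_insert, obs$acc_row)))
  expect_identical(sum(m_all), n_pairs)
  m_ex <- geometry_histogram(sv$observations, exclude_canonical = TRUE)
  expect_lt(sum(m_ex), sum(m_all))
  # canonical-bond geometries contribute nothing when excluded
  combo <- paste(obs$donor_base, obs$acc_resid, obs$acc_atom)
  n_excl <- length(unique(paste(obs$donor_chain, obs$donor_resno,
                                obs$acc_row)[combo %in%
                                  c("A U O4", "C G O6", "G C O2", "G C N3")]))
  expect_identical(sum(m_all) - sum(m_ex), n_excl)
  # single synthetic pair lands in its bin
  one <- obs[which(obs$passes)[1], , drop = FALSE]
  m1 <- geometry_histogram(one, exclude_canonical = FALSE)
  expect_identical(sum(m1), 1L)
})

test_that("criteria constructor rejects inconsistent settings", {
  expect_error(hbond_criteria(prescreen_radius = 3.0),
               class = "ContractViolation")
  expect_error(hbond_criteria(min_nha_angle = -5), class = "ContractViolation")
})
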