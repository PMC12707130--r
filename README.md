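# dualamine

Structured RNAs are held together by hydrogen bonds, yet the four
ribonucleotides offer far more H-bond acceptors (62 lone pairs) than donors
(12 polar hydrogens). The exocyclic amine — N6 of adenine, N4 of cytosine,
N2 of guanine — is the only RNA group that can donate **two** hydrogen
bonds at once. `dualamine` mines RNA-containing 3D structures for these
*dual-donating* amines and characterizes their structural context.

The workflow:

1. **Protonation.** Deposited structures usually lack hydrogens, so two
   amine hydrogens are placed analytically per A/C/G: in the base plane,
   N–H = 1.01 Å, H–N–H = 120°, sp2 geometry. Residues with missing anchor
   atoms are excluded and logged.
2. **H-bond calling.** Candidate acceptors are polymer O/N atoms from a
   curated chemistry dictionary within 4.1 Å of the amine nitrogen
   (excluding the parent nucleobase). A contact is an H-bond when the
   H···acceptor distance is ≤ 2.5 Å and the N–H···acceptor angle is ≥ 140°.
3. **Classification.** Each amine is *non-*, *single-*, or *dual-donating*.
   Dual donation requires passing bonds from **both** hydrogens to at least
   two distinct acceptor atoms; bifurcated or trifurcated bonds carried by
   a single hydrogen count as single donation. For dual donors the acceptor
   pair is tabulated (per hydrogen, the acceptor with the greatest angle),
   with OP1/OP2 merged into the generalized label `N(NPO)` and backbone
   atoms generalized to `N(...)`/`AA(O)`.
4. **Descriptors.** Per-amine burial and conformation: Shrake–Rupley
   solvent-accessible surface area of the amine nitrogen (probe 1.40 Å,
   100 sphere points), heavy-atom densities in two regions of interest
   (r ≤ 7.5 Å and 7.5–12.5 Å shells, atoms/nm³), the glycosidic χ dihedral
   (syn window (−90°, 90°)), and the η/θ backbone pseudotorsions
   (C4′(i−1)–P(i)–C4′(i)–P(i+1) and P(i)–C4′(i)–P(i+1)–C4′(i+1)).
5. **Motif discovery.** 6 × 5-nucleotide fragments around residues of
   interest are coarse-grained to five atoms per nucleotide, compared by
   least-squares superposition RMSD (proper rotations only), clustered
   hierarchically with a cutoff scan scored by Silhouette /
   Calinski–Harabasz / Davies–Bouldin, and summarized by a representative
   member per cluster.
6. **Statistics.** Pairwise Wilcoxon rank-sum tests with
   Benjamini–Hochberg FDR control for linear descriptors; Watson's
   two-sample U² for circular χ data (bracketed p-ranges, with a
   permutation mode).

A deterministic synthetic-structure generator ships with the package:
idealized A-form duplexes built from frozen templates, exact-geometry
donor–acceptor probes for all donation scenarios, sheared GA and *trans*
AA Hoogsteen pairs, and planted fragment sets for clustering validation.

## Worked example

```r
library(dualamine)

ga <- make_pair("sheared_ga")        # A amine dual-donates to one G
sv <- survey_structure(ga)
sv$records[, c("base", "klass", "scenario", "acc1", "acc2", "same_residue")]
#>   base klass scenario   acc1    acc2 same_residue
#> 1    G   non       NA   <NA>    <NA>           NA
#> 2    A  dual        5  G(N3) N(O2')         TRUE
```

The A(N6) amine is dual-donating (scenario 5: one bond per hydrogen) to
the N3 and the 2′-hydroxyl oxygen of the same G — the signature of a
sheared GA pair. On an idealized duplex the canonical-pair detector and
the pseudotorsion analysis behave as expected:

```r
h <- make_helix("GCGAUCGC")
nrow(detect_canonical_gc(survey_structure(h)))   # 6 GC pairs
et <- eta_theta(h, "A")
round(c(median(et$eta, na.rm = TRUE), median(et$theta, na.rm = TRUE)), 1)
#> 167.9 212.0        (inside the A-form box 145-190 / 190-245)
```

A command-line driver for generating fixtures and running surveys is
installed under `inst/cli/dualamine.R`.

## Chemistry dictionary

The donor/acceptor tables live in
`inst/extdata/chemistry/residue_chemistry.tsv` (one record per residue ×
atom: donors with polar-H counts, acceptors with lone-pair counts, amine
definitions with the anchor atoms used for hydrogen placement). Counting
conventions: internal chain residues with a 5′-phosphate, six backbone or
sugar oxygens per ribonucleotide, no terminal hydroxyl protons; oxygens
carry two lone pairs, unprotonated ring nitrogens one; the amine nitrogen
never accepts. The idealized A-form residue templates used by the
generator are in `inst/extdata/ideal_aform/` (synthetic, derived
geometrically; see the methods vignette).
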