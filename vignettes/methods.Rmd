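---
title: "Methods: classifying dual-donating amines and their structural context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying dual-donating amines and their structural context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualamine)
```

## The model

RNA nucleotides carry roughly five times as many H-bond acceptor lone
pairs as donatable polar hydrogens (62 vs 12 over A, C, G, U, counted as
internal chain residues). The exocyclic amine is the only group that can
donate two H-bonds, so amines that actually use both hydrogens — *dual
donors* — are a chemically privileged minority worth mapping.

An amine–acceptor contact is called an H-bond from two geometric
quantities: the hydrogen–acceptor distance `d` and the angle `α` at the
hydrogen between the amine nitrogen, the hydrogen, and the acceptor. The
defaults, `d ≤ 2.5 Å` and `α ≥ 140°`, sit at the edge of the dense
population seen in distance–angle heat maps of amine contacts in
experimental structures; both are exposed in `hbond_criteria()` because
the dual-donor census is sensitive to them (looser criteria find more
dual donors). Candidates are restricted to polymer O/N atoms with free
lone pairs within 4.1 Å of the amine nitrogen — the prescreen must cover
`d_max` plus the N–H bond length, and 4.1 Å = 2.5 + 1.01 with margin.

Classification follows the donation-scenario taxonomy:

* **non** — no passing bond;
* **single** — passing bonds, but either a single hydrogen carries all of
  them (bi-/trifurcation, scenarios 3/4) or all bonds share one acceptor
  (scenario 2), or there is just one bond (scenario 1);
* **dual** — both hydrogens carry passing bonds to ≥ 2 distinct acceptor
  atoms (scenario 5; scenario 7 when one hydrogen is additionally
  bifurcated; scenario 6 when the hydrogens also share an acceptor).

Scenarios 2 and 6 require one acceptor to satisfy `α ≥ 140°` against both
hydrogens of a 120° amine simultaneously; a numerical search over
acceptor positions shows the best achievable paired angle is ≈ 120°, so
these layouts are unconstructible under the defaults. The fixture
generator proves this constructively: `make_geometry_probe(2)` solves for
the optimal shared acceptor and raises `InfeasibleScenario`; with a
permissive threshold (e.g. 90°) the same layout is built and classifies
as scenario 2/6.

For a dual donor the *acceptor pair* takes, per hydrogen, the passing
acceptor with the greatest angle. When both hydrogens elect the same
atom, the hydrogen with the larger angle keeps it and the other falls
back to its best distinct acceptor — the literal per-hydrogen rule can
collide with the two-acceptor definition of dual donation, and the
fallback preserves it. Pairs are ordered canonically by label so counts
aggregate deterministically.

## Hydrogen placement

Deposited structures are stripped of any hydrogens and re-protonated
analytically: both amine hydrogens in the base plane, N–H = 1.01 Å,
H–N–H = 120°, symmetric about the extended C→N direction (A: N6 on C6
with N1/C5 as plane references; C: N4 on C4 with N3/C5; G: N2 on C2 with
N1/N3). Placement is deterministic — identical coordinates give
bit-identical hydrogens — and residues with missing anchors or a covalent
modification at the nitrogen (a foreign heavy atom within 1.2 Å) are
excluded with a logged reason. The bond length and angle are arguments,
not constants, and downstream geometry checks tolerate small placement
differences.

## Structure handling

mmCIF and PDB files are parsed through `bio3d`; one model is retained
(the requested model, default the first) and one alternate location per
atom site. The altloc policy is highest occupancy with ties broken by
altloc character — the choice is not dictated by the science, so it is
recorded and deterministic. Only the asymmetric unit is considered; no
symmetry expansion. Donors are the amines of A/C/G residues in the
target (IFE) chains; acceptors may come from any polymer chain — RNA,
DNA, or protein. The parent residue contributes no base-moiety acceptors,
but its own sugar/phosphate atoms remain eligible (a toggle drops the
whole residue for sensitivity analysis).

## Burial and conformation descriptors

* **SASA** — Shrake–Rupley sphere sampling with probe 1.40 Å and a
  deterministic 100-point Fibonacci lattice per atom; van der Waals radii
  N 1.55, O 1.52, C 1.70, P 1.80, S 1.80 (fallback 1.70). An isolated
  nitrogen reproduces the closed form `4π(1.55 + 1.40)²` and a fully
  enclosed one returns exactly 0.
* **Shell densities** — heavy polymer atoms within r ≤ 7.5 Å (the
  footprint of a base triple) and in the 7.5–12.5 Å shell, divided by the
  shell volumes in nm³. Boundaries are closed on the outer edge (≤), and
  the central nitrogen counts in the inner region; an isolated nitrogen
  gives ρ₁ = 1/1.7671 nm⁻³.
* **χ** — O4′–C1′–N9–C4 (purines) / O4′–C1′–N1–C2 (pyrimidines) in
  (−180°, 180°]; syn means χ ∈ (−90°, 90°). A separate *minor-population*
  flag uses the display window (−20°, 130°); the window is adopted as the
  population definition since the alternative (histogram valleys) is not
  reproducible from a rule.
* **η/θ** — pseudotorsions C4′(i−1)–P(i)–C4′(i)–P(i+1) and
  P(i)–C4′(i)–P(i+1)–C4′(i+1) mapped to [0°, 360°). Termini and chain
  breaks are explicitly undefined (`NA` with a reason), never zero. A
  chain break is a consecutive-residue O3′–P distance above 2.5 Å —
  generous against coordinate error yet far below the ~1.6 Å bond.

Three inclusive (η, θ) boxes matter downstream: the A-form region
145–190°/190–245° (the printed inequalities contain an obvious
typo — the ranges are implemented as stated bounds, lower ≤ value ≤
upper), and the two dual-donor-enriched regions Location 1
(43–72°/151–180°) and Location 2 (295–324°/14–43°).

## Fragment clustering

Around a residue of interest a 6 × 5-nucleotide fragment is cut: the
residue at position 3 of 6 on its own strand (two upstream, three
downstream — the asymmetry reflects the S-motif geometry that motivated
the window; offsets are configurable) and its pairing partner ± 2 on the
second strand. Each nucleotide is coarse-grained to five atoms (purines
P, C4′, N9, C2, C6; pyrimidines P, C4′, N1, C2, C4) so fragments of any
sequence carry 55 comparable points; incomplete fragments are rejected,
never padded. The pairing partner is taken as the residue owning the
dual-accepted atoms.

Pairwise distances are least-squares superposition RMSDs with a
determinant-guarded Kabsch solve — proper rotations only, so chirality
differences cannot be absorbed by a reflection. Agglomerative clustering
uses average linkage (a precomputed-distance-compatible choice; the
linkage is configurable because no single method is canonical).
Cutoffs are scanned on a 0.05 Å grid from the smallest height at which a
cluster of ≥ 4 members forms up to the integer below the maximum
distance. Three validation metrics are computed per cutoff; the chosen
cutoff maximizes the mean Silhouette width. Silhouette comes from the
`cluster` package directly on the distance matrix. Calinski–Harabasz and
Davies–Bouldin are evaluated in distance form using the Euclidean
identities `WSS_k = Σ_{i<j∈k} d²_ij / n_k` and
`‖c_i − c_j‖² = mean d²(between) − WSS_i/n_i − WSS_j/n_j`, which equal
the coordinate formulas whenever the distances embed in Euclidean space
(verified against the textbook forms in the tests); the Davies–Bouldin
dispersion uses the RMS distance to the centroid. Cluster
representatives are found by superposing all members onto the cluster
medoid, averaging coordinates, and returning the member with the
smallest RMSD to that average.

## Statistics

SASA and density distributions are compared by pairwise two-sided
Wilcoxon rank-sum tests (`stats::wilcox.test`: exact enumeration for
small tie-free samples, normal approximation with tie correction
otherwise) with Benjamini–Hochberg adjustment within one family per
figure-panel analogue. BH is the adopted FDR procedure — the choice is
labeled since other FDR controls exist.

Circular χ samples are compared with Watson's two-sample U², a
rotation-invariant Cramér–von Mises-type statistic. The test natively
yields p-value *ranges* bracketed by the standard asymptotic critical
values (0.152, 0.187, 0.268, 0.385 at α = 0.10, 0.05, 0.01, 0.001), so no
FDR adjustment is applied to it; a permutation mode provides point
p-values and serves as the oracle in tests. Samples below eight
observations per group fall back to permutation with a warning. Null
calibration (2000 replicates) puts both tests' rejection rates at
nominal 0.05 within binomial error.

## The synthetic-structure generator

No installed tool builds nucleic-acid helices, so the package carries its
own idealized templates (`inst/extdata/ideal_aform/`, plain text,
synthetic by construction):

* planar base atoms in standard reference frames, in which a Watson–Crick
  partner is generated by a 180° flip about the x axis (giving
  heavy-atom H-bond distances of 2.87–3.02 Å without any fitting);
* one rigid C3′-endo ribose + 5′-phosphate block (pseudorotation phase
  15°, amplitude 38°) docked at the glycosidic bond, with the spin about
  that bond, the γ/β backbone torsions, and the helical frame offsets
  solved once so the backbone closes (O3′(i)–P(i+1) = 1.607 Å, A-form-like
  α/ε/ζ) under helical symmetry twist 32.7°, rise 2.81 Å.

Assembled duplexes come out with χ ≈ −167° (anti), interior η/θ ≈
(168°, 212°) — inside the A-form box — and canonical GC pairs that pass
both defining bonds, none of which is asserted by construction: they are
emergent checks on the template. Geometry probes place single-atom
acceptors at exact (d, α) targets in closed form. The sheared GA and
*trans* AA Hoogsteen fixtures place a mobile A by a deterministic
multi-start rigid-body fit so its two amine hydrogens hit the named
acceptor atoms (G N3/O2′, or A N7/OP1) with passing geometry and no
steric clash. Planted fragment sets hinge-rotate the partner strand of
the duplex fragment about two fixed axes, guaranteeing pairwise template
RMSDs above 8 Å for up to three conformations, then add isotropic
Gaussian noise (default σ = 0.3 Å) under a caller-supplied seed; the
same seed reproduces the set bit-for-bit.

What the generator does **not** emulate: thermal/crystallographic
coordinate error beyond isotropic noise, modified nucleotides, sugar
pucker heterogeneity, multi-model ensembles, solvent, and the sequence
and motif diversity of real structures. Passing tests therefore
demonstrate that the measurement and classification machinery is correct
on known geometry — not that survey fractions measured on these fixtures
generalize to the PDB. Survey-scale census numbers require running
`run_survey()` over a representative-set listing with downloaded
entries, which is out of scope for the test suite.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run on deliberately small
instances: duplexes of 4–8 base pairs, geometry probes of ≤ 25 atoms,
random equivalence structures of ≤ 500 atoms (50 replicates), planted
fragment sets of 8 members per conformation, and 2000-replicate null
calibrations. These sizes give stable, discriminating checks for every
code path; the algorithms themselves are linear-ish in atoms (cell-list
neighbor search) and scale to ribosome-sized entries.

## Known limitations

* Donors are restricted to the A/C/G amines of the target RNA chains;
  DNA amines are not protonated (their acceptor chemistry is in the
  dictionary, so DNA can accept).
* Modified residues are skipped as donors; their atoms can optionally be
  treated as generic acceptors (`chem_options(generic_acceptors =)`),
  off by default to match the canonical-residue scope.
* Multi-model mmCIF files are read through `bio3d`, which exposes the
  first model only; multi-model selection is supported for PDB input.
* The planted fragment generator guarantees ≥ 8 Å separation for at most
  three conformations.
* Watson's U² p-ranges rely on asymptotic critical values; for small
  samples use the permutation mode.
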