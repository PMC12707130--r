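Package: dualamine
Title: Dual-Donating Exocyclic Amines in RNA 3D Structures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines RNA-containing 3D structures for exocyclic amines that
    donate two hydrogen bonds. Places idealized amine hydrogens on A, C,
    and G residues, calls hydrogen bonds from geometric distance and angle
    criteria, classifies amines as non-, single-, or dual-donating with
    explicit handling of bifurcated and trifurcated bonds, and tabulates
    the acceptor-atom pairs engaged by dual donors. Per-amine burial and
    conformation descriptors cover Shrake-Rupley solvent-accessible
    surface area, heavy-atom shell densities, the glycosidic chi dihedral,
    and the eta/theta backbone pseudotorsions. Coarse-grained fragments
    around residues of interest can be clustered by superposition RMSD
    with a validation-metric cutoff scan to discover recurring motifs.
    Includes rank-sum and circular homogeneity statistics, a deterministic
    synthetic-structure generator for idealized A-form duplexes and
    noncanonical base pairs, and a survey driver over representative-set
    listings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
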