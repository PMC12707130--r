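# Residue chemistry dictionary: hydrogen-bond donors, acceptors with
# lone-pair counts, and exocyclic amine definitions for canonical
# ribonucleotides, deoxyribonucleotides, and the standard amino acids.
#
# The tables ship as a versioned, human-readable TSV under
# inst/extdata/chemistry/ and are loaded once per session. Conventions:
#  * every oxygen acceptor carries two lone pairs, every unprotonated ring
#    nitrogen one;
#  * the exocyclic amine nitrogen (A N6, C N4, G N2) donates two H-bonds
#    and never accepts (its lone pair is delocalized into the ring);
#  * capacity counting treats a residue as internal in a chain bearing a
#    5'-phosphate: six backbone/sugar oxygens per ribonucleotide (OP1, OP2,
#    O5', O4', O3', O2') and no terminal hydroxyl protons.

.dualamine <- new.env(parent = emptyenv())

chem_table <- function() {
  if (is.null(.dualamine$chem)) {
    path <- system.file("extdata", "chemistry", "residue_chemistry.tsv",
                        package = "dualamine")
    if (path == "") { # in-tree fallback for development loads
      path <- file.path("inst", "extdata", "chemistry", "residue_chemistry.tsv")
    }
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, quote = "")
    .dualamine$chem <- tab
  }
  .dualamine$chem
}

# atom names that belong to the base moiety (vs sugar/phosphate backbone)
BASE_MOIETY_ATOMS <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9",
                       "O2", "O4", "O6", "N2", "N4", "N6", "C7")

NUCLEOTIDE_BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                               "C3'", "O3'", "C2'", "O2'", "C1'")

#' Chemistry options
#'
#' @param include_aa_side_chains include amino-acid side-chain O and
#'   unprotonated N atoms as acceptors (standard chemistry; the backbone
#'   carbonyl O is always included).
#' @param generic_acceptors treat O/N atoms of residues absent from the
#'   dictionary as generic acceptors. Off by default: the survey is defined
#'   over canonical residues.
#' @return A list of options consumed by the H-bond engine.
#' @export
chem_options <- function(include_aa_side_chains = TRUE,
                         generic_acceptors = FALSE) {
  list(include_aa_side_chains = isTRUE(include_aa_side_chains),
       generic_acceptors = isTRUE(generic_acceptors))
}

#' Residue chemistry lookup
#'
#' Returns the dictionary entry for one residue: its donors (heavy atom and
#' polar-H count), acceptors (atom and lone-pair count), and, for A, C, and
#' G, the exocyclic amine definition (nitrogen plus the anchor atoms used to
#' place its two hydrogens in the base plane).
#'
#' @param residue_name residue code ("A", "C", "G", "U", "DA", ..., "ALA", ...).
#' @return A list with elements `residue`, `polymer`, `donors` (data frame
#'   atom/n_h), `acceptors` (data frame atom/lone_pairs/side_chain), and
#'   `amine` (list with `n`, `anchor`, `ref1`, `ref2`, or `NULL`).
#' @export
get_chemistry <- function(residue_name) {
  tab <- chem_table()
  rows <- tab[tab$residue == residue_name, ]
  if (nrow(rows) == 0) {
    abort_class("UnknownResidue",
                sprintf("residue '%s' is not in the chemistry dictionary",
                        residue_name))
  }
  don <- rows[rows$record %in% c("donor", "sidechain_donor"), ]
  acc <- rows[rows$record %in% c("acceptor", "sidechain_acceptor"), ]
  amine <- NULL
  am <- rows[rows$record == "amine", ]
  if (nrow(am) == 1) {
    anchors <- strsplit(am$value, "|", fixed = TRUE)[[1]]
    amine <- list(n = am$atom, anchor = anchors[1],
                  ref1 = anchors[2], ref2 = anchors[3])
  }
  list(residue = residue_name,
       polymer = rows$polymer[1],
       donors = data.frame(atom = don$atom, n_h = as.integer(don$value),
                           side_chain = don$record == "sidechain_donor",
                           stringsAsFactors = FALSE),
       acceptors = data.frame(atom = acc$atom,
                              lone_pairs = as.integer(acc$value),
                              side_chain = acc$record == "sidechain_acceptor",
                              stringsAsFactors = FALSE),
       amine = amine)
}

#' Hydrogen-bonding capacity of a residue set
#'
#' Sums acceptor lone pairs and donatable polar hydrogens over a set of
#' residues, counted as internal chain residues (six backbone/sugar oxygens
#' per ribonucleotide, 5'-phosphate with both nonbridging oxygens, no
#' terminal hydroxyl protons). Over the four canonical ribonucleotides this
#' yields 62 lone pairs against 12 polar hydrogens.
#'
#' @param residue_names character vector of residue codes.
#' @param context "internal" (default) counts the full internal-chain
#'   backbone; "base_only" restricts to base-moiety atoms.
#' @return Named integer vector `c(lone_pairs, polar_h)`.
#' @export
hbond_capacity <- function(residue_names, context = c("internal", "base_only")) {
  context <- match.arg(context)
  lp <- 0L
  ph <- 0L
  for (r in residue_names) {
    chem <- get_chemistry(r)
    acc <- chem$acceptors
    don <- chem$donors
    if (context == "base_only") {
      acc <- acc[acc$atom %in% BASE_MOIETY_ATOMS, ]
      don <- don[don$atom %in% BASE_MOIETY_ATOMS, ]
    }
    lp <- lp + sum(acc$lone_pairs)
    ph <- ph + sum(don$n_h)
  }
  c(lone_pairs = as.integer(lp), polar_h = as.integer(ph))
}

#' Generalized acceptor label
#'
#' Maps an acceptor atom to the label used for acceptor-pair tabulation:
#' nonbridging phosphoryl oxygens OP1/OP2 merge to "N(NPO)", other
#' nucleotide backbone atoms become "N(atom)", the peptide backbone carbonyl
#' becomes "AA(O)", amino-acid side-chain acceptors keep their residue code,
#' and base atoms keep their one-letter base identity.
#'
#' @param residue_name residue code of the acceptor's parent residue.
#' @param atom_name acceptor atom name.
#' @return A single label string, e.g. "G(N3)", "N(O2')", "AA(O)".
#' @export
generalize_acceptor <- function(residue_name, atom_name) {
  chem <- get_chemistry(residue_name)
  hit <- chem$acceptors[chem$acceptors$atom == atom_name, ]
  if (nrow(hit) == 0) {
    abort_class("NotAnAcceptor",
                sprintf("%s %s is not an acceptor", residue_name, atom_name))
  }
  if (chem$polymer %in% c("rna", "dna")) {
    if (atom_name %in% c("OP1", "OP2")) return("N(NPO)")
    if (atom_name %in% NUCLEOTIDE_BACKBONE_ATOMS) {
      return(sprintf("N(%s)", atom_name))
    }
    base_letter <- sub("^D", "", residue_name)
    return(sprintf("%s(%s)", base_letter, atom_name))
  }
  # protein
  if (!hit$side_chain) return(sprintf("AA(%s)", atom_name))
  sprintf("%s(%s)", residue_name, atom_name)
}

# Vectorized acceptor-table lookup used by the H-bond engine. Returns
# lone-pair counts (NA when not an acceptor under the given options).
acceptor_lone_pairs <- function(resids, atoms, options = chem_options()) {
  tab <- chem_table()
  acc <- tab[tab$record %in% c("acceptor",
                               if (options$include_aa_side_chains)
                                 "sidechain_acceptor"), ]
  key <- paste(acc$residue, acc$atom)
  lp <- as.integer(acc$value)[match(paste(resids, atoms), key)]
  if (options$generic_acceptors) {
    known_res <- resids %in% unique(tab$residue)
    generic <- !known_res & grepl("^[NO]", atoms)
    lp[is.na(lp) & generic] <- 1L
  }
  lp
}
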