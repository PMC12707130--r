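# Structure input/output. Structures are plain data frames (class
# "dualamine_structure") with one row per atom site after model and altloc
# normalization; columns follow the bio3d naming where possible so the two
# representations interconvert cheaply.

STRUCTURE_COLS <- c("eleno", "elety", "alt", "resid", "chain", "resno",
                    "insert", "x", "y", "z", "o", "elesy", "is_polymer",
                    "model")

new_structure <- function(df, entry_id = "XXXX") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(STRUCTURE_COLS, names(df))
  if (length(missing) > 0) {
    abort_class("ParseError",
                paste("structure missing columns:", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))) {
    abort_class("ParseError", "non-finite coordinates")
  }
  rownames(df) <- NULL
  attr(df, "entry_id") <- entry_id
  class(df) <- c("dualamine_structure", "data.frame")
  df
}

#' Atom coordinates as a matrix
#' @param structure a structure data frame.
#' @return n x 3 numeric matrix.
#' @export
structure_xyz <- function(structure) {
  cbind(structure$x, structure$y, structure$z)
}

residue_key <- function(structure) {
  paste(structure$chain, structure$resno, structure$insert, sep = "|")
}

guess_element <- function(elety) {
  e <- toupper(substr(gsub("[^A-Za-z].*$", "", elety), 1, 1))
  e[e == ""] <- "C"
  e
}

#' Read an mmCIF or PDB structure
#'
#' Parses a structure file (format chosen from the extension, or forced via
#' `format`), keeps a single model and one alternate location per atom site,
#' and flags polymer atoms (ATOM records) against heteroatoms.
#'
#' @param source path to a `.pdb` or `.cif` file.
#' @param format "auto", "pdb" or "cif".
#' @param model model number to retain (default 1, the first).
#' @param altloc_policy "occupancy" keeps the highest-occupancy alternate
#'   (ties broken by altloc character order); "first" keeps the first seen.
#' @param entry_id entry identifier recorded on the result; defaults to the
#'   file base name.
#' @return A structure data frame with one row per atom.
#' @export
read_structure <- function(source, format = c("auto", "pdb", "cif"),
                           model = 1, altloc_policy = c("occupancy", "first"),
                           entry_id = NULL) {
  format <- match.arg(format)
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(source)) abort_class("ParseError", paste("no such file:", source))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(source))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (is.null(entry_id)) {
    entry_id <- toupper(sub("\\.(pdb|cif|mmcif)$", "",
                            basename(source), ignore.case = TRUE))
  }
  pdb <- tryCatch(
    suppressMessages(suppressWarnings(
      if (format == "pdb") bio3d::read.pdb(source, multi = TRUE,
                                           rm.alt = FALSE, verbose = FALSE)
      else bio3d::read.cif(source, rm.alt = FALSE, verbose = FALSE)
    )),
    error = function(e) abort_class("ParseError", conditionMessage(e)))
  at <- pdb$atom
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  if (model > n_models) {
    abort_class("ModelNotFound",
                sprintf("model %d requested; file has %d", model, n_models))
  }
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  # read.cif keeps CIF quoting on names like "O2'"; strip paired quotes only
  elety <- gsub("^\"(.*)\"$", "\\1", at$elety)
  elety <- gsub("^'(.*)'$", "\\1", elety)
  elesy <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                          guess_element(elety), at$elesy))
  df <- data.frame(
    eleno = at$eleno,
    elety = elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    resid = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = ifelse(is.na(at$o), 1, at$o),
    elesy = elesy,
    is_polymer = at$type == "ATOM",
    model = model,
    stringsAsFactors = FALSE)
  df <- resolve_altlocs(df, altloc_policy)
  new_structure(df, entry_id)
}

# one altloc per atom site: highest occupancy, ties by altloc character
resolve_altlocs <- function(df, policy) {
  site <- paste(df$chain, df$resno, df$insert, df$resid, df$elety)
  if (!anyDuplicated(site)) return(df)
  keep <- logical(nrow(df))
  for (idx in split(seq_len(nrow(df)), site)) {
    if (length(idx) == 1) { keep[idx] <- TRUE; next }
    if (policy == "first") { keep[idx[1]] <- TRUE; next }
    o <- df$o[idx]
    best <- idx[o == max(o)]
    keep[best[order(df$alt[best])][1]] <- TRUE
  }
  df[keep, , drop = FALSE]
}

#' Remove hydrogen atoms
#'
#' Drops all H (and D) atoms; heavy atoms are untouched. Idempotent.
#'
#' @param structure a structure data frame.
#' @return The structure without hydrogens.
#' @export
strip_hydrogens <- function(structure) {
  out <- structure[!(structure$elesy %in% c("H", "D")), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "entry_id") <- attr(structure, "entry_id")
  class(out) <- class(structure)
  out
}

#' Write a structure to PDB or mmCIF
#'
#' PDB output goes through bio3d; mmCIF output writes a minimal atom_site
#' loop (sufficient for round-tripping the generator's fixtures).
#' Coordinates are written at 3-decimal precision in both dialects.
#'
#' @param structure a structure data frame.
#' @param path output path; format chosen from the extension unless forced.
#' @param format "auto", "pdb" or "cif".
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  s <- structure
  if (format == "pdb") {
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(structure_xyz(s))),
                     type = ifelse(s$is_polymer, "ATOM", "HETATM"),
                     resno = s$resno, resid = s$resid,
                     eleno = seq_len(nrow(s)), elety = s$elety,
                     chain = s$chain, insert = ifelse(s$insert == "", NA, s$insert),
                     alt = ifelse(s$alt == "", NA, s$alt),
                     o = s$o, b = rep(0, nrow(s)), elesy = s$elesy)
  } else {
    quo <- function(x) ifelse(grepl("'", x), sprintf("\"%s\"", x), x)
    lines <- c(
      sprintf("data_%s", attr(s, "entry_id") %||% "XXXX"),
      "#", "loop_",
      paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                              "label_atom_id", "label_alt_id", "label_comp_id",
                              "label_asym_id", "label_entity_id", "label_seq_id",
                              "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                              "Cartn_z", "occupancy", "B_iso_or_equiv",
                              "pdbx_formal_charge", "auth_seq_id",
                              "auth_comp_id", "auth_asym_id", "auth_atom_id",
                              "pdbx_PDB_model_num")),
      sprintf("%s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s %d",
              ifelse(s$is_polymer, "ATOM", "HETATM"), seq_len(nrow(s)),
              s$elesy, quo(s$elety),
              ifelse(s$alt == "", ".", s$alt), s$resid, s$chain, s$resno,
              ifelse(s$insert == "", "?", s$insert),
              s$x, s$y, s$z, s$o, s$resno, s$resid, s$chain, quo(s$elety),
              s$model),
      "#")
    writeLines(lines, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a representative-set listing
#'
#' Reads a CSV in the nonredundant-list dialect: each row carries an
#' integrated functional element (IFE) as `PDBID|model|chain` tokens joined
#' by `+` for multi-chain IFEs. When the file has several columns the
#' second holds the representative IFE, otherwise the first is used.
#'
#' @param path CSV path.
#' @return A data frame with one row per IFE: `entry_id`, `model`, and a
#'   list-column `chains` (chain order preserved).
#' @export
parse_representative_set <- function(path) {
  if (!file.exists(path)) abort_class("ParseError", paste("no such file:", path))
  raw <- tryCatch(utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    return(data.frame(entry_id = character(), model = integer(),
                      ife = character(),
                      chains = I(list()), stringsAsFactors = FALSE))
  }
  col <- if (ncol(raw) >= 2) 2 else 1
  tokens <- as.character(raw[[col]])
  out <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    parts <- strsplit(strsplit(tokens[i], "+", fixed = TRUE)[[1]], "|", fixed = TRUE)
    ok <- all(vapply(parts, length, 1L) == 3)
    if (!ok || length(parts) == 0) {
      abort_class("ParseError", sprintf("malformed IFE token in row %d: '%s'",
                                        i, tokens[i]))
    }
    entry <- unique(vapply(parts, `[[`, "", 1))
    model <- unique(vapply(parts, `[[`, "", 2))
    if (length(entry) != 1 || length(model) != 1 ||
        is.na(suppressWarnings(as.integer(model[1])))) {
      abort_class("ParseError", sprintf("inconsistent IFE token in row %d: '%s'",
                                        i, tokens[i]))
    }
    out[[i]] <- list(entry_id = entry, model = as.integer(model),
                     chains = vapply(parts, `[[`, "", 3))
  }
  data.frame(entry_id = vapply(out, `[[`, "", "entry_id"),
             model = vapply(out, function(x) x$model, 1L),
             ife = tokens,
             chains = I(lapply(out, `[[`, "chains")),
             stringsAsFactors = FALSE)
}
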