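# Chemical-environment annotation of residues and heavy atoms.
#
# Node types are not bare elements: one element maps to several classes
# depending on its local chemical environment (backbone carbonyl oxygen
# vs hydroxyl oxygen, aliphatic vs aromatic carbon, ...), following
# ff19SB-style force-field groupings. The shipped scheme is a documented
# reconstruction constrained to exactly 21 residue classes, 31 heavy-atom
# classes and 20 hydrogen classes; alternative tables can be loaded from
# TSV.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# heavy atoms per standard residue (PDB v3 names)
AA_HEAVY_ATOMS <- list(
  ALA = c("N", "CA", "C", "O", "CB"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  CYS = c("N", "CA", "C", "O", "CB", "SG"),
  GLN = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
  GLY = c("N", "CA", "C", "O"),
  HIS = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
  LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  MET = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
  PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("N", "CA", "C", "O", "CB", "CG", "CD"),
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  THR = c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
  TRP = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2",
          "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
          "CZ", "OH"),
  VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2"))

HEAVY_CLASSES <- c(
  "C_ALPHA", "C_CARBONYL", "C_BETA", "C_SP3", "C_AROMATIC",
  "C_AROM_HYDROXYL", "C_IMIDAZOLE_CE1", "C_CARBOXYLATE", "C_AMIDE",
  "C_GUANIDINO", "C_INDOLE_BRIDGE",
  "N_BACKBONE", "N_AMIDE", "N_IMIDAZOLE", "N_INDOLE", "N_AMINE",
  "N_GUANIDINO_NE", "N_GUANIDINO_NH", "N_PROLINE",
  "O_CARBONYL", "O_CARBOXYLATE", "O_AMIDE", "O_HYDROXYL", "O_PHENOL",
  "S_THIOL", "S_THIOETHER",
  "C_OTHER", "N_OTHER", "O_OTHER", "S_OTHER", "X_OTHER")

HYDROGEN_CLASSES <- c(
  "H_BACKBONE_N", "H_ALPHA", "H_BETA", "H_SP3", "H_AROMATIC",
  "H_HYDROXYL", "H_PHENOL", "H_THIOL", "H_AMIDE", "H_AMINE",
  "H_GUANIDINO", "H_IMIDAZOLE", "H_INDOLE", "H_N_TERMINUS", "H_GAMMA",
  "H_DELTA", "H_EPSILON", "H_ZETA", "H_WATER", "H_OTHER")

# chemical-environment class for one (residue, heavy atom) pair
.heavy_class <- function(res, atom) {
  if (atom == "CA") return("C_ALPHA")
  if (atom == "C") return("C_CARBONYL")
  if (atom == "O") return("O_CARBONYL")
  if (atom == "OXT") return("O_CARBOXYLATE")
  if (atom == "N") return(if (res == "PRO") "N_PROLINE" else "N_BACKBONE")
  if (atom == "CB") return("C_BETA")
  el <- substr(atom, 1L, 1L)
  if (el == "S") return(if (res == "CYS") "S_THIOL" else "S_THIOETHER")
  if (el == "O") {
    if (res %in% c("ASP", "GLU")) return("O_CARBOXYLATE")
    if (res %in% c("ASN", "GLN")) return("O_AMIDE")
    if (res == "TYR") return("O_PHENOL")
    return("O_HYDROXYL")                     # SER OG, THR OG1
  }
  if (el == "N") {
    if (res %in% c("ASN", "GLN")) return("N_AMIDE")
    if (res == "HIS") return("N_IMIDAZOLE")
    if (res == "TRP") return("N_INDOLE")
    if (res == "LYS") return("N_AMINE")
    if (res == "ARG") return(if (atom == "NE") "N_GUANIDINO_NE" else "N_GUANIDINO_NH")
    return("N_OTHER")
  }
  # remaining carbons
  if (res %in% c("PHE", "TYR", "TRP", "HIS")) {
    if (res == "TYR" && atom == "CZ") return("C_AROM_HYDROXYL")
    if (res == "HIS" && atom == "CE1") return("C_IMIDAZOLE_CE1")
    if (res == "TRP" && atom %in% c("CD2", "CE2")) return("C_INDOLE_BRIDGE")
    return("C_AROMATIC")
  }
  if (res == "ASP" && atom == "CG") return("C_CARBOXYLATE")
  if (res == "GLU" && atom == "CD") return("C_CARBOXYLATE")
  if (res == "ASN" && atom == "CG") return("C_AMIDE")
  if (res == "GLN" && atom == "CD") return("C_AMIDE")
  if (res == "ARG" && atom == "CZ") return("C_GUANIDINO")
  "C_SP3"
}

#' Default chemical-environment annotation scheme
#'
#' Builds the shipped 21-residue / 31-heavy-atom / 20-hydrogen vocabulary
#' and the total lookup table over all standard residue x heavy-atom
#' pairs. Unknown residues or atoms fall through to per-element catch-all
#' classes, so annotation is a total function. The hydrogen vocabulary is
#' carried for completeness but unused by the default models (hydrogens
#' are dropped on reading to keep graphs small).
#'
#' @return an \linkS4class{AnnotationScheme}.
#' @examples
#' sch <- defaultAnnotationScheme()
#' annotateResidue(sch, "ALA")
#' annotateAtom(sch, "SER", "OG") != annotateAtom(sch, "SER", "O")
#' @export
defaultAnnotationScheme <- function() {
  keys <- character(0); vals <- character(0)
  for (res in STANDARD_AA) {
    for (atom in c(AA_HEAVY_ATOMS[[res]], "OXT")) {
      keys <- c(keys, paste0(res, "|", atom))
      vals <- c(vals, .heavy_class(res, atom))
    }
  }
  lookup <- match(vals, HEAVY_CLASSES)
  names(lookup) <- keys
  residueLookup <- seq_along(STANDARD_AA)
  names(residueLookup) <- STANDARD_AA
  methods::new("AnnotationScheme",
               residueVocab = c(STANDARD_AA, "OTHER"),
               heavyAtomVocab = HEAVY_CLASSES,
               hydrogenVocab = HYDROGEN_CLASSES,
               lookup = lookup, residueLookup = residueLookup,
               version = "pocketec-default-1")
}

#' Load an annotation scheme from a TSV table
#'
#' Expects columns \code{residue_name}, \code{atom_name},
#' \code{class_name} (tab-separated, with header). Class counts are
#' validated against the 31-class heavy-atom contract; residue classes
#' stay at the default 20 + other.
#'
#' @param path TSV file.
#' @param version version string to stamp on the scheme.
#' @return an \linkS4class{AnnotationScheme}.
#' @export
readAnnotationScheme <- function(path, version = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue_name", "atom_name", "class_name")
  if (!all(need %in% names(tab)))
    stop("annotation table must have columns residue_name, atom_name, class_name")
  classes <- unique(tab$class_name)
  catchall <- c("C_OTHER", "N_OTHER", "O_OTHER", "S_OTHER", "X_OTHER")
  vocab <- unique(c(classes, catchall))
  if (length(vocab) != 31L)
    stop(sprintf("heavy-atom vocabulary must have exactly 31 classes, got %d",
                 length(vocab)))
  lookup <- match(tab$class_name, vocab)
  names(lookup) <- paste0(toupper(tab$residue_name), "|", toupper(tab$atom_name))
  residueLookup <- seq_along(STANDARD_AA)
  names(residueLookup) <- STANDARD_AA
  methods::new("AnnotationScheme",
               residueVocab = c(STANDARD_AA, "OTHER"),
               heavyAtomVocab = vocab,
               hydrogenVocab = HYDROGEN_CLASSES,
               lookup = lookup, residueLookup = residueLookup,
               version = version)
}

#' Annotate a residue name
#'
#' Total function: the 20 standard amino acids map to their own classes,
#' anything else (including modified residues such as MSE) to the 21st
#' catch-all class.
#'
#' @param scheme an \linkS4class{AnnotationScheme}.
#' @param residueName 3-letter code(s).
#' @return 1-based class index in \code{1..21} (vectorized).
#' @export
annotateResidue <- function(scheme, residueName) {
  idx <- scheme@residueLookup[toupper(residueName)]
  idx[is.na(idx)] <- length(scheme@residueVocab)   # OTHER
  unname(idx)
}

#' Annotate a heavy atom by its chemical environment
#'
#' Class is determined by the (residue, atom) pair, not the element
#' alone: e.g. the backbone carbonyl O and a serine hydroxyl OG land in
#' different classes, alpha carbons of all residues in the same class.
#' Unknown pairs fall back to the element catch-all class. Hydrogens are
#' rejected: they belong to the separate hydrogen vocabulary.
#'
#' @param scheme an \linkS4class{AnnotationScheme}.
#' @param residueName 3-letter code(s).
#' @param atomName PDB atom name(s).
#' @return 1-based class index in \code{1..31} (vectorized).
#' @export
annotateAtom <- function(scheme, residueName, atomName) {
  residueName <- toupper(residueName)
  atomName <- toupper(atomName)
  el <- .guess_element(atomName, "")
  if (any(el %in% c("H", "D")))
    stop("wrong vocabulary: hydrogen atoms use the hydrogen vocabulary")
  idx <- scheme@lookup[paste0(residueName, "|", atomName)]
  fallback <- match(paste0(el, "_OTHER"), scheme@heavyAtomVocab)
  fallback[is.na(fallback)] <- match("X_OTHER", scheme@heavyAtomVocab)
  idx[is.na(idx)] <- fallback[is.na(idx)]
  unname(idx)
}

#' @rdname annotateResidue
#' @param x an \linkS4class{AnnotationScheme}.
#' @export
schemeVersion <- function(x) x@version

#' Vocabulary accessors
#' @param x an \linkS4class{AnnotationScheme}.
#' @return character vector of class names.
#' @export
residueVocab <- function(x) x@residueVocab

#' @rdname residueVocab
#' @export
heavyAtomVocab <- function(x) x@heavyAtomVocab

#' @rdname residueVocab
#' @export
hydrogenVocab <- function(x) x@hydrogenVocab
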