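# Reading, filtering, writing and perturbing PDB structures.
#
# Parsing is delegated to bio3d; the filters applied on top implement the
# preprocessing used throughout the package: ATOM records only (HETATM,
# waters and nucleic-acid chains discarded), all protein chains kept in a
# single object, first model of multi-model files, highest-occupancy
# alternate location, hydrogens dropped unless asked for.

NUCLEIC_RESIDUES <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "U", "I")
WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

# element inferred from the PDB element column when present, otherwise
# from the atom name (leading letters, digits stripped)
.guess_element <- function(atom_name, elesy) {
  el <- rep_len(toupper(trimws(elesy)), length(atom_name))
  miss <- !nzchar(el) | is.na(el)
  if (any(miss)) {
    nm <- toupper(gsub("[^A-Z]", "", gsub("^[0-9]+", "", atom_name[miss])))
    two <- substr(nm, 1L, 2L)
    known2 <- c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "NA", "CA")
    # atom names like "CA" are alpha carbons, not calcium: inside protein
    # residues a leading C/N/O/S/H/P is the element
    first <- substr(nm, 1L, 1L)
    el[miss] <- ifelse(first %in% c("C", "N", "O", "S", "H", "P"), first,
                       ifelse(two %in% known2, two, first))
  }
  el
}

#' Read a protein structure from PDB text or file
#'
#' Keeps ATOM records only: HETATM entries, waters and nucleic-acid
#' chains are discarded, every protein chain is retained in one
#' \linkS4class{ProteinStructure} (the localized descriptor may pick up
#' chemistry from nearby chains). For multi-model (NMR) files only the
#' first model is kept; for alternate locations only the
#' highest-occupancy copy (ties: first occurrence).
#'
#' @param pdb path to a PDB file, or PDB-format text (single string with
#'   newlines or a character vector of lines).
#' @param keepHydrogens keep hydrogen atoms (default drops them).
#' @param sourceId identifier to store; defaults to the file base name or
#'   \code{"unknown"} for literal text.
#' @param ecLabel optional dotted EC string.
#' @param depositionDate optional \code{Date}.
#' @return a \linkS4class{ProteinStructure}.
#' @examples
#' pdb <- makeToyStructure(8, seed = 1)$structure
#' tf <- tempfile(fileext = ".pdb")
#' writeStructure(pdb, tf)
#' s <- readStructure(tf)
#' nAtoms(s)
#' @export
readStructure <- function(pdb, keepHydrogens = FALSE, sourceId = NULL,
                          ecLabel = NA_character_,
                          depositionDate = as.Date(NA)) {
  is_path <- length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)
  if (is_path) {
    lines <- readLines(pdb, warn = FALSE)
    if (is.null(sourceId))
      sourceId <- sub("\\.(pdb|ent)$", "", basename(pdb), ignore.case = TRUE)
  } else {
    lines <- unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE))
    if (is.null(sourceId)) sourceId <- "unknown"
  }

  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (any(is_atom)) {
    for (fld in list(c(31L, 38L), c(39L, 46L), c(47L, 54L))) {
      val <- suppressWarnings(as.numeric(substr(lines[is_atom], fld[1L], fld[2L])))
      if (anyNA(val)) {
        bad <- which(is_atom)[which(is.na(val))[1L]]
        stop(sprintf("malformed record at line %d: unparseable coordinate field", bad))
      }
    }
  }
  if (!any(rec == "ATOM  "))
    stop("empty structure: no ATOM records in input")

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdbobj <- suppressWarnings(bio3d::read.pdb(tf, multi = FALSE, verbose = FALSE,
                                             rm.alt = FALSE))
  a <- pdbobj$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$chain[is.na(a$chain)] <- " "
  a$o[is.na(a$o)] <- 1

  a <- a[!(a$resid %in% WATER_RESIDUES), , drop = FALSE]

  # chains that are mostly nucleic residues are dropped entirely
  for (ch in unique(a$chain)) {
    res <- unique(paste(a$resno, a$insert, a$resid)[a$chain == ch])
    frac <- mean(sub(".* ", "", res) %in% NUCLEIC_RESIDUES)
    if (frac > 0.5) a <- a[a$chain != ch, , drop = FALSE]
  }
  if (nrow(a) == 0L)
    stop("empty structure: no protein atoms left after filtering")

  # altloc: per (chain, residue, atom name) keep highest occupancy,
  # ties resolved by first occurrence (stable order)
  key <- paste(a$chain, a$resno, a$insert, a$elety)
  ord <- order(match(key, unique(key)), -a$o,
               seq_len(nrow(a)), method = "radix")
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety)), , drop = FALSE]
  a <- a[order(match(paste(a$chain, a$resno, a$insert, a$elety), key)), , drop = FALSE]

  element <- .guess_element(a$elety, a$elesy %||% "")
  is_h <- element %in% c("H", "D")
  if (!keepHydrogens) {
    a <- a[!is_h, , drop = FALSE]
    element <- element[!is_h]
    is_h <- is_h[!is_h]
  }
  if (nrow(a) == 0L)
    stop("empty structure: no atoms left")

  tab <- data.frame(
    atom_name = a$elety, element = element, residue_name = a$resid,
    chain_id = a$chain, residue_seq = as.integer(a$resno),
    insert = a$insert, x = a$x, y = a$y, z = a$z,
    occupancy = a$o, is_hydrogen = is_h,
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  methods::new("ProteinStructure", atoms = tab, sourceId = sourceId,
               ecLabel = as.character(ecLabel),
               depositionDate = depositionDate)
}

#' Write a structure as PDB-format ATOM records
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param path output file; omit to get the lines back invisibly.
#' @return invisibly, the character vector of PDB lines.
#' @export
writeStructure <- function(s, path = NULL) {
  a <- atoms(s)
  nm <- a$atom_name
  # 4-char names fill columns 13-16; shorter names start at column 14
  nm_fmt <- ifelse(nchar(nm) >= 4L, substr(nm, 1L, 4L),
                   sprintf(" %-3s", nm))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000L, nm_fmt, a$residue_name,
    substr(a$chain_id, 1L, 1L), a$residue_seq %% 10000L,
    ifelse(nzchar(a$insert), substr(a$insert, 1L, 1L), " "),
    a$x, a$y, a$z, a$occupancy, 0, a$element)
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

ALA_KEEP_ATOMS <- c("N", "CA", "C", "O", "CB", "OXT")

#' Computationally mutate residues to alanine
#'
#' Selected residues are renamed ALA and truncated at the beta carbon:
#' side-chain atoms beyond CB are removed while backbone (N, CA, C, O)
#' and CB coordinates stay untouched. Glycine gains no atoms. Used by the
#' perturbation experiments to strip side-chain chemistry while leaving
#' the shape of a residue-level graph unchanged.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param selector which residues to mutate: \code{NULL} for all, a
#'   character vector of residue keys (see \code{\link{residueKeys}}), or
#'   a predicate \code{function(residue_name, chain_id, residue_seq)}
#'   returning TRUE/FALSE.
#' @return the mutated \linkS4class{ProteinStructure}.
#' @export
mutateToAlanine <- function(s, selector = NULL) {
  a <- atoms(s)
  key <- paste0(a$chain_id, "|", a$residue_seq, a$insert)
  if (is.null(selector)) {
    sel <- rep(TRUE, nrow(a))
  } else if (is.character(selector)) {
    sel <- key %in% selector
  } else if (is.function(selector)) {
    u <- !duplicated(key)
    hit <- key[u][mapply(selector, a$residue_name[u], a$chain_id[u],
                         a$residue_seq[u])]
    sel <- key %in% hit
  } else stop("selector must be NULL, residue keys, or a predicate function")
  if (!any(sel)) return(s)

  drop <- sel & !(a$atom_name %in% ALA_KEEP_ATOMS) & !a$is_hydrogen
  a$residue_name[sel] <- "ALA"
  a <- a[!drop, , drop = FALSE]
  rownames(a) <- NULL
  methods::initialize(s, atoms = a)
}

#' Randomly displace every atom of a structure
#'
#' Each atom is displaced independently by a random vector with uniform
#' direction and radius uniform in \code{[0, amplitude]}; the same seed
#' reproduces the same output. Emulates coordinate-noise robustness
#' experiments (0 to 2.5 Angstrom sweeps).
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param amplitude maximum displacement in Angstrom (>= 0).
#' @param seed integer seed.
#' @return the perturbed \linkS4class{ProteinStructure}.
#' @export
perturbCoordinates <- function(s, amplitude, seed = 1L) {
  if (amplitude < 0) stop("invalid amplitude: must be >= 0")
  if (amplitude == 0) return(s)
  a <- atoms(s)
  d <- with_seed(seed, random_displacements(nrow(a), amplitude))
  a$x <- a$x + d[, 1L]
  a$y <- a$y + d[, 2L]
  a$z <- a$z + d[, 3L]
  methods::initialize(s, atoms = a)
}

# coordinate matrix helper used across modules
coords <- function(s) {
  a <- atoms(s)
  m <- cbind(a$x, a$y, a$z)
  colnames(m) <- c("x", "y", "z")
  m
}

# Calpha rows of the atom table, one per residue that has a CA
calpha_table <- function(s) {
  a <- atoms(s)
  ca <- a[a$atom_name == "CA" & !a$is_hydrogen, , drop = FALSE]
  keys <- paste0(ca$chain_id, "|", ca$residue_seq, ca$insert)
  ca[!duplicated(keys), , drop = FALSE]
}
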