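# Synthetic structures with planted chemical motifs.
#
# The generator emulates the premise that local chemistry around the
# binding site suffices to classify function: each class is defined by a
# small residue motif placed around a designated site center on an
# otherwise random chain. Backbones are ideal alpha-helical curves with
# 3.8 Angstrom Calpha spacing; side chains are pseudo-atoms at
# idealized internal coordinates (no rotamer library) -- sufficient for
# atom typing and distance tests, not physically realistic. Decoy
# structures carry a wrong-class motif far from the site center, so the
# label is recoverable only from the site region (a locality probe).

# ideal helix parameters giving 3.8 A between consecutive Calphas
.HELIX_RISE <- 1.5
.HELIX_TURN <- 99.1 * pi / 180
.HELIX_RADIUS <- sqrt(3.8^2 - .HELIX_RISE^2) / (2 * sin(.HELIX_TURN / 2))

.helix_positions <- function(idx) {
  cbind(.HELIX_RADIUS * cos(idx * .HELIX_TURN),
        .HELIX_RADIUS * sin(idx * .HELIX_TURN),
        idx * .HELIX_RISE)
}

#' Specify a planted class motif
#'
#' @param classId integer class index the motif encodes.
#' @param residues character vector of 3-letter codes (the motif
#'   multiset, placed on consecutive chain positions).
#' @param geometry optional pairwise Calpha distance matrix for the
#'   motif segment; must be realizable in 3D and keep consecutive
#'   distances at 3.8 +/- 0.01 so the chain stays intact. Default NULL
#'   uses the helical segment geometry.
#' @param placementRadius all motif residues end up within this radius
#'   of the returned site center (Angstrom, default 8).
#' @return a motif spec list.
#' @export
motifSpec <- function(classId, residues, geometry = NULL,
                      placementRadius = 8) {
  residues <- toupper(residues)
  if (!all(residues %in% STANDARD_AA))
    stop("motif residues must be standard amino acids")
  if (!is.null(geometry)) {
    m <- length(residues)
    if (!is.matrix(geometry) || any(dim(geometry) != m))
      stop("geometry must be an m x m distance matrix")
    consec <- geometry[cbind(seq_len(m - 1L), 2L:m)]
    if (any(abs(consec - 3.8) > 0.01))
      stop("infeasible motif: consecutive motif distances must be 3.8 A")
    # a non-Euclidean matrix yields negative eigenvalues here; the
    # reconstruction check below turns that into an explicit error
    emb <- suppressWarnings(stats::cmdscale(geometry, k = min(3L, m - 1L)))
    if (ncol(emb) < 3L) emb <- cbind(emb, matrix(0, m, 3L - ncol(emb)))
    if (max(abs(as.matrix(stats::dist(emb)) - geometry)) > 0.05)
      stop("infeasible motif: distance matrix is not realizable in 3D")
    attr(geometry, "embedding") <- emb
  }
  list(classId = as.integer(classId), residues = residues,
       geometry = geometry, placementRadius = placementRadius)
}

#' Default 4-class motif set
#'
#' Four planted motifs of six residues (three chemistries, twice each)
#' with pairwise-disjoint residue types, labeled with EC-style
#' designations so hierarchy-level metrics can be exercised.
#'
#' @return list of \code{\link{motifSpec}}s with a \code{"vocab"}
#'   attribute of EC-style labels.
#' @export
defaultClassSpecs <- function() {
  specs <- list(
    motifSpec(1L, c("SER", "HIS", "ASP", "SER", "HIS", "ASP")),
    motifSpec(2L, c("CYS", "MET", "TRP", "CYS", "MET", "TRP")),
    motifSpec(3L, c("LYS", "ARG", "GLU", "LYS", "ARG", "GLU")),
    motifSpec(4L, c("PHE", "TYR", "THR", "PHE", "TYR", "THR")))
  attr(specs, "vocab") <- c("1.1.1.1", "2.7.10.1", "3.4.21.4", "4.2.1.1")
  specs
}

# deterministic orthonormal frame per residue from chain neighbors
.residue_frame <- function(pos, i) {
  n <- nrow(pos)
  prev <- if (i > 1L) pos[i - 1L, ] else pos[i, ] - c(1, 0, 0)
  nxt <- if (i < n) pos[i + 1L, ] else pos[i, ] + c(1, 0, 0)
  e1 <- nxt - prev
  e1 <- e1 / max(sqrt(sum(e1^2)), 1e-9)
  ref <- if (abs(e1[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- c(e1[2L] * ref[3L] - e1[3L] * ref[2L],
          e1[3L] * ref[1L] - e1[1L] * ref[3L],
          e1[1L] * ref[2L] - e1[2L] * ref[1L])
  e2 <- e2 / max(sqrt(sum(e2^2)), 1e-9)
  e3 <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
          e1[3L] * e2[1L] - e1[1L] * e2[3L],
          e1[1L] * e2[2L] - e1[2L] * e2[1L])
  list(e1 = e1, e2 = e2, e3 = e3)
}

# heavy pseudo-atoms for one residue at idealized offsets
.residue_atoms <- function(resname, ca, frame) {
  nm <- AA_HEAVY_ATOMS[[resname]]
  out <- matrix(NA_real_, length(nm), 3L)
  rownames(out) <- nm
  out["N", ] <- ca - frame$e1 - frame$e2
  out["CA", ] <- ca
  out["C", ] <- ca + frame$e1 - frame$e2
  out["O", ] <- ca + frame$e1 - 1.9 * frame$e2
  side <- setdiff(nm, c("N", "CA", "C", "O"))
  for (k in seq_along(side)) {
    zig <- if (k %% 2L) 0.5 else -0.5
    out[side[k], ] <- ca + (0.9 + 0.75 * k) * frame$e3 +
      zig * frame$e2 * (k > 1L)
  }
  out
}

#' Generate one synthetic structure with a planted motif
#'
#' The backbone is an ideal helix-like curve (Calpha spacing 3.8
#' Angstrom, no self-clashes below 2.5); the motif residues occupy
#' consecutive positions near the chain middle (or follow a custom
#' realizable geometry), all within the placement radius of the
#' returned site center (the motif Calpha centroid). Remaining residue
#' types are drawn uniformly from the 20 standard amino acids.
#'
#' @param nResidues chain length (>= motif size + 3).
#' @param motif a \code{\link{motifSpec}}, or NULL for a motif-free
#'   chain (site center then sits at the chain middle).
#' @param seed integer seed; the same seed reproduces the structure
#'   bit-identically.
#' @param sourceId identifier stored on the structure.
#' @param ecLabel label string stored on the structure.
#' @param decoyMotif optional second \code{\link{motifSpec}} written far
#'   from the site center (> 2x placement radius).
#' @return list with \code{structure} (\linkS4class{ProteinStructure}),
#'   \code{site} (\linkS4class{BindingSite}, source experimental),
#'   \code{label} (the motif's classId or NA).
#' @export
makeToyStructure <- function(nResidues, motif = NULL, seed = 1L,
                             sourceId = sprintf("SYN_%06d", seed),
                             ecLabel = NA_character_, decoyMotif = NULL) {
  m <- if (is.null(motif)) 0L else length(motif$residues)
  if (nResidues < m + 3L) stop("nResidues must be >= motif size + 3")
  pos <- .helix_positions(seq_len(nResidues))

  start <- max(1L, (nResidues - m) %/% 2L)
  if (m > 0L && !is.null(motif$geometry)) {
    emb <- attr(motif$geometry, "embedding")
    # place the embedded segment so its first point continues the chain
    sv <- rigidSuperpose(emb, pos[start:(start + m - 1L), , drop = FALSE])
    seg <- emb %*% sv$R + matrix(sv$t, m, 3L, byrow = TRUE)
    seg <- seg + matrix(pos[start, ] - seg[1L, ], m, 3L, byrow = TRUE)
    pos[start:(start + m - 1L), ] <- seg
    if (m + start <= nResidues) {
      tail_idx <- (start + m):nResidues
      dirv <- seg[m, ] - seg[m - 1L, ]
      dirv <- dirv / sqrt(sum(dirv^2))
      shift <- seg[m, ] + 3.8 * dirv - pos[start + m, ]
      pos[tail_idx, ] <- pos[tail_idx, , drop = FALSE] +
        matrix(shift, length(tail_idx), 3L, byrow = TRUE)
    }
    dmin <- min(stats::dist(pos))
    if (dmin < 2.5) stop("infeasible motif: self-clash below 2.5 A")
  }

  restypes <- with_seed(seed, sample(STANDARD_AA, nResidues, replace = TRUE))
  if (m > 0L) restypes[start:(start + m - 1L)] <- motif$residues
  label <- if (m > 0L) motif$classId else NA_integer_

  if (!is.null(decoyMotif)) {
    dm <- length(decoyMotif$residues)
    dstart <- nResidues - dm + 1L
    restypes[dstart:nResidues] <- decoyMotif$residues
  }

  center <- if (m > 0L) colMeans(pos[start:(start + m - 1L), , drop = FALSE])
            else colMeans(pos)
  if (m > 0L) {
    rmax <- max(sqrt(rowSums((pos[start:(start + m - 1L), , drop = FALSE] -
      matrix(center, m, 3L, byrow = TRUE))^2)))
    if (rmax > motif$placementRadius)
      stop("infeasible motif: segment exceeds the placement radius")
  }
  if (!is.null(decoyMotif)) {
    dm <- length(decoyMotif$residues)
    ddist <- min(sqrt(rowSums((pos[(nResidues - dm + 1L):nResidues, ,
                                   drop = FALSE] -
      matrix(center, dm, 3L, byrow = TRUE))^2)))
    if (ddist <= 2 * decoyMotif$placementRadius)
      stop("chain too short to place the decoy motif far from the site")
  }

  tabs <- vector("list", nResidues)
  for (i in seq_len(nResidues)) {
    fr <- .residue_frame(pos, i)
    xyz <- .residue_atoms(restypes[i], pos[i, ], fr)
    tabs[[i]] <- data.frame(
      atom_name = rownames(xyz),
      element = substr(rownames(xyz), 1L, 1L),
      residue_name = restypes[i], chain_id = "A", residue_seq = i,
      insert = "", x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      occupancy = 1, is_hydrogen = FALSE, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  s <- methods::new("ProteinStructure", atoms = tab, sourceId = sourceId,
                    ecLabel = as.character(ecLabel),
                    depositionDate = as.Date(NA))
  list(structure = s, site = bindingSite(center, "experimental"),
       label = label)
}

#' Generate a labeled synthetic dataset with sites and clustering
#'
#' Balanced classes, each structure with its planted motif and site
#' center; a fraction of structures additionally carries a wrong-class
#' decoy motif far from the site (label recoverable only locally). A
#' lineage clustering (generator families per class) and per-structure
#' pseudo deposition dates are emitted so the split machinery can be
#' exercised end to end.
#'
#' @param nPerClass structures per class (default 40).
#' @param classSpecs list of \code{\link{motifSpec}}s (default the
#'   4-class set).
#' @param decoyRate fraction of structures receiving a decoy motif
#'   (default 0.25).
#' @param seed integer seed.
#' @param nResidues chain length (default 60).
#' @param nLineages clusters per class in the emitted clustering.
#' @param dir optional directory: writes PDB files, a site CSV
#'   (\code{sites.csv}), a cluster TSV (\code{clusters.tsv}) and a label
#'   CSV (\code{labels.csv}).
#' @return list with \code{entries} (list of id/structure/site/label/
#'   cluster/date), \code{labels}, \code{clustering}, \code{dates}
#'   (named vectors) and \code{vocab} (class label strings).
#' @export
makeDataset <- function(nPerClass = 40L, classSpecs = defaultClassSpecs(),
                        decoyRate = 0.25, seed = 1L, nResidues = 60L,
                        nLineages = 10L, dir = NULL) {
  if (length(classSpecs) < 2L) stop("need at least two classes")
  sigs <- vapply(classSpecs, function(sp)
    paste(sort(sp$residues), collapse = "-"), character(1))
  if (anyDuplicated(sigs)) stop("class motifs must be distinct")
  vocab <- attr(classSpecs, "vocab") %||%
    paste0(seq_along(classSpecs), ".1.1.1")

  entries <- list()
  with_seed(seed, {
    for (ci in seq_along(classSpecs)) {
      decoy <- stats::runif(nPerClass) < decoyRate
      sseeds <- sample.int(2^30, nPerClass)
      for (k in seq_len(nPerClass)) {
        dspec <- NULL
        if (decoy[k]) {
          others <- setdiff(seq_along(classSpecs), ci)
          dspec <- classSpecs[[others[1L + (k %% length(others))]]]
        }
        id <- sprintf("SYN_C%d_%03d", ci, k)
        toy <- makeToyStructure(nResidues, classSpecs[[ci]],
                                seed = sseeds[k], sourceId = id,
                                ecLabel = vocab[ci], decoyMotif = dspec)
        entries[[length(entries) + 1L]] <- list(
          id = id, structure = toy$structure, site = toy$site,
          label = ci,
          cluster = sprintf("L%d_%d", ci, 1L + (k - 1L) %% nLineages),
          date = as.Date("2000-01-01") + length(entries))
      }
    }
  })
  ids <- vapply(entries, `[[`, character(1), "id")
  labels <- stats::setNames(vocab[vapply(entries, `[[`, integer(1), "label")], ids)
  clustering <- stats::setNames(vapply(entries, `[[`, character(1), "cluster"), ids)
  dates <- stats::setNames(as.Date(vapply(entries, function(e)
    as.character(e$date), character(1))), ids)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sites <- list()
    for (e in entries) {
      writeStructure(e$structure, file.path(dir, paste0(e$id, ".pdb")))
      sites[[e$id]] <- list(e$site)
    }
    writeSiteTable(sites, file.path(dir, "sites.csv"))
    writeClusterTSV(clustering, file.path(dir, "clusters.tsv"))
    utils::write.csv(data.frame(item_id = ids, ec = unname(labels)),
                     file.path(dir, "labels.csv"), row.names = FALSE)
  }
  list(entries = entries, labels = labels, clustering = clustering,
       dates = dates, vocab = vocab)
}
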