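#' ProteinStructure: ordered heavy atoms of one (multi-chain) protein
#'
#' Raw 3D object behind every descriptor: an ordered atom table with
#' coordinates in Angstrom, residue and chain identity, plus provenance.
#' All chains of a file live in one object so that the localized
#' descriptor can pick up local chemistry contributed by nearby chains.
#'
#' @slot atoms data.frame, one row per atom (see \code{\link{atoms}}).
#' @slot sourceId character scalar, e.g. a PDB id, \code{"AF2_<uniprot>"}.
#' @slot ecLabel dotted EC string or NA.
#' @slot depositionDate \code{Date} or NA (used by the temporal split).
#' @export
setClass("ProteinStructure",
  representation(atoms = "data.frame", sourceId = "character",
                 ecLabel = "character", depositionDate = "Date"),
  prototype(sourceId = "unknown", ecLabel = NA_character_,
            depositionDate = as.Date(NA)))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("atom_name", "element", "residue_name", "chain_id",
            "residue_seq", "insert", "x", "y", "z", "occupancy",
            "is_hydrogen")
  if (!all(need %in% names(a)))
    return(paste("atom table misses columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) < 1L) return("structure must contain at least one atom")
  if (!all(is.finite(c(a$x, a$y, a$z)))) return("non-finite coordinates")
  if (any(!nzchar(a$atom_name))) return("empty atom names")
  key <- paste(a$chain_id, a$residue_seq, a$insert, a$atom_name)
  if (anyDuplicated(key)) return("duplicate (chain, residue, atom) entries")
  TRUE
})

#' BindingSite: a 3D site center with provenance
#'
#' @slot center numeric length-3, Angstrom.
#' @slot source one of \code{"experimental"}, \code{"predicted"},
#'   \code{"transferred"}, \code{"random"}.
#' @slot rank positive integer (1 = best).
#' @slot score optional real score (NA if none).
#' @export
setClass("BindingSite",
  representation(center = "numeric", source = "character",
                 rank = "integer", score = "numeric"),
  prototype(source = "experimental", rank = 1L, score = NA_real_))

setValidity("BindingSite", function(object) {
  if (length(object@center) != 3L || !all(is.finite(object@center)))
    return("center must be a finite 3-vector")
  if (!object@source %in% c("experimental", "predicted", "transferred", "random"))
    return("unknown site source")
  if (object@rank < 1L) return("rank must be >= 1")
  TRUE
})

#' SiteSelection: the residues/atoms kept by a descriptor cut
#'
#' @slot structure the parent \linkS4class{ProteinStructure}.
#' @slot keys kept residue keys (residue resolution) or atom row indices
#'   (atom resolution), in distance order for count cuts.
#' @slot resolution \code{"residue"} or \code{"atom"}.
#' @slot cutMode \code{"none"}, \code{"radius"} or \code{"count"}.
#' @slot parameter the radius (Angstrom) or count used.
#' @slot site the \linkS4class{BindingSite} the cut was centered on (may be
#'   a placeholder for \code{cutMode == "none"}).
#' @export
setClass("SiteSelection",
  representation(structure = "ProteinStructure", keys = "ANY",
                 resolution = "character", cutMode = "character",
                 parameter = "numeric", site = "BindingSite"))

setValidity("SiteSelection", function(object) {
  if (!object@resolution %in% c("residue", "atom"))
    return("resolution must be 'residue' or 'atom'")
  if (!object@cutMode %in% c("none", "radius", "count"))
    return("cutMode must be none/radius/count")
  if (length(object@keys) < 1L) return("empty selection")
  if (object@resolution == "residue") {
    if (!all(object@keys %in% residueKeys(object@structure)))
      return("selection keys not present in structure")
  } else {
    if (!all(object@keys >= 1L & object@keys <= nAtoms(object@structure)))
      return("atom indices out of range")
  }
  TRUE
})

#' AnnotationScheme: the chemical-environment node vocabulary
#'
#' Maps residue names to 21 residue classes and (residue, heavy atom)
#' pairs to 31 heavy-atom classes; a 20-class hydrogen vocabulary is
#' carried along but unused by the default models. Lookups are total via
#' catch-all classes, so annotation never fails on nonstandard input.
#'
#' @slot residueVocab character(21).
#' @slot heavyAtomVocab character(31).
#' @slot hydrogenVocab character(20).
#' @slot lookup named integer vector, key \code{"RES|ATOM"} -> heavy-atom
#'   class index.
#' @slot residueLookup named integer vector, residue name -> class index.
#' @slot version character scheme version, embedded in serialized graphs.
#' @export
setClass("AnnotationScheme",
  representation(residueVocab = "character", heavyAtomVocab = "character",
                 hydrogenVocab = "character", lookup = "integer",
                 residueLookup = "integer", version = "character"))

setValidity("AnnotationScheme", function(object) {
  if (length(object@residueVocab) != 21L) return("residue vocabulary must have 21 classes")
  if (length(object@heavyAtomVocab) != 31L) return("heavy-atom vocabulary must have 31 classes")
  if (length(object@hydrogenVocab) != 20L) return("hydrogen vocabulary must have 20 classes")
  if (anyDuplicated(object@residueVocab) || anyDuplicated(object@heavyAtomVocab))
    return("duplicated class names")
  TRUE
})

#' ProteinGraph: a typed 3D graph over a localized descriptor
#'
#' Nodes carry positions (Angstrom) and chemical-environment type
#' indices; edges are directed j -> i, radius-limited and capped at
#' \code{maxNeighbors} per receiving node. Graphs carry no edge features:
#' distances and angles are recomputed from positions inside the
#' networks, which keeps coordinate augmentation cheap.
#'
#' @slot positions N x 3 matrix.
#' @slot types integer N, 1-based indices into the annotation vocabulary.
#' @slot edges E x 2 integer matrix, columns (j, i).
#' @slot label integer class index or NA.
#' @slot resolution \code{"residue"} or \code{"atom"}.
#' @slot neighborRadius numeric, the cutoff used to build edges.
#' @slot provenance list(structure_id, site_rank, residue_keys or atom rows).
#' @slot schemeVersion annotation scheme version string.
#' @export
setClass("ProteinGraph",
  representation(positions = "matrix", types = "integer", edges = "matrix",
                 label = "integer", resolution = "character",
                 neighborRadius = "numeric", provenance = "list",
                 schemeVersion = "character"),
  prototype(label = NA_integer_, schemeVersion = "unversioned"))

setValidity("ProteinGraph", function(object) {
  n <- nrow(object@positions)
  if (ncol(object@positions) != 3L) return("positions must be N x 3")
  if (length(object@types) != n) return("types length != node count")
  if (nrow(object@edges) > 0L) {
    if (ncol(object@edges) != 2L) return("edges must be E x 2 (j, i)")
    if (any(object@edges < 1L | object@edges > n)) return("edge endpoint out of range")
    if (any(object@edges[, 1L] == object@edges[, 2L])) return("self-edges not allowed")
    d <- sqrt(rowSums((object@positions[object@edges[, 1L], , drop = FALSE] -
                       object@positions[object@edges[, 2L], , drop = FALSE])^2))
    if (any(d > object@neighborRadius + 1e-9)) return("edge longer than neighborRadius")
  }
  TRUE
})

#' GraphBatch: several graphs packed for one forward pass
#'
#' Node blocks are concatenated, edges re-indexed, and a node -> graph
#' assignment kept so that the pooled readout (and hence the minibatch
#' loss) decomposes as a sum of per-graph terms.
#'
#' @slot positions total-N x 3 matrix.
#' @slot types integer vector.
#' @slot edges E x 2 integer (j, i) in concatenated indexing.
#' @slot graphIndex integer, node -> graph (1..G).
#' @slot labels integer length G (NA allowed).
#' @slot nGraphs integer.
#' @export
setClass("GraphBatch",
  representation(positions = "matrix", types = "integer", edges = "matrix",
                 graphIndex = "integer", labels = "integer",
                 nGraphs = "integer"))

setValidity("GraphBatch", function(object) {
  if (length(object@graphIndex) != nrow(object@positions))
    return("graphIndex must assign every node")
  if (length(object@labels) != object@nGraphs) return("one label slot per graph")
  if (nrow(object@edges) > 0L &&
      any(object@graphIndex[object@edges[, 1L]] != object@graphIndex[object@edges[, 2L]]))
    return("edges may not cross graphs")
  TRUE
})

#' GraphClassifier: a message-passing EC classifier
#'
#' Holds the architecture name, its configuration, the parameter list and
#' the class vocabulary (dotted EC strings or arbitrary class names).
#' Constructed with \code{\link{graphClassifier}}, trained with
#' \code{\link{trainClassifier}}.
#'
#' @slot architecture \code{"distances"} or \code{"distances_angles"}.
#' @slot config named list (dims, cutoffs, basis settings, dropout ...).
#' @slot params named list of numeric matrices/vectors.
#' @slot classVocab character C, class index -> label.
#' @slot schemeVersion annotation scheme the model was built against.
#' @export
setClass("GraphClassifier",
  representation(architecture = "character", config = "list",
                 params = "list", classVocab = "character",
                 schemeVersion = "character"))

setValidity("GraphClassifier", function(object) {
  if (!object@architecture %in% c("distances", "distances_angles"))
    return("unknown architecture")
  if (length(object@classVocab) < 2L) return("need at least two classes")
  TRUE
})

#' NodeImportance: per-node relevance from the softmask explainer
#'
#' @slot raw numeric per-node converged mask values.
#' @slot normalized numeric in [0, 1] (min-max per structure).
#' @slot mapping data.frame linking nodes to chain/residue (and atom).
#' @slot trace numeric objective values across accepted optimizer steps.
#' @slot flags character vector of warnings raised during explanation.
#' @export
setClass("NodeImportance",
  representation(raw = "numeric", normalized = "numeric",
                 mapping = "data.frame", trace = "numeric",
                 flags = "character"),
  prototype(flags = character(0)))

setValidity("NodeImportance", function(object) {
  if (length(object@raw) != length(object@normalized))
    return("raw/normalized length mismatch")
  if (length(object@normalized) &&
      (min(object@normalized) < -1e-9 || max(object@normalized) > 1 + 1e-9))
    return("normalized importance must lie in [0, 1]")
  TRUE
})

## ---- accessors & show ----

#' @rdname atoms
#' @export
setMethod("atoms", "ProteinStructure", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("nAtoms", "ProteinStructure", function(x) nrow(x@atoms))

#' @rdname sourceId
#' @export
setMethod("sourceId", "ProteinStructure", function(x) x@sourceId)

#' @rdname ecLabel
#' @export
setMethod("ecLabel", "ProteinStructure", function(x) x@ecLabel)

#' @rdname ecLabel
#' @export
setMethod("ecLabel<-", "ProteinStructure", function(x, value) {
  x@ecLabel <- as.character(value)
  x
})

#' @rdname residueKeys
#' @export
setMethod("residueKeys", "ProteinStructure", function(x) {
  a <- x@atoms
  unique(paste0(a$chain_id, "|", a$residue_seq, a$insert))
})

#' @rdname residueKeys
#' @export
setMethod("residueKeys", "SiteSelection", function(x) {
  if (x@resolution != "residue")
    stop("selection is at atom resolution; keys are atom indices")
  x@keys
})

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  cat("ProteinStructure", object@sourceId, "\n",
      " ", nrow(a), "atoms,", length(residueKeys(object)), "residues,",
      length(unique(a$chain_id)), "chain(s)\n")
  if (!is.na(object@ecLabel)) cat("  EC:", object@ecLabel, "\n")
})

setMethod("show", "BindingSite", function(object) {
  cat(sprintf("BindingSite rank %d (%s) at [%.2f, %.2f, %.2f] A\n",
              object@rank, object@source,
              object@center[1], object@center[2], object@center[3]))
})

setMethod("show", "SiteSelection", function(object) {
  cat(sprintf("SiteSelection: %d %ss kept (%s cut%s)\n",
              length(object@keys), object@resolution, object@cutMode,
              if (object@cutMode == "none") ""
              else sprintf(", parameter %g", object@parameter)))
})

setMethod("show", "ProteinGraph", function(object) {
  cat(sprintf("ProteinGraph (%s resolution): %d nodes, %d edges%s\n",
              object@resolution, nrow(object@positions), nrow(object@edges),
              if (is.na(object@label)) "" else sprintf(", class %d", object@label)))
})

setMethod("show", "GraphClassifier", function(object) {
  cat(sprintf("GraphClassifier [%s]: %d classes, embedding %d\n",
              object@architecture, length(object@classVocab),
              object@config$embeddingDim))
})

setMethod("show", "NodeImportance", function(object) {
  cat(sprintf("NodeImportance over %d nodes (median %.3f)\n",
              length(object@raw), stats::median(object@normalized)))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})
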