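# Building typed 3D graphs from site selections, triplet enumeration for
# directional message passing, batching, and the graph-set container.

#' Build a typed 3D graph from a site selection
#'
#' One node per kept residue (position = Calpha, type = amino-acid class)
#' or per kept heavy atom (type = chemical-environment class). A directed
#' edge j -> i exists iff \code{d_ij <= neighborRadius} and j is among
#' the \code{maxNeighbors} nearest neighbors of i (ties broken by node
#' index). Construction is symmetric before the per-receiver cap.
#'
#' @param sel a \linkS4class{SiteSelection}.
#' @param scheme an \linkS4class{AnnotationScheme}.
#' @param neighborRadius edge cutoff in Angstrom; default 15 at residue
#'   resolution, 6 at atom resolution (Calpha-contact vs covalent+contact
#'   scale, matching the radial basis support).
#' @param maxNeighbors in-degree cap per node (default 32).
#' @param label optional integer class label to attach.
#' @return a \linkS4class{ProteinGraph}.
#' @export
buildGraph <- function(sel, scheme, neighborRadius = NULL, maxNeighbors = 32L,
                       label = NA_integer_) {
  if (length(sel@keys) < 1L) stop("empty descriptor")
  s <- sel@structure
  if (is.null(neighborRadius))
    neighborRadius <- if (sel@resolution == "residue") 15 else 6

  if (sel@resolution == "residue") {
    ca <- calpha_table(s)
    keys <- paste0(ca$chain_id, "|", ca$residue_seq, ca$insert)
    rows <- which(keys %in% sel@keys)          # file order
    pos <- cbind(ca$x[rows], ca$y[rows], ca$z[rows])
    types <- annotateResidue(scheme, ca$residue_name[rows])
    prov_keys <- keys[rows]
  } else {
    rows <- sort(as.integer(sel@keys))
    a <- atoms(s)[rows, , drop = FALSE]
    pos <- cbind(a$x, a$y, a$z)
    types <- annotateAtom(scheme, a$residue_name, a$atom_name)
    prov_keys <- rows
  }
  n <- nrow(pos)

  edges <- matrix(integer(0), 0L, 2L)
  if (n > 1L) {
    dm <- as.matrix(stats::dist(pos))
    elist <- vector("list", n)
    for (i in seq_len(n)) {
      cand <- which(dm[, i] <= neighborRadius)
      cand <- cand[cand != i]
      if (length(cand)) {
        cand <- cand[order(dm[cand, i], cand, method = "radix")]
        cand <- cand[seq_len(min(maxNeighbors, length(cand)))]
        elist[[i]] <- cbind(cand, i)
      }
    }
    edges <- do.call(rbind, elist)
    if (is.null(edges)) edges <- matrix(integer(0), 0L, 2L)
    dimnames(edges) <- NULL
    storage.mode(edges) <- "integer"
  }
  methods::new("ProteinGraph", positions = pos, types = as.integer(types),
               edges = edges, label = as.integer(label),
               resolution = sel@resolution, neighborRadius = neighborRadius,
               provenance = list(structure_id = sourceId(s),
                                 site_rank = sel@site@rank,
                                 keys = prov_keys),
               schemeVersion = scheme@version)
}

#' Enumerate directional triplets (k, j, i) with angles
#'
#' One triplet per pair of edges (k -> j, j -> i) with \code{k != i}; the
#' angle is taken at j between the vectors to k and to i, in
#' \code{[0, pi]}. These angles feed the spherical Fourier-Bessel filters
#' of the directional architecture.
#'
#' @param g a \linkS4class{ProteinGraph}.
#' @return data.frame with columns \code{k, j, i, edge_kj, edge_ji,
#'   angle} (edge columns are row indices into \code{g@edges}).
#' @export
computeTriplets <- function(g) {
  ed <- g@edges
  if (nrow(ed) == 0L) stop("graph has no edges")
  into <- split(seq_len(nrow(ed)), ed[, 2L])    # edge ids arriving at node
  out <- vector("list", nrow(ed))
  for (e2 in seq_len(nrow(ed))) {
    j <- ed[e2, 1L]; i <- ed[e2, 2L]
    inc <- into[[as.character(j)]]
    if (is.null(inc)) next
    keep <- ed[inc, 1L] != i
    if (!any(keep)) next
    out[[e2]] <- cbind(k = ed[inc[keep], 1L], j = j, i = i,
                       edge_kj = inc[keep], edge_ji = e2)
  }
  tr <- do.call(rbind, out)
  if (is.null(tr))
    return(data.frame(k = integer(0), j = integer(0), i = integer(0),
                      edge_kj = integer(0), edge_ji = integer(0),
                      angle = numeric(0)))
  tr <- as.data.frame(tr)
  vk <- g@positions[tr$k, , drop = FALSE] - g@positions[tr$j, , drop = FALSE]
  vi <- g@positions[tr$i, , drop = FALSE] - g@positions[tr$j, , drop = FALSE]
  nk <- sqrt(rowSums(vk^2)); ni <- sqrt(rowSums(vi^2))
  if (any(nk < 1e-9) || any(ni < 1e-9))
    stop("degenerate geometry: coincident points make an angle undefined")
  cosv <- pmin(1, pmax(-1, rowSums(vk * vi) / (nk * ni)))
  tr$angle <- acos(cosv)
  tr
}

#' Pack graphs into one batch
#'
#' Concatenates node blocks, re-indexes edges, and records a node ->
#' graph assignment so pooled readouts (and the minibatch loss)
#' decompose per graph.
#'
#' @param graphs list of \linkS4class{ProteinGraph}.
#' @return a \linkS4class{GraphBatch}.
#' @export
batchGraphs <- function(graphs) {
  sizes <- vapply(graphs, function(g) nrow(g@positions), integer(1))
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  pos <- do.call(rbind, lapply(graphs, function(g) g@positions))
  types <- unlist(lapply(graphs, function(g) g@types))
  edges <- do.call(rbind, mapply(function(g, o)
    if (nrow(g@edges)) g@edges + o else g@edges,
    graphs, offs, SIMPLIFY = FALSE))
  if (is.null(edges)) edges <- matrix(integer(0), 0L, 2L)
  storage.mode(edges) <- "integer"
  methods::new("GraphBatch", positions = pos, types = as.integer(types),
               edges = edges,
               graphIndex = rep(seq_along(graphs), sizes),
               labels = vapply(graphs, function(g) g@label, integer(1)),
               nGraphs = length(graphs))
}

#' Write / read a set of graphs (hierarchical container)
#'
#' Hierarchical layout \code{/graph_id/\{positions, types, edges, label\}}
#' serialized as JSON with full-precision numbers; the annotation scheme
#' version travels with every graph and a round trip preserves graphs
#' exactly.
#'
#' @param graphs named (or auto-named) list of \linkS4class{ProteinGraph}.
#' @param path output file.
#' @return \code{writeGraphSet}: the path, invisibly. \code{readGraphSet}:
#'   a named list of \linkS4class{ProteinGraph}.
#' @export
writeGraphSet <- function(graphs, path) {
  if (is.null(names(graphs)) || any(!nzchar(names(graphs))))
    names(graphs) <- make.unique(vapply(graphs, function(g)
      paste0(g@provenance$structure_id %||% "graph", "_r",
             g@provenance$site_rank %||% 1L), character(1)))
  payload <- lapply(graphs, function(g) list(
    positions = unname(g@positions), types = g@types,
    edges = unname(g@edges), label = g@label,
    resolution = g@resolution, neighbor_radius = g@neighborRadius,
    scheme_version = g@schemeVersion,
    provenance = g@provenance[c("structure_id", "site_rank")]))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname writeGraphSet
#' @export
readGraphSet <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyMatrix = TRUE)
  lapply(payload, function(p) {
    edges <- p$edges
    if (length(edges) == 0L) edges <- matrix(integer(0), 0L, 2L)
    if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2L)
    storage.mode(edges) <- "integer"
    pos <- p$positions
    if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3L)
    methods::new("ProteinGraph", positions = pos,
                 types = as.integer(p$types), edges = edges,
                 label = if (is.null(p$label)) NA_integer_ else as.integer(p$label),
                 resolution = p$resolution,
                 neighborRadius = p$neighbor_radius,
                 provenance = list(structure_id = p$provenance$structure_id,
                                   site_rank = p$provenance$site_rank),
                 schemeVersion = p$scheme_version)
  })
}
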