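# The localized 3D descriptor: cutting a structure around a binding-site
# center. Extraction happens in memory at graph-build time; PDB files are
# never edited. Three cut modes: none (full object), radius (everything
# within r), count (n nearest units). Residue-resolution distances are
# measured at the Calpha atom; residues missing a CA are skipped with a
# warning.

#' Construct a binding site
#'
#' @param center numeric 3-vector (Angstrom).
#' @param source provenance: experimental, predicted, transferred, random.
#' @param rank site rank (1 = best).
#' @param score optional score.
#' @return a \linkS4class{BindingSite}.
#' @export
bindingSite <- function(center, source = "experimental", rank = 1L,
                        score = NA_real_) {
  methods::new("BindingSite", center = as.numeric(center), source = source,
               rank = as.integer(rank), score = as.numeric(score))
}

# distance of every selectable unit to the site center; returns a list
# with keys (residue keys or atom indices) and distances, in file order
.unit_distances <- function(s, site, resolution) {
  if (resolution == "residue") {
    ca <- calpha_table(s)
    all_keys <- residueKeys(s)
    have <- paste0(ca$chain_id, "|", ca$residue_seq, ca$insert)
    if (length(have) < length(all_keys))
      warning(sprintf("%d residue(s) without CA skipped",
                      length(all_keys) - length(have)))
    d <- sqrt((ca$x - site@center[1])^2 + (ca$y - site@center[2])^2 +
              (ca$z - site@center[3])^2)
    list(keys = have, dist = d)
  } else {
    xyz <- coords(s)
    d <- sqrt(colSums((t(xyz) - site@center)^2))
    list(keys = seq_len(nrow(xyz)), dist = d)
  }
}

#' Keep the full structure (no cutting)
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param resolution \code{"residue"} or \code{"atom"}.
#' @return a \linkS4class{SiteSelection} keeping every unit.
#' @export
selectAll <- function(s, resolution = c("residue", "atom")) {
  resolution <- match.arg(resolution)
  keys <- if (resolution == "residue") residueKeys(s) else seq_len(nAtoms(s))
  methods::new("SiteSelection", structure = s, keys = keys,
               resolution = resolution, cutMode = "none",
               parameter = Inf,
               site = bindingSite(colMeans(coords(s)), "experimental"))
}

#' Circular cut: everything within a radius of the site center
#'
#' At residue resolution a residue is kept iff its Calpha lies within
#' \code{r} of the center (inclusive boundary); at atom resolution every
#' atom within \code{r} is kept.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param site a \linkS4class{BindingSite}.
#' @param r radius in Angstrom (>= 0). Default 16, the radius used for
#'   localized baselines.
#' @param resolution \code{"residue"} or \code{"atom"}.
#' @return a \linkS4class{SiteSelection}.
#' @export
selectByRadius <- function(s, site, r = 16, resolution = c("residue", "atom")) {
  resolution <- match.arg(resolution)
  if (r < 0) stop("radius must be >= 0")
  ud <- .unit_distances(s, site, resolution)
  keep <- ud$dist <= r
  if (!any(keep))
    stop("empty descriptor: no unit within radius of the site center")
  methods::new("SiteSelection", structure = s, keys = ud$keys[keep],
               resolution = resolution, cutMode = "radius", parameter = r,
               site = site)
}

#' Count cut: the n units nearest the site center
#'
#' Selection expands from the closest unit outwards until \code{n} units
#' are kept (or the structure is exhausted). Distance ties are broken by
#' file order (chain, residue number, atom index), which makes the cut
#' deterministic.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param site a \linkS4class{BindingSite}.
#' @param n number of residues/atoms to keep (default 100 residues; use
#'   150 for heavy atoms).
#' @param resolution \code{"residue"} or \code{"atom"}.
#' @return a \linkS4class{SiteSelection}; keys are in distance order.
#' @export
selectByCount <- function(s, site, n = 100, resolution = c("residue", "atom")) {
  resolution <- match.arg(resolution)
  if (n < 1) stop("n must be >= 1")
  ud <- .unit_distances(s, site, resolution)
  ord <- order(ud$dist, seq_along(ud$dist), method = "radix")
  keep <- ord[seq_len(min(n, length(ord)))]
  methods::new("SiteSelection", structure = s, keys = ud$keys[keep],
               resolution = resolution, cutMode = "count", parameter = n,
               site = site)
}

#' Draw a random binding-site center (control condition)
#'
#' Samples uniformly among the structure's Calpha positions. Serves as
#' the negative control for the localized descriptor: with random
#' centers the local region no longer covers the catalytic chemistry and
#' classification should degrade.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param seed integer seed.
#' @return a \linkS4class{BindingSite} with source \code{"random"}.
#' @export
randomCenter <- function(s, seed = 1L) {
  ca <- calpha_table(s)
  i <- with_seed(seed, sample.int(nrow(ca), 1L))
  bindingSite(c(ca$x[i], ca$y[i], ca$z[i]), source = "random")
}

#' Read / write a binding-site table
#'
#' CSV dialect: columns \code{structure_id}, \code{rank},
#' \code{center_x}, \code{center_y}, \code{center_z}, \code{source},
#' \code{score}. Consumers take rank-1 sites by default.
#'
#' @param path CSV file.
#' @return named list of lists of \linkS4class{BindingSite}, one entry
#'   per structure id, sites sorted by rank.
#' @export
readSiteTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure_id", "rank", "center_x", "center_y", "center_z")
  if (!all(need %in% names(tab)))
    stop("dialect error: site table misses columns ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (is.null(tab$source)) tab$source <- "experimental"
  if (is.null(tab$score)) tab$score <- NA_real_
  out <- split(tab, tab$structure_id)
  lapply(out, function(g) {
    g <- g[order(g$rank), , drop = FALSE]
    lapply(seq_len(nrow(g)), function(i)
      bindingSite(c(g$center_x[i], g$center_y[i], g$center_z[i]),
                  g$source[i], g$rank[i], g$score[i]))
  })
}

#' @rdname readSiteTable
#' @param sites named list (structure_id -> list of BindingSite).
#' @export
writeSiteTable <- function(sites, path) {
  rows <- do.call(rbind, lapply(names(sites), function(id) {
    do.call(rbind, lapply(sites[[id]], function(b)
      data.frame(structure_id = id, rank = b@rank,
                 center_x = b@center[1], center_y = b@center[2],
                 center_z = b@center[3], source = b@source,
                 score = b@score, stringsAsFactors = FALSE)))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
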