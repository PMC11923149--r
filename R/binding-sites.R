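# Binding-site ingestion: pocket-prediction tables and homolog-transfer
# of ligand locations onto modeled structures.

#' Parse a pocket-prediction table
#'
#' Accepts CSV with columns including \code{rank} and center coordinates
#' (either \code{center_x/y/z} or the \code{center_x}-style names used
#' by pocket predictors, with surrounding whitespace tolerated). Sites
#' come back sorted by rank with source \code{"predicted"}; downstream
#' consumers take the rank-1 site by default.
#'
#' @param text CSV text or a file path.
#' @return list of \linkS4class{BindingSite}, sorted by rank (empty
#'   list for a table with zero rows; the caller decides whether a
#'   structure without predicted pockets is dropped).
#' @export
parsePocketTable <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    tab <- utils::read.csv(text, stringsAsFactors = FALSE,
                           strip.white = TRUE)
  else
    tab <- utils::read.csv(text = paste(text, collapse = "\n"),
                           stringsAsFactors = FALSE, strip.white = TRUE)
  names(tab) <- trimws(tolower(names(tab)))
  cx <- intersect(c("center_x", "x"), names(tab))[1L]
  cy <- intersect(c("center_y", "y"), names(tab))[1L]
  cz <- intersect(c("center_z", "z"), names(tab))[1L]
  if (!"rank" %in% names(tab) || is.na(cx) || is.na(cy) || is.na(cz))
    stop("dialect error: pocket table needs rank and center_x/y/z columns")
  if (nrow(tab) == 0L) return(list())
  tab <- tab[order(tab$rank), , drop = FALSE]
  score <- if ("score" %in% names(tab)) tab$score else rep(NA_real_, nrow(tab))
  lapply(seq_len(nrow(tab)), function(i)
    bindingSite(c(tab[[cx]][i], tab[[cy]][i], tab[[cz]][i]),
                source = "predicted", rank = tab$rank[i], score = score[i]))
}

#' Least-squares rigid superposition (fixture utility)
#'
#' Kabsch fit of \code{mobile} onto \code{target} over given point
#' correspondences; returns a proper rotation and translation with
#' minimal RMSD. Provided so tests can construct homolog hits without an
#' external structure-alignment tool.
#'
#' @param mobile,target n x 3 matrices of corresponding points.
#' @return list with \code{R} (3 x 3, det +1), \code{t} (length 3) such
#'   that \code{mobile \%*\% R + t} approximates \code{target}, and
#'   \code{rmsd}.
#' @export
rigidSuperpose <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2L, cm)
  B <- sweep(target, 2L, ct)
  sv <- svd(crossprod(A, B))
  d <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tv <- ct - as.numeric(cm %*% Rm)
  fitted <- mobile %*% Rm + matrix(tv, nrow(mobile), 3L, byrow = TRUE)
  list(R = Rm, t = tv, rmsd = sqrt(mean(rowSums((fitted - target)^2))))
}

#' Default excluded-ligand list
#'
#' Common crystallization additives whose positions say nothing about
#' catalysis (glycerol, ethylene glycol, sulfate, phosphate, PEG
#' fragments, ...). Users can extend or replace the list.
#'
#' @return character vector of 3-letter ligand codes.
#' @export
defaultExcludedLigands <- function() {
  path <- system.file("extdata", "excluded_ligands.tsv", package = "pocketec")
  if (nzchar(path)) utils::read.delim(path)$ligand
  else c("GOL", "EDO", "SO4", "PO4", "PEG", "PG4", "PGE", "MPD", "DMS",
         "ACT", "TRS", "EPE", "MES", "FMT", "NO3", "CIT", "BME", "IMD")
}

#' Transfer binding sites from ligand-bearing homologs
#'
#' Homologs superposed onto the target with an alignment score above
#' \code{scoreMin} (strict) contribute their ligand centroids, mapped
#' through the superposition into the target frame. Common
#' crystallization ligands are filtered out. Mapped centroids within
#' \code{overlapRadius} of each other merge into one candidate location
#' (center = mean of members); locations are ranked by descending
#' member count, ties by best alignment score.
#'
#' @param target the \linkS4class{ProteinStructure} to annotate (used
#'   for provenance only; transforms must already map into its frame).
#' @param hits list of homolog hits, each a list with \code{R} (3 x 3
#'   proper rotation), \code{t} (length-3 translation), \code{score} in
#'   [0, 1], and \code{ligands}: data.frame with columns \code{name},
#'   \code{x}, \code{y}, \code{z} (heavy-atom centroid in the homolog
#'   frame).
#' @param scoreMin minimum alignment score, exclusive (default 0.5).
#' @param excludedLigands ligand codes to ignore.
#' @param overlapRadius merge radius between mapped centroids (Angstrom,
#'   default 4).
#' @return ranked list of \linkS4class{BindingSite} with source
#'   \code{"transferred"}; empty list with a warning when nothing
#'   survives filtering.
#' @export
transferSites <- function(target, hits, scoreMin = 0.5,
                          excludedLigands = defaultExcludedLigands(),
                          overlapRadius = 4) {
  pts <- list()
  for (h in hits) {
    if (h$score <= scoreMin) next
    lg <- h$ligands
    lg <- lg[!(toupper(lg$name) %in% toupper(excludedLigands)), , drop = FALSE]
    if (!nrow(lg)) next
    mapped <- as.matrix(lg[, c("x", "y", "z")]) %*% h$R +
      matrix(h$t, nrow(lg), 3L, byrow = TRUE)
    for (i in seq_len(nrow(lg)))
      pts[[length(pts) + 1L]] <- list(xyz = mapped[i, ], score = h$score)
  }
  if (!length(pts)) {
    warning("no transferable site: no ligand survives score and name filters")
    return(list())
  }
  # single-linkage merge of centroids within overlapRadius
  xyz <- do.call(rbind, lapply(pts, `[[`, "xyz"))
  n <- nrow(xyz)
  comp <- seq_len(n)
  if (n > 1L) {
    dm <- as.matrix(stats::dist(xyz))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (dm[i, j] <= overlapRadius) {
        old <- comp[j]; comp[comp == old] <- comp[i]
      }
    }
  }
  groups <- split(seq_len(n), comp)
  locs <- lapply(groups, function(ix) list(
    center = colMeans(xyz[ix, , drop = FALSE]),
    count = length(ix),
    best = max(vapply(pts[ix], `[[`, numeric(1), "score"))))
  ord <- order(-vapply(locs, `[[`, numeric(1), "count"),
               -vapply(locs, `[[`, numeric(1), "best"))
  lapply(seq_along(ord), function(r) {
    l <- locs[[ord[r]]]
    bindingSite(l$center, source = "transferred", rank = r, score = l$best)
  })
}
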