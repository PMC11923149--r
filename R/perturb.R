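# Structure perturbation experiments: alanine scanning and coordinate
# translation sweeps over a trained model.

#' Build descriptor graphs for a dataset
#'
#' Applies the count or radius cut around each entry's binding site and
#' builds labeled graphs, the shared path for training, evaluation and
#' the perturbation sweeps.
#'
#' @param dataset list of entries with elements \code{structure}
#'   (\linkS4class{ProteinStructure}), \code{site}
#'   (\linkS4class{BindingSite}) and \code{label} (integer class).
#' @param scheme an \linkS4class{AnnotationScheme}.
#' @param resolution \code{"residue"} or \code{"atom"}.
#' @param cut \code{"count"} or \code{"radius"}.
#' @param parameter count n or radius r.
#' @param neighborRadius,maxNeighbors edge construction settings.
#' @return list of \linkS4class{ProteinGraph}.
#' @export
datasetGraphs <- function(dataset, scheme, resolution = "residue",
                          cut = "count", parameter = 30,
                          neighborRadius = 10, maxNeighbors = 16L) {
  lapply(dataset, function(e) {
    sel <- if (cut == "count")
      selectByCount(e$structure, e$site, parameter, resolution)
    else selectByRadius(e$structure, e$site, parameter, resolution)
    buildGraph(sel, scheme, neighborRadius, maxNeighbors, label = e$label)
  })
}

# mutate a random fraction of residues to alanine (uniform, without
# replacement, per structure)
.mutate_fraction <- function(s, fraction, seed) {
  if (fraction <= 0) return(s)
  keys <- residueKeys(s)
  k <- round(fraction * length(keys))
  if (k == 0L) return(s)
  sel <- with_seed(seed, sample(keys, k))
  mutateToAlanine(s, sel)
}

#' Perturbation sweep over a trained model
#'
#' For each level of the grid, perturbs every structure (random-fraction
#' alanine mutation or coordinate translation of the given amplitude),
#' rebuilds descriptors and graphs, and re-evaluates the model. Level 0
#' reproduces the baseline evaluation exactly. Residues to mutate are
#' drawn uniformly without replacement with a fresh seed per level and
#' structure.
#'
#' @param model a trained \linkS4class{GraphClassifier}.
#' @param dataset as in \code{\link{datasetGraphs}}.
#' @param kind \code{"alanine_fraction"} (grid = fractions in [0, 1]) or
#'   \code{"translation"} (grid = amplitudes in Angstrom).
#' @param grid ascending perturbation levels.
#' @param seed integer seed.
#' @param scheme annotation scheme.
#' @param replicates independent perturbation draws per level; metrics
#'   are averaged over draws (several draws tighten the per-level
#'   estimate when the perturbation effect is small relative to the
#'   test-set quantization).
#' @param ... passed to \code{\link{datasetGraphs}}.
#' @return list with \code{curve} (data.frame level, accuracy,
#'   mean_aupr, median_aupr) and \code{spearman} (rank correlation of
#'   level vs accuracy and vs mean AUPR; 0 when the metric is constant
#'   across the grid).
#' @export
perturbationSweep <- function(model, dataset,
                              kind = c("alanine_fraction", "translation"),
                              grid, seed = 1L,
                              scheme = defaultAnnotationScheme(),
                              replicates = 1L, ...) {
  kind <- match.arg(kind)
  if (is.unsorted(grid)) stop("grid must be ascending")
  rows <- lapply(seq_along(grid), function(li) {
    level <- grid[li]
    reps <- lapply(seq_len(if (level > 0) replicates else 1L), function(ri) {
      pert <- lapply(seq_along(dataset), function(si) {
        e <- dataset[[si]]
        sseed <- (seed * 1009L + li * 7919L + ri * 4241L +
                    si * 97L) %% 2147483647L
        s <- if (kind == "alanine_fraction")
          .mutate_fraction(e$structure, level, sseed)
        else if (level > 0) perturbCoordinates(e$structure, level, sseed)
        else e$structure
        list(structure = s, site = e$site, label = e$label)
      })
      graphs <- datasetGraphs(pert, scheme, ...)
      ev <- evaluateClassifier(model, graphs)
      c(accuracy = ev$accuracy,
        mean_aupr = mean(ev$aupr$perClass, na.rm = TRUE),
        median_aupr = stats::median(ev$aupr$perClass, na.rm = TRUE))
    })
    avg <- colMeans(do.call(rbind, reps))
    data.frame(level = level, accuracy = avg[["accuracy"]],
               mean_aupr = avg[["mean_aupr"]],
               median_aupr = avg[["median_aupr"]])
  })
  curve <- do.call(rbind, rows)
  sp <- function(y) {
    if (stats::sd(y) == 0) return(0)
    stats::cor(grid, y, method = "spearman")
  }
  list(curve = curve,
       spearman = list(accuracy = sp(curve$accuracy),
                       mean_aupr = sp(curve$mean_aupr)))
}
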