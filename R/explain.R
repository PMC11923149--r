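# Node-softmask explanation of a trained classifier.
#
# Instead of searching for an explanatory subgraph, a soft mask F in
# [0, 1] per node multiplies the node's type embedding; F is optimized
# to keep the model's prediction for the target class while penalizing
# mask size (beta1 * mean(F)) and mask entropy
# (beta2 * mean(H(F)) with H = -F log(F + c) - (1 - F) log(1 - F + c)).
# Edge masks are deliberately not used: graph edges encode spatial
# neighborhood, not chemical bonds, so an edge explanation would not be
# chemically interpretable. The converged mask is the node importance.

#' Binary entropy of mask values with a log guard
#'
#' \code{H = -F log(F + c) - (1 - F) log(1 - F + c)} elementwise, where
#' c is a small positive constant that avoids log(0). Maximal (ln 2) at
#' F = 0.5, ~0 at saturated masks; penalizing it pushes mask values
#' toward 0 or 1.
#'
#' @param F mask values in [0, 1].
#' @param c small positive guard constant.
#' @param reduce \code{"mean"}, \code{"sum"} or \code{"none"}.
#' @return reduced entropy (or the elementwise vector).
#' @export
entropyTerm <- function(F, c = 1e-15, reduce = c("mean", "sum", "none")) {
  reduce <- match.arg(reduce)
  if (c <= 0) stop("c must be > 0")
  h <- -F * log(F + c) - (1 - F) * log(1 - F + c)
  switch(reduce, mean = mean(h), sum = sum(h), none = h)
}

# d/dF of the guarded binary entropy
.entropy_grad <- function(F, c) {
  -log(F + c) - F / (F + c) + log(1 - F + c) + (1 - F) / (1 - F + c)
}

#' Explainer configuration
#'
#' @param beta1 mask-size penalty weight (higher -> sparser masks).
#' @param beta2 mask-entropy penalty weight (higher -> more binary
#'   masks).
#' @param c entropy log guard.
#' @param steps maximum accepted optimization steps.
#' @param stepSize initial gradient step on the mask logits; each step
#'   backtracks (halving) until the objective decreases, so the
#'   objective trace is non-increasing by construction.
#' @param initMask initial mask value (sigmoid-parameterized).
#' @param seed integer seed.
#' @return config list.
#' @export
explainerConfig <- function(beta1 = 0.05, beta2 = 0.1, c = 1e-15,
                            steps = 150L, stepSize = 0.25, initMask = 0.5,
                            seed = 1L) {
  stopifnot(c > 0, steps >= 1L)
  list(beta1 = beta1, beta2 = beta2, c = c, steps = as.integer(steps),
       stepSize = stepSize, initMask = initMask, seed = as.integer(seed))
}

#' Softmask node importance for one graph
#'
#' Optimizes a per-node mask on the type embeddings by gradient descent
#' with backtracking on the objective
#' \code{l(y, yhat) + beta1 mean(F) + beta2 mean(H(F))}, where l is the
#' cross-entropy of the masked prediction against the target class.
#' The converged mask is returned as raw importance together with its
#' min-max normalization.
#'
#' @param model a trained \linkS4class{GraphClassifier}.
#' @param g a \linkS4class{ProteinGraph}.
#' @param targetClass integer class index to explain; default the
#'   model's own prediction. Explaining a class the model does not
#'   predict at full mask raises a warning but still runs.
#' @param cfg an \code{\link{explainerConfig}}.
#' @return a \linkS4class{NodeImportance}.
#' @export
softmaskExplain <- function(model, g, targetClass = NULL,
                            cfg = explainerConfig()) {
  batch <- .as_batch(g)
  n <- nrow(batch@positions)
  flags <- character(0)
  base <- forwardLogits(model, batch)
  basePred <- which.max(base[1L, ])
  if (is.null(targetClass)) targetClass <- basePred
  if (targetClass != basePred) {
    warning("explaining a non-predicted class")
    flags <- c(flags, "explaining a non-predicted class")
  }
  lossFn <- function(logits) {
    lg <- .wce_grad(logits, targetClass, rep(1, ncol(logits)))
    list(loss = lg$loss, dlogits = lg$dlogits)
  }
  theta <- rep(stats::qlogis(cfg$initMask), n)  # mask logits
  objective <- function(Fv, predLoss)
    predLoss + cfg$beta1 * mean(Fv) + cfg$beta2 * entropyTerm(Fv, cfg$c)
  Fv <- sigmoid(theta)
  gr <- mask_gradient(model, batch, Fv, lossFn)
  obj <- objective(Fv, gr$loss)
  trace <- obj
  for (it in seq_len(cfg$steps)) {
    # total gradient w.r.t. theta through F = sigmoid(theta)
    dF <- gr$grad + cfg$beta1 / n + cfg$beta2 * .entropy_grad(Fv, cfg$c) / n
    dtheta <- dF * Fv * (1 - Fv)
    step <- cfg$stepSize
    accepted <- FALSE
    for (bt in 1:12) {
      cand <- theta - step * dtheta
      Fc <- sigmoid(cand)
      grc <- mask_gradient(model, batch, Fc, lossFn)
      objc <- objective(Fc, grc$loss)
      if (objc < obj) {
        theta <- cand; Fv <- Fc; gr <- grc; obj <- objc
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    trace <- c(trace, obj)
  }
  ni <- normalizeImportance(Fv, mapping = .node_mapping(g))
  methods::initialize(ni, trace = trace, flags = c(flags, ni@flags))
}

.node_mapping <- function(g) {
  if (!methods::is(g, "ProteinGraph") || is.null(g@provenance$keys))
    return(data.frame(node = seq_len(if (methods::is(g, "ProteinGraph"))
      nrow(g@positions) else 0L)))
  keys <- g@provenance$keys
  if (is.character(keys)) {
    parts <- strsplit(keys, "|", fixed = TRUE)
    data.frame(node = seq_along(keys),
               chain = vapply(parts, `[`, character(1), 1L),
               residue = vapply(parts, `[`, character(1), 2L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(node = seq_along(keys), atom_row = keys)
  }
}

#' Min-max normalize raw node importance
#'
#' Per-structure min-max normalization to [0, 1]. A constant raw vector
#' is mapped to 0.5 everywhere and flagged (a single node to 1.0 by
#' convention). Atom-level values can be aggregated to residues with
#' \code{\link{aggregateImportance}}.
#'
#' @param raw per-node raw importance.
#' @param mapping optional node-identity data.frame carried along.
#' @return a \linkS4class{NodeImportance}.
#' @export
normalizeImportance <- function(raw, mapping = data.frame(node = seq_along(raw))) {
  if (!length(raw)) stop("need at least one node")
  flags <- character(0)
  if (length(raw) == 1L) {
    norm <- 1
    flags <- "single node: importance 1.0 by convention"
  } else if (max(raw) - min(raw) < 1e-12) {
    norm <- rep(0.5, length(raw))
    flags <- "constant raw importance: normalized to 0.5"
  } else {
    norm <- (raw - min(raw)) / (max(raw) - min(raw))
  }
  methods::new("NodeImportance", raw = as.numeric(raw),
               normalized = as.numeric(norm), mapping = mapping,
               trace = numeric(0), flags = flags)
}

#' Aggregate atom-level importance to residues
#'
#' @param ni a \linkS4class{NodeImportance} whose mapping identifies the
#'   residue of each node (columns \code{chain}, \code{residue} or a
#'   \code{residue_key} column).
#' @param keys residue key per node (overrides the mapping).
#' @param mode \code{"max"} (default) or \code{"mean"}.
#' @return named numeric vector residue key -> aggregated importance.
#' @export
aggregateImportance <- function(ni, keys = NULL, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  if (is.null(keys)) {
    m <- ni@mapping
    keys <- if (!is.null(m$residue_key)) m$residue_key
            else paste0(m$chain, "|", m$residue)
  }
  fn <- if (mode == "max") max else mean
  vapply(split(ni@normalized, keys), fn, numeric(1))
}

#' Write importance values to CSV or a PDB B-factor column
#'
#' The PDB writer places normalized importance in the B-factor field of
#' every atom of the mapped residue, for coloring in a molecular viewer.
#'
#' @param ni a \linkS4class{NodeImportance}.
#' @param path output file.
#' @param structureId id recorded in the CSV.
#' @export
writeImportanceCSV <- function(ni, path, structureId = "structure") {
  df <- cbind(structure_id = structureId, ni@mapping,
              raw = ni@raw, normalized = ni@normalized)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeImportanceCSV
#' @param s the \linkS4class{ProteinStructure} the nodes map into.
#' @export
writeImportancePDB <- function(ni, s, path) {
  a <- atoms(s)
  key <- paste0(a$chain_id, "|", a$residue_seq, a$insert)
  res_imp <- aggregateImportance(ni)
  b <- res_imp[key]
  b[is.na(b)] <- 0
  lines <- writeStructure(s)
  atom_lines <- grepl("^ATOM", lines)
  lines[atom_lines] <- paste0(substr(lines[atom_lines], 1L, 60L),
                              sprintf("%6.2f", b),
                              substr(lines[atom_lines], 67L, 80L))
  writeLines(lines, path)
  invisible(path)
}
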