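# User-facing model construction, forward pass, prediction, EC
# hierarchy handling, and checkpoints.

.default_config <- function(architecture, vocabSize, nClasses) {
  base <- list(vocabSize = as.integer(vocabSize),
               nClasses = as.integer(nClasses),
               embeddingDim = 128L, nGaussians = 50L, cutoff = 15,
               gamma = 10, maxNeighbors = 32L, dropout = 0.25,
               pooling = "sum")
  if (architecture == "distances") {
    base$nInteractions <- 6L
  } else {
    base$nBlocks <- 4L
    base$basisEmbedding <- 8L
    base$interactionEmbedding <- 64L
    base$outputEmbedding <- 256L
    base$numSpherical <- 7L
    base$numRadial <- 6L
    base$dropout <- 0
  }
  base
}

#' Construct a message-passing EC classifier
#'
#' \code{"distances"} is the continuous-filter convolution network (six
#' interaction blocks, 128-dim embeddings and filters, 50 Gaussians by
#' default); \code{"distances_angles"} the directional network (four
#' embedding+interaction building blocks, basis embedding 8, interaction
#' embedding 64, output embedding 256, seven spherical harmonics and six
#' radial Fourier-Bessel functions). All dimensions can be overridden
#' through \code{...}; smaller settings are appropriate for desk-scale
#' experiments.
#'
#' @param architecture \code{"distances"} or \code{"distances_angles"}.
#' @param classVocab character vector of class labels (dotted EC strings
#'   or arbitrary names); its length fixes the logit dimension.
#' @param scheme the \linkS4class{AnnotationScheme} graphs were built
#'   with (fixes the node-type vocabulary size per resolution).
#' @param resolution \code{"residue"} or \code{"atom"} (selects the
#'   relevant vocabulary size).
#' @param seed seed for parameter initialization.
#' @param ... config overrides (e.g. \code{embeddingDim = 64},
#'   \code{nInteractions = 3}, \code{cutoff = 10}).
#' @return a \linkS4class{GraphClassifier} with random weights.
#' @export
graphClassifier <- function(architecture = c("distances", "distances_angles"),
                            classVocab, scheme = defaultAnnotationScheme(),
                            resolution = c("residue", "atom"),
                            seed = 1L, ...) {
  architecture <- match.arg(architecture)
  resolution <- match.arg(resolution)
  vocabSize <- if (resolution == "residue") length(scheme@residueVocab)
               else length(scheme@heavyAtomVocab)
  cfg <- .default_config(architecture, vocabSize, length(classVocab))
  over <- list(...)
  cfg[names(over)] <- over
  cfg$resolution <- resolution
  params <- with_seed(seed, {
    if (architecture == "distances") init_distances_params(cfg)
    else init_dimenet_params(cfg)
  })
  methods::new("GraphClassifier", architecture = architecture, config = cfg,
               params = params, classVocab = as.character(classVocab),
               schemeVersion = scheme@version)
}

.as_batch <- function(g) {
  if (methods::is(g, "GraphBatch")) g else batchGraphs(list(g))
}

#' Forward pass: logits for one graph or a batch
#'
#' Deterministic in eval mode (\code{training = FALSE}); dropout is only
#' active during training. Logits are invariant under rigid motions of
#' the input (geometry enters through distances and angles only) and
#' under node permutations (sum pooling).
#'
#' @param model a \linkS4class{GraphClassifier}.
#' @param g a \linkS4class{ProteinGraph} or \linkS4class{GraphBatch}.
#' @param mask optional per-node multiplier on the type embeddings
#'   (softmask explanations).
#' @param training enable dropout.
#' @return G x C matrix of logits.
#' @export
forwardLogits <- function(model, g, mask = NULL, training = FALSE) {
  batch <- .as_batch(g)
  if (max(batch@types) > model@config$vocabSize)
    stop("config error: node types exceed the model's vocabulary")
  if (model@architecture == "distances")
    forward_distances(model@params, model@config, batch, mask = mask,
                      training = training)$logits
  else
    forward_dimenet(model@params, model@config, batch, mask = mask)$logits
}

#' Split an EC designation into its hierarchy levels
#'
#' A four-level dotted EC string is truncated from the right: e.g. a
#' protein-tyrosine kinase designated 2.7.10.1 is a transferase (main
#' class 2) transferring phosphorus-containing groups (subclass 2.7) as
#' a protein-tyrosine kinase (sub-subclass 2.7.10).
#'
#' @param ec dotted EC string(s).
#' @param level one of \code{"main"}, \code{"sub"}, \code{"subsub"},
#'   \code{"designation"}.
#' @return truncated EC string(s).
#' @export
ecTruncate <- function(ec, level = c("main", "sub", "subsub", "designation")) {
  level <- match.arg(level)
  k <- c(main = 1L, sub = 2L, subsub = 3L, designation = 4L)[[level]]
  vapply(strsplit(ec, ".", fixed = TRUE), function(p)
    paste(p[seq_len(min(k, length(p)))], collapse = "."), character(1))
}

#' Predict the EC label from logits
#'
#' Softmax over the class vocabulary; the argmax class is reported with
#' its softmax confidence, plus all four truncation levels of the
#' predicted designation. Exact ties at the argmax resolve to the lowest
#' class index and are flagged.
#'
#' @param logits numeric vector (length C) or G x C matrix.
#' @param vocab character class vocabulary, length C.
#' @return data.frame with columns \code{label}, \code{confidence},
#'   \code{main}, \code{sub}, \code{subsub}, \code{tie}.
#' @export
predictEC <- function(logits, vocab) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  if (ncol(logits) != length(vocab))
    stop("vocab length must equal the number of logit columns")
  sm <- exp(logits - apply(logits, 1L, max))
  sm <- sm / rowSums(sm)
  idx <- apply(logits, 1L, which.max)
  tie <- apply(logits, 1L, function(r) sum(r == max(r)) > 1L)
  if (any(tie)) warning("argmax tie: lowest class index reported")
  lab <- vocab[idx]
  data.frame(label = lab,
             confidence = sm[cbind(seq_len(nrow(sm)), idx)],
             main = ecTruncate(lab, "main"),
             sub = ecTruncate(lab, "sub"),
             subsub = ecTruncate(lab, "subsub"),
             tie = tie, stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' Self-describing: parameters, architecture, configuration, class
#' vocabulary and annotation-scheme version are stored together.
#' Loading refuses a checkpoint whose class vocabulary or scheme version
#' does not match the expectation.
#'
#' @param model a \linkS4class{GraphClassifier}.
#' @param path file path.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(architecture = model@architecture, config = model@config,
               params = model@params, classVocab = model@classVocab,
               schemeVersion = model@schemeVersion, format = 1L), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @param expectVocab optional class vocabulary that must match.
#' @param expectScheme optional scheme version that must match.
#' @export
loadCheckpoint <- function(path, expectVocab = NULL, expectScheme = NULL) {
  ck <- readRDS(path)
  if (!is.null(expectVocab) && !identical(ck$classVocab, expectVocab))
    stop("checkpoint refused: class vocabulary mismatch")
  if (!is.null(expectScheme) && !identical(ck$schemeVersion, expectScheme))
    stop("checkpoint refused: annotation scheme mismatch")
  methods::new("GraphClassifier", architecture = ck$architecture,
               config = ck$config, params = ck$params,
               classVocab = ck$classVocab, schemeVersion = ck$schemeVersion)
}

# gradient of a scalar loss w.r.t. the node mask. Analytic for the
# distances architecture; central finite differences otherwise.
mask_gradient <- function(model, batch, mask, lossFn) {
  if (model@architecture == "distances") {
    fw <- forward_distances(model@params, model@config, batch, mask = mask,
                            keepCache = TRUE)
    lg <- lossFn(fw$logits)
    bw <- backward_distances(model@params, model@config, batch, fw$cache,
                             lg$dlogits, maskGrad = TRUE)
    list(loss = lg$loss, grad = bw$dmask)
  } else {
    f0 <- lossFn(forward_dimenet(model@params, model@config, batch,
                                 mask = mask)$logits)$loss
    eps <- 1e-4
    grad <- vapply(seq_along(mask), function(i) {
      up <- mask; up[i] <- up[i] + eps
      dn <- mask; dn[i] <- dn[i] - eps
      fu <- lossFn(forward_dimenet(model@params, model@config, batch,
                                   mask = up)$logits)$loss
      fd <- lossFn(forward_dimenet(model@params, model@config, batch,
                                   mask = dn)$logits)$loss
      (fu - fd) / (2 * eps)
    }, numeric(1))
    list(loss = f0, grad = grad)
  }
}
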