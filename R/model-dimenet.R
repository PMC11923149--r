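# Directional message-passing classifier (distances + angles).
#
# Messages live on directed edges. An embedding block initializes each
# message from the two endpoint type embeddings and a radial expansion
# of the edge length; interaction blocks update message m_ji by
# aggregating incoming messages m_kj modulated by the radial basis of
# the j-i distance and a spherical Fourier-Bessel expansion of the k-j
# distance and the angle at j. Following the efficiency variant of
# directional message passing, basis representations are transformed by
# small linear maps and combined with messages by Hadamard products
# (no bilinear layer), with down-/up-projections around the triplet
# aggregation. Every block (embedding + interactions) feeds an output
# block; the per-node outputs of all blocks are summed into logits.

init_dimenet_params <- function(cfg) {
  F <- cfg$embeddingDim; K <- cfg$nGaussians; C <- cfg$nClasses
  S <- cfg$numSpherical * cfg$numRadial
  BE <- cfg$basisEmbedding; IE <- cfg$interactionEmbedding
  OE <- cfg$outputEmbedding
  p <- list(embed = .rnorm_mat(cfg$vocabSize, F, 0.5),
            emb.Wrbf = .rnorm_mat(K, F, 1 / sqrt(K)),
            emb.W = .rnorm_mat(3L * F, F, 1 / sqrt(3 * F)),
            emb.b = numeric(F))
  for (l in seq_len(cfg$nBlocks)) {
    pre <- paste0("i", l, ".")
    p[[paste0(pre, "Wrbf")]] <- .rnorm_mat(K, F, 1 / sqrt(K))
    p[[paste0(pre, "Wsbf1")]] <- .rnorm_mat(S, BE, 1 / sqrt(S))
    p[[paste0(pre, "Wsbf2")]] <- .rnorm_mat(BE, IE, 1 / sqrt(BE))
    p[[paste0(pre, "Wdown")]] <- .rnorm_mat(F, IE, 1 / sqrt(F))
    p[[paste0(pre, "Wup")]] <- .rnorm_mat(IE, F, 1 / sqrt(IE))
    p[[paste0(pre, "W1")]] <- .rnorm_mat(F, F, 1 / sqrt(F))
    p[[paste0(pre, "W2")]] <- .rnorm_mat(F, F, 1 / sqrt(F))
    p[[paste0(pre, "b")]] <- numeric(F)
  }
  for (l in seq_len(cfg$nBlocks + 1L)) {
    pre <- paste0("o", l, ".")
    p[[paste0(pre, "Wrbf")]] <- .rnorm_mat(K, F, 1 / sqrt(K))
    p[[paste0(pre, "W1")]] <- .rnorm_mat(F, OE, 1 / sqrt(F))
    p[[paste0(pre, "b1")]] <- numeric(OE)
    p[[paste0(pre, "W2")]] <- .rnorm_mat(OE, C, 1 / sqrt(OE))
    p[[paste0(pre, "b2")]] <- numeric(C)
  }
  p
}

#' One directional message update
#'
#' Updates each message \code{m_ji} from the incoming messages
#' \code{m_kj} of its triplets: incoming messages are down-projected,
#' modulated (Hadamard) by the transformed spherical basis of the
#' triplet, summed over k, up-projected, and combined with the
#' radial-basis-modulated self path; no triplets means an empty
#' directional sum (the self/RBF path alone).
#'
#' @param messages E x F message matrix.
#' @param rbf E x K radial expansion of the j-i edge lengths.
#' @param sbf T x S spherical Fourier-Bessel expansion per triplet.
#' @param triplets data.frame from \code{\link{computeTriplets}}.
#' @param params named list with entries Wrbf, Wsbf1, Wsbf2, Wdown, Wup,
#'   W1, W2, b.
#' @return updated E x F message matrix.
#' @export
dimenetMessageUpdate <- function(messages, rbf, sbf, triplets, params) {
  E <- nrow(messages)
  rbf_f <- rbf %*% params$Wrbf
  mdown <- ssp(messages %*% params$Wdown)
  tsum <- matrix(0, E, ncol(params$Wdown))
  if (nrow(triplets)) {
    sbf_f <- (sbf %*% params$Wsbf1) %*% params$Wsbf2
    contrib <- mdown[triplets$edge_kj, , drop = FALSE] * sbf_f
    tsum <- scatter_sum(contrib, triplets$edge_ji, E)
  }
  tup <- ssp(tsum %*% params$Wup)
  upd <- ssp(sweep((messages * rbf_f) %*% params$W1 + tup %*% params$W2,
                   2L, params$b, "+"))
  messages + upd
}

# full forward pass (eval mode); returns G x C logits
forward_dimenet <- function(params, cfg, batch, mask = NULL) {
  N <- nrow(batch@positions); G <- batch@nGraphs
  ed <- batch@edges
  if (nrow(ed) == 0L) stop("directional network requires edges")
  rbfc <- rbfConfig(cfg$nGaussians, cfg$cutoff, cfg$gamma)
  sbfc <- sbfConfig(cfg$numSpherical, cfg$numRadial, cfg$cutoff)
  d_ji <- edge_lengths(batch@positions, ed)
  rbf <- rbfExpand(d_ji, rbfc)
  tr <- computeTriplets(methods::new("ProteinGraph",
    positions = batch@positions, types = batch@types, edges = ed,
    resolution = "residue", neighborRadius = Inf,
    provenance = list(), schemeVersion = "batch"))
  sbf <- if (nrow(tr))
    sphericalFourierBessel(d_ji[tr$edge_kj], tr$angle, sbfc)
  else matrix(0, 0L, cfg$numSpherical * cfg$numRadial)

  x <- params$embed[batch@types, , drop = FALSE]
  if (!is.null(mask)) x <- x * mask
  je <- ed[, 1L]; ie <- ed[, 2L]
  m <- ssp(sweep(cbind(x[je, , drop = FALSE], x[ie, , drop = FALSE],
                       rbf %*% params$emb.Wrbf) %*% params$emb.W,
                 2L, params$emb.b, "+"))

  out_block <- function(l, m) {
    pre <- paste0("o", l, ".")
    node <- scatter_sum(m * (rbf %*% params[[paste0(pre, "Wrbf")]]), ie, N)
    h <- ssp(sweep(node %*% params[[paste0(pre, "W1")]], 2L,
                   params[[paste0(pre, "b1")]], "+"))
    sweep(h %*% params[[paste0(pre, "W2")]], 2L, params[[paste0(pre, "b2")]], "+")
  }
  nodeLogits <- out_block(1L, m)
  for (l in seq_len(cfg$nBlocks)) {
    pre <- paste0("i", l, ".")
    bp <- list(Wrbf = params[[paste0(pre, "Wrbf")]],
               Wsbf1 = params[[paste0(pre, "Wsbf1")]],
               Wsbf2 = params[[paste0(pre, "Wsbf2")]],
               Wdown = params[[paste0(pre, "Wdown")]],
               Wup = params[[paste0(pre, "Wup")]],
               W1 = params[[paste0(pre, "W1")]],
               W2 = params[[paste0(pre, "W2")]],
               b = params[[paste0(pre, "b")]])
    m <- dimenetMessageUpdate(m, rbf, sbf, tr, bp)
    nodeLogits <- nodeLogits + out_block(l + 1L, m)
  }
  logits <- scatter_sum(nodeLogits, batch@graphIndex, G)
  if (identical(cfg$pooling, "mean"))
    logits <- logits / tabulate(batch@graphIndex, G)
  list(logits = logits)
}
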