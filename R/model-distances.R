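# Continuous-filter convolution classifier over typed 3D graphs.
#
# Type embeddings are refined by interaction blocks; each block generates
# per-edge filters from a Gaussian radial expansion of the interatomic
# distance (two dense layers with shifted-softplus), convolves node
# features with them (Hadamard product, sum over in-neighbors), and
# recombines through atom-wise dense layers with a residual connection.
# A linear + shifted-softplus readout with dropout produces per-node
# class contributions that are sum-pooled per graph. Geometry enters
# only through distances, so logits are invariant under rigid motions by
# construction. Backpropagation is implemented analytically; it drives
# both training and the softmask explainer.

#' Continuous-filter convolution over one edge set
#'
#' \code{x_i' = sum_j x_j o W(d_ij)}: features of in-neighbors j are
#' modulated elementwise by a filter generated from the j-i distance and
#' summed. The filter generator sees positions only through distances,
#' which yields rotational invariance. Nodes without in-edges get a zero
#' row (empty sum).
#'
#' @param nodeFeats N x F feature matrix.
#' @param positions N x 3 coordinates (Angstrom).
#' @param edges E x 2 integer matrix (j, i).
#' @param filterNet function mapping an E x K radial-basis expansion to
#'   an E x F filter matrix.
#' @param cfg an \code{\link{rbfConfig}} used to expand distances.
#' @return N x F convolved features.
#' @export
cfconv <- function(nodeFeats, positions, edges, filterNet,
                   cfg = rbfConfig(cutoff = 15)) {
  n <- nrow(nodeFeats)
  if (nrow(edges) == 0L) return(matrix(0, n, ncol(nodeFeats)))
  filt <- filterNet(rbfExpand(edge_lengths(positions, edges), cfg))
  if (!identical(dim(filt), c(nrow(edges), ncol(nodeFeats))))
    stop("shape error: filter must be E x F")
  scatter_sum(nodeFeats[edges[, 1L], , drop = FALSE] * filt,
              edges[, 2L], n)
}

#' Atom-wise dense layer
#'
#' \code{x_i' = W x_i + b}, the same weights applied to every node
#' (permutation-equivariant feature recombination).
#'
#' @param x N x F features.
#' @param W F x F' weight matrix.
#' @param b length-F' bias.
#' @return N x F' features.
#' @export
atomwise <- function(x, W, b) {
  if (ncol(x) != nrow(W)) stop("shape error: ncol(x) != nrow(W)")
  sweep(x %*% W, 2L, b, "+")
}

.rnorm_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

init_distances_params <- function(cfg) {
  F <- cfg$embeddingDim; K <- cfg$nGaussians; C <- cfg$nClasses
  p <- list(embed = .rnorm_mat(cfg$vocabSize, F, 0.5))
  for (l in seq_len(cfg$nInteractions)) {
    p[[paste0("b", l, ".Wf1")]] <- .rnorm_mat(K, F, 1 / sqrt(K))
    p[[paste0("b", l, ".bf1")]] <- numeric(F)
    p[[paste0("b", l, ".Wf2")]] <- .rnorm_mat(F, F, 1 / sqrt(F))
    p[[paste0("b", l, ".bf2")]] <- numeric(F)
    p[[paste0("b", l, ".Wa1")]] <- .rnorm_mat(F, F, 1 / sqrt(F))
    p[[paste0("b", l, ".ba1")]] <- numeric(F)
    p[[paste0("b", l, ".Wa2")]] <- .rnorm_mat(F, F, 1 / sqrt(F))
    p[[paste0("b", l, ".ba2")]] <- numeric(F)
  }
  p$r.W1 <- .rnorm_mat(F, F, 1 / sqrt(F))
  p$r.b1 <- numeric(F)
  p$r.W2 <- .rnorm_mat(F, C, 1 / sqrt(F))
  p$r.b2 <- numeric(C)
  p
}

# forward pass; batch is a GraphBatch (a single ProteinGraph is wrapped
# upstream). mask: optional per-node multiplier on the type embedding
# (softmask explainer). training: enables inverted dropout before the
# classifier. Returns list(logits = G x C, cache) when keepCache.
forward_distances <- function(params, cfg, batch, mask = NULL,
                              training = FALSE, keepCache = FALSE) {
  N <- nrow(batch@positions); G <- batch@nGraphs
  ed <- batch@edges
  rbfc <- rbfConfig(cfg$nGaussians, cfg$cutoff, cfg$gamma)
  d <- edge_lengths(batch@positions, ed)
  rbf <- if (length(d)) rbfExpand(d, rbfc) else matrix(0, 0L, rbfc$count)
  je <- ed[, 1L]; ie <- ed[, 2L]

  x <- params$embed[batch@types, , drop = FALSE]
  if (!is.null(mask)) x <- x * mask
  x0 <- x
  maskvec <- mask
  blocks <- vector("list", cfg$nInteractions)
  for (l in seq_len(cfg$nInteractions)) {
    p <- function(nm) params[[paste0("b", l, ".", nm)]]
    H1pre <- sweep(rbf %*% p("Wf1"), 2L, p("bf1"), "+")
    H1 <- ssp(H1pre)
    filt <- sweep(H1 %*% p("Wf2"), 2L, p("bf2"), "+")
    conv <- scatter_sum(x[je, , drop = FALSE] * filt, ie, N)
    A1pre <- sweep(conv %*% p("Wa1"), 2L, p("ba1"), "+")
    A1 <- ssp(A1pre)
    xnew <- x + sweep(A1 %*% p("Wa2"), 2L, p("ba2"), "+")
    if (keepCache)
      blocks[[l]] <- list(xin = x, H1pre = H1pre, H1 = H1, filt = filt,
                          conv = conv, A1pre = A1pre, A1 = A1)
    x <- xnew
  }
  R1pre <- sweep(x %*% params$r.W1, 2L, params$r.b1, "+")
  R1 <- ssp(R1pre)
  dropMask <- NULL
  if (training && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    dropMask <- matrix(stats::rbinom(length(R1), 1L, keep) / keep,
                       nrow(R1), ncol(R1))
    R1 <- R1 * dropMask
  }
  nodeLogits <- sweep(R1 %*% params$r.W2, 2L, params$r.b2, "+")
  logits <- scatter_sum(nodeLogits, batch@graphIndex, G)
  if (identical(cfg$pooling, "mean")) {
    cnt <- tabulate(batch@graphIndex, G)
    logits <- logits / cnt
  }
  if (!keepCache) return(list(logits = logits))
  list(logits = logits,
       cache = list(x0 = x0, xfinal = x, blocks = blocks, rbf = rbf,
                    R1pre = R1pre, R1 = R1, dropMask = dropMask,
                    je = je, ie = ie, N = N, maskvec = maskvec))
}

# analytic gradients; dlogits is G x C. Returns list(grads, dmask).
backward_distances <- function(params, cfg, batch, cache, dlogits,
                               maskGrad = FALSE) {
  N <- cache$N
  g <- list()
  dnode <- dlogits[batch@graphIndex, , drop = FALSE]
  if (identical(cfg$pooling, "mean")) {
    cnt <- tabulate(batch@graphIndex, batch@nGraphs)
    dnode <- dnode / cnt[batch@graphIndex]
  }
  g$r.W2 <- crossprod(cache$R1, dnode)
  g$r.b2 <- colSums(dnode)
  dR1 <- dnode %*% t(params$r.W2)
  if (!is.null(cache$dropMask)) dR1 <- dR1 * cache$dropMask
  dR1pre <- dR1 * ssp_grad(cache$R1pre)
  g$r.W1 <- crossprod(cache$xfinal, dR1pre)
  g$r.b1 <- colSums(dR1pre)
  dx <- dR1pre %*% t(params$r.W1)

  je <- cache$je; ie <- cache$ie
  for (l in rev(seq_len(cfg$nInteractions))) {
    p <- function(nm) params[[paste0("b", l, ".", nm)]]
    cb <- cache$blocks[[l]]
    g[[paste0("b", l, ".Wa2")]] <- crossprod(cb$A1, dx)
    g[[paste0("b", l, ".ba2")]] <- colSums(dx)
    dA1 <- dx %*% t(p("Wa2"))
    dA1pre <- dA1 * ssp_grad(cb$A1pre)
    g[[paste0("b", l, ".Wa1")]] <- crossprod(cb$conv, dA1pre)
    g[[paste0("b", l, ".ba1")]] <- colSums(dA1pre)
    dconv <- dA1pre %*% t(p("Wa1"))
    if (length(je)) {
      dmsg <- dconv[ie, , drop = FALSE]
      dfilt <- dmsg * cb$xin[je, , drop = FALSE]
      dxin_msg <- scatter_sum(dmsg * cb$filt, je, N)
      g[[paste0("b", l, ".Wf2")]] <- crossprod(cb$H1, dfilt)
      g[[paste0("b", l, ".bf2")]] <- colSums(dfilt)
      dH1 <- dfilt %*% t(p("Wf2"))
      dH1pre <- dH1 * ssp_grad(cb$H1pre)
      g[[paste0("b", l, ".Wf1")]] <- crossprod(cache$rbf, dH1pre)
      g[[paste0("b", l, ".bf1")]] <- colSums(dH1pre)
    } else {
      dxin_msg <- 0
      g[[paste0("b", l, ".Wf2")]] <- array(0, dim(p("Wf2")))
      g[[paste0("b", l, ".bf2")]] <- numeric(length(p("bf2")))
      g[[paste0("b", l, ".Wf1")]] <- array(0, dim(p("Wf1")))
      g[[paste0("b", l, ".bf1")]] <- numeric(length(p("bf1")))
    }
    dx <- dx + dxin_msg          # residual + message path
  }
  # dx is the gradient w.r.t. the (possibly masked) embedding rows:
  # with x0 = mask * embed[type], d embed picks up the mask factor and
  # d mask the embedding row
  dx_embed <- if (is.null(cache$maskvec)) dx else dx * cache$maskvec
  g$embed <- scatter_sum(dx_embed, batch@types, cfg$vocabSize)
  dmask <- NULL
  if (maskGrad)
    dmask <- rowSums(dx * params$embed[batch@types, , drop = FALSE])
  list(grads = g, dmask = dmask, dx0 = dx)
}
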