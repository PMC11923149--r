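test_that("the Gaussian radial expansion matches its closed form", {
  cfg <- rbfConfig(count = 16, cutoff = 15, gamma = 10)
  # at a center the component is exactly 1
  e <- rbfExpand(cfg$centers[5], cfg)
  expect_identical(e[1, 5], 1)
  # gamma = 10, offset 0.1: exp(-10 * 0.01) = exp(-0.1)
  e2 <- rbfExpand(cfg$centers[5] + 0.1, cfg)
  expect_equal(e2[1, 5], exp(-0.1), tolerance = 1e-12)
  # 3 Angstrom off-center the Gaussian tail is numerically zero
  cfg2 <- rbfConfig(count = 4, cutoff = 3, gamma = 10)
  expect_lt(rbfExpand(3, cfg2)[1, 1], 1e-39)
  expect_error(rbfExpand(-1, cfg), ">= 0")
  # dense published grid: 301 centers 0..30 every 0.1
  expect_length(rbfConfig(grid = TRUE)$centers, 301L)
})

test_that("cfconv equals a dense double-loop reference and handles isolated nodes", {
  set.seed(21)
  n <- 6; F <- 5
  g <- random_graph(n = n, seed = 3, radius = 4, maxNeighbors = 4)
  x <- matrix(rnorm(n * F), n, F)
  cfg <- rbfConfig(count = 7, cutoff = 6)
  W <- matrix(rnorm(7 * F, sd = 0.3), 7, F)
  fnet <- function(rbf) rbf %*% W
  out <- cfconv(x, g@positions, g@edges, fnet, cfg)
  ref <- matrix(0, n, F)
  for (e in seq_len(nrow(g@edges))) {
    j <- g@edges[e, 1]; i <- g@edges[e, 2]
    d <- sqrt(sum((g@positions[i, ] - g@positions[j, ])^2))
    ref[i, ] <- ref[i, ] + x[j, ] * as.numeric(rbfExpand(d, cfg) %*% W)
  }
  expect_equal(out, ref, tolerance = 1e-6)
  # an isolated node receives the empty sum
  iso <- cfconv(x, g@positions, g@edges[0, , drop = FALSE], fnet, cfg)
  expect_true(all(iso == 0))
  expect_error(cfconv(x, g@positions, g@edges, function(r) r[, 1:2], cfg),
               "shape error")
})

test_that("atomwise layers are shared-weight dense maps, hence permutation-equivariant", {
  set.seed(4)
  x <- matrix(rnorm(12), 4, 3)
  expect_equal(atomwise(x, diag(3), rep(0, 3)), x)
  W <- matrix(rnorm(6), 3, 2); b <- rnorm(2)
  out <- atomwise(x, W, b)
  expect_equal(out, x %*% W + matrix(b, 4, 2, byrow = TRUE))
  p <- c(3, 1, 4, 2)
  expect_equal(atomwise(x[p, ], W, b), out[p, ])
  expect_error(atomwise(x, matrix(0, 5, 2), rep(0, 2)), "shape error")
})

test_that("directional message updates match a literal triplet-loop reference", {
  set.seed(9)
  g <- random_graph(n = 6, seed = 5, radius = 5, maxNeighbors = 4)
  E <- nrow(g@edges); F <- 6; IE <- 4; BE <- 3; K <- 5
  tr <- computeTriplets(g)
  cfgR <- rbfConfig(count = K, cutoff = 6)
  sbfc <- sbfConfig(3, 2, 6)
  d <- pocketec:::edge_lengths(g@positions, g@edges)
  rbf <- rbfExpand(d, cfgR)
  sbf <- sphericalFourierBessel(d[tr$edge_kj], tr$angle, sbfc)
  p <- list(Wrbf = matrix(rnorm(K * F), K, F),
            Wsbf1 = matrix(rnorm(6 * BE), 6, BE),
            Wsbf2 = matrix(rnorm(BE * IE), BE, IE),
            Wdown = matrix(rnorm(F * IE), F, IE),
            Wup = matrix(rnorm(IE * F), IE, F),
            W1 = matrix(rnorm(F * F), F, F),
            W2 = matrix(rnorm(F * F), F, F),
            b = rnorm(F))
  m <- matrix(rnorm(E * F), E, F)
  out <- dimenetMessageUpdate(m, rbf, sbf, tr, p)
  # naive per-edge loop
  ssp <- pocketec:::ssp
  mdown <- ssp(m %*% p$Wdown)
  sbf_f <- (sbf %*% p$Wsbf1) %*% p$Wsbf2
  for (e in seq_len(E)) {
    rows <- which(tr$edge_ji == e)
    tsum <- rep(0, IE)
    for (r in rows) tsum <- tsum + mdown[tr$edge_kj[r], ] * sbf_f[r, ]
    upd <- ssp((m[e, ] * as.numeric(rbf[e, , drop = FALSE] %*% p$Wrbf)) %*%
                 p$W1 + ssp(tsum %*% p$Wup) %*% p$W2 + p$b)
    expect_equal(out[e, ], m[e, ] + as.numeric(upd), tolerance = 1e-6)
  }
  # permuting the triplet list leaves the update unchanged (commutative sum)
  perm <- sample(nrow(tr))
  out2 <- dimenetMessageUpdate(m, rbf, sbf[perm, , drop = FALSE],
                               tr[perm, ], p)
  expect_equal(out2, out, tolerance = 1e-10)
})

test_that("a two-node graph has no triplets and reduces to the self/RBF path", {
  g <- methods::new("ProteinGraph",
                    positions = rbind(c(0, 0, 0), c(2, 0, 0)),
                    types = c(1L, 2L),
                    edges = rbind(c(1L, 2L), c(2L, 1L)),
                    resolution = "residue", neighborRadius = 3,
                    provenance = list(), schemeVersion = "test")
  expect_equal(nrow(computeTriplets(g)), 0L)
  m <- tiny_model("distances_angles", seed = 2)
  expect_length(forwardLogits(m, g), 3L)     # forward runs without angles
})

test_that("logits are invariant under rigid motions and node permutations", {
  set.seed(11)
  for (arch in c("distances", "distances_angles")) {
    m <- tiny_model(arch, seed = 5)
    for (rep in 1:10) {
      g <- random_graph(n = 7, seed = 100 + rep, radius = 6, maxNeighbors = 5)
      l0 <- forwardLogits(m, g)
      l1 <- forwardLogits(m, rotate_graph(g))
      expect_lt(max(abs(l1 - l0)) / max(abs(l0)), 1e-4)
    }
    # node permutation: permute nodes and re-index edges
    g <- random_graph(n = 6, seed = 33)
    p <- sample(6)
    inv <- order(p)
    gp <- methods::initialize(g, positions = g@positions[p, , drop = FALSE],
                              types = g@types[p],
                              edges = matrix(inv[g@edges], ncol = 2))
    expect_equal(forwardLogits(m, gp), forwardLogits(m, g),
                 tolerance = 1e-10)
  }
})

test_that("a single-node distances graph reduces to the readout of its embedding", {
  m <- tiny_model("distances", seed = 8)
  g <- methods::new("ProteinGraph", positions = matrix(0, 1, 3),
                    types = 3L, edges = matrix(integer(0), 0, 2),
                    resolution = "residue", neighborRadius = 6,
                    provenance = list(), schemeVersion = "test")
  lo <- forwardLogits(m, g)
  p <- m@params
  ssp <- pocketec:::ssp
  x <- p$embed[3L, , drop = FALSE]
  # all cfconv sums are empty; interaction blocks add only bias terms
  for (l in 1:2) {
    conv <- matrix(0, 1, ncol(x))
    A1 <- ssp(conv %*% p[[paste0("b", l, ".Wa1")]] +
                matrix(p[[paste0("b", l, ".ba1")]], 1))
    x <- x + A1 %*% p[[paste0("b", l, ".Wa2")]] +
      matrix(p[[paste0("b", l, ".ba2")]], 1)
  }
  hand <- ssp(x %*% p$r.W1 + matrix(p$r.b1, 1)) %*% p$r.W2 +
    matrix(p$r.b2, 1)
  expect_equal(lo, unname(hand), tolerance = 1e-10)
})

test_that("analytic gradients match finite differences", {
  g1 <- random_graph(n = 6, seed = 41, nTypes = 10)
  g2 <- random_graph(n = 5, seed = 42, nTypes = 10, label = 2L)
  m <- tiny_model("distances", seed = 3)
  gb <- batchGraphs(list(g1, g2))
  w <- c(1, 1.3, 0.6)
  fw <- pocketec:::forward_distances(m@params, m@config, gb, keepCache = TRUE)
  lg <- pocketec:::.wce_grad(fw$logits, c(1L, 2L), w)
  bw <- pocketec:::backward_distances(m@params, m@config, gb, fw$cache,
                                      lg$dlogits)
  eps <- 1e-6
  set.seed(17)
  for (nm in names(m@params)) {
    i <- sample(length(m@params[[nm]]), 1)
    up <- m@params; up[[nm]][i] <- up[[nm]][i] + eps
    dn <- m@params; dn[[nm]][i] <- dn[[nm]][i] - eps
    fu <- pocketec:::.wce_grad(pocketec:::forward_distances(
      up, m@config, gb)$logits, c(1L, 2L), w)$loss
    fd <- pocketec:::.wce_grad(pocketec:::forward_distances(
      dn, m@config, gb)$logits, c(1L, 2L), w)$loss
    num <- (fu - fd) / (2 * eps)
    expect_equal(bw$grads[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("gradient flows to every node embedding on a connected graph", {
  g <- random_graph(n = 7, seed = 55, radius = 50, maxNeighbors = 6)
  for (arch in c("distances", "distances_angles")) {
    m <- tiny_model(arch, seed = 9)
    lossFn <- function(lo) {
      z <- pocketec:::.wce_grad(lo, 1L, rep(1, 3))
      list(loss = z$loss, dlogits = z$dlogits)
    }
    mg <- pocketec:::mask_gradient(m, batchGraphs(list(g)),
                                   rep(1, 7), lossFn)
    expect_true(all(abs(mg$grad) > 0))
  }
})

test_that("nodes of one graph cannot influence another graph in a batch", {
  gA <- random_graph(n = 6, seed = 61, nTypes = 10)
  gB <- random_graph(n = 6, seed = 62, nTypes = 10)
  m <- tiny_model("distances", seed = 2)
  lA <- forwardLogits(m, batchGraphs(list(gA, gB)))[1, ]
  gB2 <- methods::initialize(gB, types = rev(gB@types))
  lA2 <- forwardLogits(m, batchGraphs(list(gA, gB2)))[1, ]
  expect_identical(lA, lA2)
})

test_that("EC designations truncate through the hierarchy and predictions carry confidence", {
  expect_equal(ecTruncate("2.7.10.1", "main"), "2")
  expect_equal(ecTruncate("2.7.10.1", "sub"), "2.7")
  expect_equal(ecTruncate("2.7.10.1", "subsub"), "2.7.10")
  expect_equal(ecTruncate("2.7.10.1", "designation"), "2.7.10.1")
  vocab <- c("1.1.1.1", "2.7.10.1", "3.4.21.4", "4.2.1.1")
  onehot <- c(-50, 50, -50, -50)
  pr <- predictEC(onehot, vocab)
  expect_equal(pr$label, "2.7.10.1")
  expect_equal(pr$confidence, 1.0)
  expect_equal(pr$main, "2")
  expect_equal(pr$subsub, "2.7.10")
  pu <- suppressWarnings(predictEC(c(0, 0, 0, 0), vocab))
  expect_equal(pu$confidence, 0.25)
  expect_true(pu$tie)
  expect_warning(predictEC(c(1, 1, 0, 0), vocab), "tie")
})

test_that("checkpoints round-trip and refuse mismatched vocabularies", {
  m <- tiny_model("distances", seed = 13)
  tf <- tempfile(fileext = ".ckpt")
  saveCheckpoint(m, tf)
  m2 <- loadCheckpoint(tf, expectVocab = m@classVocab,
                       expectScheme = m@schemeVersion)
  g <- random_graph(n = 5, seed = 7, nTypes = 10)
  expect_identical(forwardLogits(m2, g), forwardLogits(m, g))
  expect_error(loadCheckpoint(tf, expectVocab = c("x", "y")),
               "vocabulary mismatch")
  expect_error(loadCheckpoint(tf, expectScheme = "other-scheme"),
               "scheme mismatch")
})

test_that("Fourier-Bessel bases are well-formed", {
  cfg <- sbfConfig(4, 3, 10)
  # roots interlace and j_l vanishes there
  for (l in 0:3) {
    z <- cfg$roots[[l + 1]]
    expect_true(all(diff(z) > 0))
    expect_true(all(abs(pocketec:::spherical_bessel_j(l, z)) < 1e-8))
  }
  rb <- besselRadialBasis(c(1, 5, 9.999), cfg)
  expect_equal(dim(rb), c(3L, 3L))
  expect_true(all(abs(rb[3, ]) < 1e-4))   # envelope vanishes at the cutoff
  sb <- sphericalFourierBessel(c(2, 4), c(0.3, 2.1), cfg)
  expect_equal(dim(sb), c(2L, 12L))
  expect_true(all(is.finite(sb)))
})
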