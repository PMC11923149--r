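test_that("class weights are inverse-frequency, mean-normalized, monotone", {
  expect_equal(unname(classWeights(c(a = 10, b = 10))), c(1, 1))
  w <- classWeights(c(a = 1, b = 9))
  expect_equal(unname(w), c(1.8, 0.2))
  expect_gt(w["a"], w["b"])
  w3 <- classWeights(c(a = 2, b = 5, c = 20))
  expect_true(all(diff(unname(w3)) < 0))
  expect_equal(mean(w3), 1)
  expect_error(classWeights(c(a = 0, b = 5)), "unseen class")
})

test_that("weighted cross-entropy matches its closed forms and is linear in the weights", {
  # probability ~1 on the true class -> loss ~ 0
  expect_lt(weightedCrossEntropy(matrix(c(100, 0, 0, 0), 1), 1L), 1e-12)
  # uniform logits over 4 classes, unit weights: ln 4 per sample
  expect_equal(weightedCrossEntropy(matrix(0, 3, 4), c(1L, 2L, 3L)),
               log(4), tolerance = 1e-12)
  set.seed(6)
  lo <- matrix(rnorm(12), 3, 4)
  y <- c(2L, 4L, 1L)
  w <- c(0.5, 1.5, 1, 1)
  expect_equal(weightedCrossEntropy(lo, y, 2 * w),
               2 * weightedCrossEntropy(lo, y, w), tolerance = 1e-12)
  # uniform weights equal standard cross-entropy
  p <- exp(lo - apply(lo, 1, max)); p <- p / rowSums(p)
  std <- -mean(log(p[cbind(1:3, y)]))
  expect_equal(weightedCrossEntropy(lo, y), std, tolerance = 1e-12)
  # one-hot target matrix form and sum reduction
  Y <- diag(4)[y, ]
  expect_equal(weightedCrossEntropy(lo, Y, w, reduction = "sum"),
               3 * weightedCrossEntropy(lo, y, w), tolerance = 1e-12)
  expect_error(weightedCrossEntropy(matrix(c(NaN, 1), 1), 1L), "numeric error")
})

test_that("oversampling balances expected class frequencies and is seeded", {
  labels <- c(rep("a", 90), rep("b", 10))
  idx <- oversampleIndices(labels, size = 10000, seed = 3)
  fb <- mean(labels[idx] == "b")
  expect_lt(abs(fb - 0.5), 0.02)
  expect_identical(idx, oversampleIndices(labels, size = 10000, seed = 3))
  bal <- oversampleIndices(rep(c("x", "y"), 50), size = 5000, seed = 1)
  expect_lt(abs(mean(rep(c("x", "y"), 50)[bal] == "x") - 0.5), 0.03)
})

test_that("jitter augmentation is bounded, seeded, and identity at amplitude 0", {
  g <- random_graph(n = 10, seed = 2)
  expect_identical(augmentTranslate(g, 0), g)
  a1 <- augmentTranslate(g, 0.05, seed = 4)
  a2 <- augmentTranslate(g, 0.05, seed = 4)
  expect_identical(a1@positions, a2@positions)
  disp <- sqrt(rowSums((a1@positions - g@positions)^2))
  expect_true(all(disp <= 0.05 + 1e-12))
  expect_identical(a1@edges, g@edges)
})

test_that("training improves a small planted-motif problem and is reproducible", {
  scheme <- defaultAnnotationScheme()
  specs <- defaultClassSpecs()[1:2]
  attr(specs, "vocab") <- c("1.1.1.1", "2.7.10.1")
  ds <- makeDataset(8L, classSpecs = specs, decoyRate = 0, seed = 5L,
                    nResidues = 30L)
  graphs <- datasetGraphs(ds$entries, scheme, parameter = 15,
                          neighborRadius = 10, maxNeighbors = 8L)
  tr_idx <- c(1:6, 9:14)
  va_idx <- c(7:8, 15:16)
  m <- graphClassifier("distances", ds$vocab[1:2], scheme,
                       embeddingDim = 16L, nInteractions = 2L,
                       nGaussians = 8L, cutoff = 10, seed = 2)
  tc <- trainConfig(batchSize = 6L, maxEpochs = 25L, patience = 5L, seed = 9L)
  fit <- trainClassifier(m, graphs[tr_idx], graphs[va_idx], tc)
  expect_gte(max(fit$history$train_acc), 0.9)
  # early stopping: when it stops before the cap, the run ends exactly
  # patience epochs after the last strict validation improvement
  if (nrow(fit$history) < tc$maxEpochs) {
    va <- fit$history$val_acc
    lastImp <- max(which(va > c(-Inf, cummax(va))[seq_along(va)]))
    expect_equal(nrow(fit$history), lastImp + tc$patience)
  }
  # bit-for-bit reproducibility under the same seed
  fit2 <- trainClassifier(m, graphs[tr_idx], graphs[va_idx], tc)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model@params, fit2$model@params)
  expect_error(trainClassifier(m, list(), graphs[va_idx], tc),
               "empty dataset")
})

test_that("protein-centric F-score sweeps thresholds as hand enumeration predicts", {
  all_right <- proteinCentricF1(c("a", "b"), c(1, 1), c("a", "b"))
  expect_equal(all_right$f1, 1.0)
  expect_equal(all_right$fmax, 1.0)
  all_wrong <- proteinCentricF1(c("a", "b"), c(1, 1), c("b", "a"))
  expect_equal(all_wrong$fmax, 0.0)
  # 3 proteins: correct at 0.9, correct at 0.8, wrong at 0.99
  # t=0    : P = 2/3, R = 2/3, F = 2/3
  # t=0.85 : covered {0.9, 0.99}, P = 1/2, R = 1/3, F = 0.4
  # t=0.95 : covered {0.99},      P = 0,   R = 0,   F = 0
  sw <- proteinCentricF1(c("a", "b", "c"), c(0.9, 0.8, 0.99),
                         c("a", "b", "x"),
                         thresholds = c(0, 0.85, 0.95))
  expect_equal(sw$curve$f, c(2 / 3, 0.4, 0), tolerance = 1e-12)
  expect_equal(sw$fmax, 2 / 3, tolerance = 1e-12)
  expect_equal(sw$bestThreshold, 0)
})

test_that("per-class AUPR matches hand-computed areas and the random baseline", {
  # perfect separation
  sc <- cbind(c(0.9, 0.8, 0.1, 0.2), c(0.1, 0.2, 0.9, 0.8))
  expect_equal(unname(perClassAUPR(sc, c(1L, 1L, 2L, 2L))$perClass),
               c(1, 1))
  # 6-sample hand example, class 1 positives at ranks 1, 3, 4 by score:
  # recall steps 1/3 (P=1), 2/3 (P=2/3), 1 (P=3/4)
  s1 <- c(0.95, 0.8, 0.7, 0.6, 0.3, 0.1)
  pos <- c(1L, 2L, 1L, 1L, 2L, 2L)
  hand <- (1 / 3) * 1 + (1 / 3) * (2 / 3) + (1 / 3) * (3 / 4)
  got <- perClassAUPR(cbind(s1, 1 - s1), pos)$perClass
  expect_equal(unname(got[1]), hand, tolerance = 1e-12)
  # scores independent of truth -> AUPR near prevalence
  set.seed(12)
  n <- 4000
  y <- sample(c(1L, 2L), n, replace = TRUE, prob = c(0.25, 0.75))
  r <- runif(n)
  big <- perClassAUPR(cbind(r, 1 - r), y)
  expect_lt(abs(big$perClass[1] - 0.25), 0.05)
  # a class without positives is excluded with a message
  expect_message(out <- perClassAUPR(cbind(s1, 1 - s1, 0), pos),
                 "without positives")
  expect_true(is.na(out$perClass[3]))
})

test_that("the step-interpolated AUPR agrees with an independent threshold-loop reference", {
  # reference: direct precision/recall at every distinct score cutoff
  ref_aupr <- function(scores, positive) {
    cuts <- sort(unique(scores), decreasing = TRUE)
    prev_r <- 0; area <- 0
    for (t in cuts) {
      sel <- scores >= t
      p <- sum(positive & sel) / sum(sel)
      r <- sum(positive & sel) / sum(positive)
      area <- area + (r - prev_r) * p
      prev_r <- r
    }
    area
  }
  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    sc <- round(runif(n), 2)          # ties likely
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(y)) y[1] <- TRUE
    got <- perClassAUPR(cbind(sc, 1 - sc), ifelse(y, 1L, 2L))$perClass[1]
    expect_equal(unname(got), ref_aupr(sc, y), tolerance = 1e-10)
  }
})
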